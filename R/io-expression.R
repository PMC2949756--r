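#' Read a tab-delimited expression matrix
#'
#' Parses a series-matrix-like TSV with header
#' `probe_id<TAB>gene_symbol<TAB><sample columns>` into a
#' [SummarizedExperiment::SummarizedExperiment] with one `intensity` assay.
#' Sample columns are mapped to experimental conditions either via `design`
#' (a named character vector, `c(colname = condition)`) or, by default, by
#' parsing column names of the form `N_1`, `NL_2`, `TL_1`, `T_2` (condition
#' prefix, separator, replicate index).
#'
#' Row order is preserved. Unannotated probes (empty `gene_symbol`) are
#' retained and flagged in `rowData(x)$annotated`. The element
#' `metadata(x)$counts` records both the total probe count and the
#' annotation-bearing probe count, since published totals may refer to either.
#'
#' @param path path to the TSV file.
#' @param design optional named character vector mapping sample column names
#'   to conditions (values in `N`, `NL`, `TL`, `T`).
#' @return A `SummarizedExperiment`; `colData` has `condition` and
#'   `replicate`, `rowData` has `probe_id`, `gene_symbol`, `annotated`.
#' @seealso [writeExpressionMatrix()], [conditionAverages()]
#' @export
readExpressionMatrix <- function(path, design = NULL) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  for (col in c("probe_id", "gene_symbol"))
    if (!col %in% names(df))
      stop("expression matrix is missing required column '", col, "'")
  sampleCols <- setdiff(names(df), c("probe_id", "gene_symbol"))
  if (!length(sampleCols)) stop("expression matrix has no sample columns")
  if (is.null(design)) {
    m <- regmatches(sampleCols,
                    regexec("^(N|NL|TL|T)[._-]([0-9]+)$", sampleCols))
    bad <- vapply(m, length, 0L) == 0L
    if (any(bad))
      stop("cannot infer condition for sample column(s): ",
           paste(sampleCols[bad], collapse = ", "),
           " (supply `design`)")
    design <- vapply(m, `[`, "", 2L)
    names(design) <- sampleCols
  } else {
    missingCols <- setdiff(names(design), sampleCols)
    if (length(missingCols))
      stop("design names sample column(s) absent from the file: ",
           paste(missingCols, collapse = ", "))
    sampleCols <- names(design)
  }
  intens <- suppressWarnings(
    vapply(sampleCols, function(cn) as.numeric(df[[cn]]),
           numeric(nrow(df))))
  if (nrow(df) == 1L) intens <- matrix(intens, nrow = 1L,
                                       dimnames = list(NULL, sampleCols))
  badRow <- which(rowSums(is.na(intens)) > 0L)
  if (length(badRow))
    stop("non-numeric intensity in row ", badRow[1L],
         " (file line ", badRow[1L] + 1L, ") of ", path)
  if (any(intens < 0))
    stop("negative intensity values are not allowed (first at row ",
         which(rowSums(intens < 0) > 0)[1L], ")")
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id: ",
         df$probe_id[duplicated(df$probe_id)][1L])
  cond <- unname(design[sampleCols])
  repl <- as.integer(stats::ave(seq_along(cond), cond, FUN = seq_along))
  se <- SummarizedExperiment(
    assays = list(intensity = `dimnames<-`(intens,
                    list(df$probe_id, sampleCols))),
    rowData = DataFrame(probe_id = df$probe_id,
                        gene_symbol = df$gene_symbol,
                        annotated = nzchar(trimws(df$gene_symbol)),
                        row.names = df$probe_id),
    colData = DataFrame(condition = cond, replicate = repl,
                        row.names = sampleCols))
  metadata(se)$counts <- list(n_probes = nrow(df),
                              n_annotated = sum(nzchar(trimws(df$gene_symbol))))
  .validateDesign(se)
  se
}

.validateDesign <- function(se) {
  cond <- colData(se)$condition
  if (is.null(cond)) stop("colData must carry a 'condition' column")
  bad <- setdiff(unique(cond), c("N", "NL", "TL", "T"))
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  invisible(se)
}

#' Write an expression matrix TSV
#'
#' Inverse of [readExpressionMatrix()]; intensities are written with full
#' precision (`format(..., digits = 15)`) so that write/read round-trips are
#' exact at double precision.
#'
#' @param se a `SummarizedExperiment` as produced by [readExpressionMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- assay(se, "intensity")
  df <- data.frame(probe_id = rowData(se)$probe_id,
                   gene_symbol = rowData(se)$gene_symbol,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (cn in colnames(m)) df[[cn]] <- format(m[, cn], digits = 15,
                                             scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intensity sub-matrix for one condition
#'
#' @param se a `SummarizedExperiment` with a `condition` column in `colData`.
#' @param condition one of `"N"`, `"NL"`, `"TL"`, `"T"`.
#' @return matrix of replicate intensities (probes x replicates).
#' @export
conditionIntensities <- function(se, condition) {
  keep <- colData(se)$condition == condition
  if (!any(keep)) stop("condition '", condition, "' absent from the design")
  assay(se, "intensity")[, keep, drop = FALSE]
}

#' Collapse probe-level rows to genes
#'
#' Probes sharing a gene symbol (case-insensitive, trimmed) are collapsed by
#' keeping the probe with the highest overall mean intensity; unannotated
#' probes are dropped. This is the probe-to-gene rule used everywhere a "gene"
#' count is reported.
#'
#' @param se a `SummarizedExperiment` from [readExpressionMatrix()].
#' @return A `SummarizedExperiment` with one row per gene symbol;
#'   `rowData(x)$n_probes` records how many probes were collapsed into each.
#' @export
collapseToGenes <- function(se) {
  rd <- rowData(se)
  ann <- which(rd$annotated)
  if (!length(ann)) return(se[integer(0), ])
  key <- toupper(trimws(rd$gene_symbol[ann]))
  means <- rowMeans(assay(se, "intensity"))[ann]
  ord <- ann[order(key, -means)]
  keyOrd <- toupper(trimws(rd$gene_symbol[ord]))
  keep <- ord[!duplicated(keyOrd)]
  out <- se[sort(keep), ]
  nper <- table(key)
  rowData(out)$n_probes <-
    as.integer(nper[toupper(trimws(rowData(out)$gene_symbol))])
  out
}
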