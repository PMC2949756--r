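#' Read curated TF-to-target-gene lists
#'
#' Tab-delimited with header `accession<TAB>tf_name<TAB>targets`; the targets
#' field is a comma-separated list of gene symbols. Symbols are trimmed and
#' deduplicated case-insensitively within each association (the first spelling
#' encountered is kept for display; all comparisons elsewhere are
#' case-insensitive, since curated tables mix capitalizations such as
#' "Sry"/"SRY").
#'
#' @param path TSV path.
#' @return A data.frame with columns `accession`, `tf_name` and a list-column
#'   `targets` (character vectors, non-empty).
#' @seealso [writeTargetList()], [overlapTargets()]
#' @export
readTargetList <- function(path) {
  if (!file.exists(path)) stop("target list file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("accession", "tf_name", "targets")
  if (!all(need %in% names(df)))
    stop("target list must have columns: ", paste(need, collapse = ", "))
  targets <- lapply(seq_len(nrow(df)), function(i) {
    tg <- trimws(strsplit(df$targets[i], ",", fixed = TRUE)[[1L]])
    tg <- tg[nzchar(tg)]
    if (!length(tg))
      stop("empty target field for accession '", df$accession[i],
           "' (row ", i, ")")
    tg[!duplicated(toupper(tg))]
  })
  out <- data.frame(accession = df$accession, tf_name = df$tf_name,
                    stringsAsFactors = FALSE)
  out$targets <- targets
  out
}

#' @rdname readTargetList
#' @param associations data.frame as returned by [readTargetList()].
#' @export
writeTargetList <- function(associations, path) {
  df <- data.frame(
    accession = associations$accession,
    tf_name = associations$tf_name,
    targets = vapply(associations$targets, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
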