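# Literature-target validation: overlap curated TF-target lists with the
# two-fold pro-inflammatory signature, profile the overlapping targets, and
# optionally run the cross-dataset (four-condition) tolerizability check and
# a random-gene-set null.

#' Overlap curated targets with an expression signature
#'
#' Deduplicated (case-insensitive) union of all association targets,
#' intersected with the signature gene set. Idempotent under repeated
#' association entries.
#'
#' @param associations data.frame from [readTargetList()].
#' @param signature character vector of signature gene symbols (e.g. from
#'   [twofoldSignature()]).
#' @return character vector of overlapping symbols (uppercase, sorted), with
#'   attribute `n_targets`, the deduplicated target-universe size.
#' @export
overlapTargets <- function(associations, signature) {
  targets <- toupper(trimws(unlist(associations$targets, use.names = FALSE)))
  targets <- unique(targets[nzchar(targets)])
  sig <- unique(toupper(trimws(as.character(signature))))
  out <- sort(intersect(targets, sig))
  attr(out, "n_targets") <- length(targets)
  out
}

#' Validate predicted profile TFs against curated targets
#'
#' Assembles the relaxed two-fold pro-inflammatory signature from the
#' matrix, overlaps it with the curated target lists, flags the
#' pro-inflammatory expression pattern per overlapping gene, computes
#' relative-expression profiles (normalized to the global N-condition
#' maximum), and — when given — runs the four-condition cross-dataset check
#' on a second matrix and the random-gene-set pattern null.
#'
#' On a signature built from the same matrix with the same fold threshold,
#' every overlapping gene necessarily shows the pattern, so
#' `pattern_pass_count == overlap_count`; the counts can differ only when
#' pattern and signature come from different matrices or thresholds.
#'
#' @param se the three-condition `SummarizedExperiment`.
#' @param associations data.frame from [readTargetList()].
#' @param secondSe optional four-condition matrix for the cross-dataset
#'   check.
#' @param seed optional seed; when supplied, [randomGenePatternNull()] is run
#'   with `setSize = overlap_count` (or `nullSetSize`).
#' @param fold two-fold filter threshold (default 2).
#' @param nSets,nullSetSize random-null controls.
#' @return A `ValidationReport`: list with `signature_size`, `overlap_genes`,
#'   `overlap_count`, `target_universe_count`, `pattern_pass_count`,
#'   `pattern_flags`, `profiles`, `cross_dataset` (or NULL),
#'   `cross_dataset_pass_count` (or NA), `random_null_counts` (or NULL).
#' @export
validateTargets <- function(se, associations, secondSe = NULL, seed = NULL,
                            fold = 2, nSets = 10, nullSetSize = NULL) {
  sig <- twofoldSignature(se, fold = fold)
  overlap <- overlapTargets(associations, sig)
  sigSet <- toupper(sig)
  flags <- setNames(overlap %in% sigSet, overlap)
  profiles <- relativeProfiles(se, overlap)
  crossDf <- NULL
  crossPass <- NA_integer_
  if (!is.null(secondSe)) {
    crossDf <- crossDatasetPattern(secondSe, overlap)
    crossPass <- attr(crossDf, "n_tolerizable")
  }
  nullCounts <- NULL
  if (!is.null(seed) && length(overlap)) {
    if (is.null(nullSetSize)) nullSetSize <- length(overlap)
    nullCounts <- randomGenePatternNull(se, setSize = nullSetSize,
                                        nSets = nSets, seed = seed,
                                        fold = fold)
  }
  structure(list(signature_size = length(sig),
                 overlap_genes = as.character(overlap),
                 overlap_count = length(overlap),
                 target_universe_count = attr(overlap, "n_targets"),
                 pattern_pass_count = sum(flags),
                 pattern_flags = flags,
                 profiles = profiles,
                 cross_dataset = crossDf,
                 cross_dataset_pass_count = crossPass,
                 random_null_counts = nullCounts,
                 fold = fold),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport (", x$fold, "-fold signature)\n", sep = "")
  cat("  signature genes:     ", x$signature_size, "\n")
  cat("  curated targets:     ", x$target_universe_count, "\n")
  cat("  overlap:             ", x$overlap_count, "\n")
  cat("  pattern passes:      ", x$pattern_pass_count, "\n")
  if (!is.na(x$cross_dataset_pass_count))
    cat("  cross-dataset passes:", x$cross_dataset_pass_count, "of",
        x$overlap_count, "\n")
  if (!is.null(x$random_null_counts))
    cat("  random-null counts:  ",
        paste(x$random_null_counts, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a ValidationReport to JSON
#'
#' @param report a `ValidationReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  x <- unclass(report)
  x$pattern_flags <- as.list(x$pattern_flags)
  x$random_null_counts <- if (is.null(x$random_null_counts)) NULL
    else as.integer(x$random_null_counts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
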