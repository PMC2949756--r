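#' Read a TRANSFAC-style PWM library
#'
#' Parses a flat file of matrix blocks separated by `//`. Each block carries
#' an accession line (`AC M00062`), an optional name line (`NA IRF-1` or
#' `ID ...`), a `P0 A C G T` column header and one row per motif position
#' (`01  5  0  0  12  C`). Rows may hold either counts or probabilities:
#' blocks whose column totals are all within 0.01 of 1 are treated as
#' already-normalized frequencies and used as-is (so that write/read
#' round-trips are exact to rounding); otherwise rows are treated as counts
#' and converted with a 0.5 per-cell pseudocount.
#'
#' @param path library file path.
#' @return A list of [PWMotif-class], named by accession.
#' @seealso [writePWMLibrary()], [readMotifTable()]
#' @export
readPWMLibrary <- function(path) {
  if (!file.exists(path)) stop("PWM library file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (bl in blocks) {
    bl <- bl[!grepl("^(//|XX|\\s*$)", bl)]
    if (!length(bl)) next
    acLine <- grep("^AC\\s+", bl, value = TRUE)
    if (!length(acLine)) next
    acc <- trimws(sub("^AC\\s+", "", acLine[1L]))
    naLine <- grep("^NA\\s+", bl, value = TRUE)
    tf <- if (length(naLine)) trimws(sub("^NA\\s+", "", naLine[1L])) else ""
    rows <- grep("^[0-9]+\\s+", bl, value = TRUE)
    if (!length(rows))
      stop("PWM block '", acc, "' has no matrix rows")
    vals <- lapply(strsplit(trimws(rows), "\\s+"), function(p) {
      v <- suppressWarnings(as.numeric(p[2:5]))
      if (anyNA(v)) stop("malformed matrix row in block '", acc, "'")
      v
    })
    m <- t(do.call(rbind, vals))  # 4 x w, rows A,C,G,T
    rownames(m) <- c("A", "C", "G", "T")
    if (any(colSums(m) <= 0))
      stop("PWM block '", acc, "' has a column with zero total")
    pwm <- if (all(abs(colSums(m) - 1) <= 0.01)) {
      PWMotif(sweep(m, 2L, colSums(m), "/"), accession = acc, tfName = tf)
    } else {
      pwmFromCounts(m, accession = acc, tfName = tf, pseudocount = 0.5)
    }
    if (acc %in% names(out))
      stop("duplicate accession in PWM library: ", acc)
    out[[acc]] <- pwm
  }
  if (!length(out)) stop("no PWM blocks found in ", path)
  out
}

#' Write a PWM library in the TRANSFAC-style flat format
#'
#' Probabilities are written with six decimals; [readPWMLibrary()] recognizes
#' such blocks as frequencies, so round-trips reproduce columns within 1e-6.
#'
#' @param library list of [PWMotif-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePWMLibrary <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in library) {
    p <- motifMatrix(pwm)
    cons <- strsplit(motifConsensus(pwm), "")[[1L]]
    writeLines(c(paste("AC", accession(pwm)), "XX",
                 paste("NA", tfName(pwm)), "XX",
                 "P0      A       C       G       T"), con)
    for (j in seq_len(ncol(p)))
      writeLines(sprintf("%02d  %.6f  %.6f  %.6f  %.6f  %s",
                         j, p[1L, j], p[2L, j], p[3L, j], p[4L, j],
                         cons[j]), con)
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read/write a minimal per-motif matrix TSV
#'
#' The minimal format used for de novo discovery output: a four-column TSV
#' (`A`, `C`, `G`, `T`) with one row per motif position, probabilities.
#'
#' @param path TSV path.
#' @inheritParams PWMotif
#' @return `readMotifTable`: a [PWMotif-class]; `writeMotifTable`: `path`.
#' @export
readMotifTable <- function(path, accession = "", tfName = "") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("A", "C", "G", "T") %in% names(df)))
    stop("motif TSV must have columns A, C, G, T")
  m <- t(as.matrix(df[, c("A", "C", "G", "T")]))
  rownames(m) <- c("A", "C", "G", "T")
  PWMotif(sweep(m, 2L, colSums(m), "/"), accession = accession,
          tfName = tfName)
}

#' @rdname readMotifTable
#' @param pwm a [PWMotif-class] to write.
#' @export
writeMotifTable <- function(pwm, path) {
  p <- motifMatrix(pwm)
  df <- data.frame(A = p[1L, ], C = p[2L, ], G = p[3L, ], T = p[4L, ])
  utils::write.table(format(df, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
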