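#' Read promoter sequences from FASTA
#'
#' Promoters cover a fixed window around the transcription start site
#' (default -1000..+300, i.e. 1301 nt); repeat-masked stretches arrive as `N`
#' runs. Headers follow `>gene_id window=-1000..300 strand=+`; when the
#' `window=` field is absent, `expectedWindow` is assumed. Sequences are
#' uppercased; characters outside A,C,G,T,N are rejected. Promoters shorter
#' than the declared window are accepted with a warning (genes near contig
#' ends get truncated windows); downstream scans simply use the available
#' sequence.
#'
#' @param path FASTA file path.
#' @param expectedWindow integer pair `c(start, end)` relative to the TSS,
#'   default `c(-1000, 300)`.
#' @return A [Biostrings::DNAStringSet] named by `gene_id`; `mcols()` carries
#'   `window_start`, `window_end`, `strand`.
#' @seealso [writePromoters()]
#' @export
readPromoters <- function(path, expectedWindow = c(-1000L, 300L)) {
  if (!file.exists(path)) stop("promoter FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("promoter FASTA is empty: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in promoter FASTA: ",
         ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    stop("zero-length promoter record: ", ids[!nzchar(seqs)][1L])
  badChr <- grepl("[^ACGTN]", seqs)
  if (any(badChr))
    stop("promoter '", ids[badChr][1L],
         "' contains characters outside A,C,G,T,N")
  winRe <- "window=(-?[0-9]+)\\.\\.(\\+?-?[0-9]+)"
  ws <- rep(expectedWindow[1L], length(ids))
  we <- rep(expectedWindow[2L], length(ids))
  hasWin <- grepl(winRe, headers)
  if (any(hasWin)) {
    mm <- regmatches(headers[hasWin], regexec(winRe, headers[hasWin]))
    ws[hasWin] <- as.integer(vapply(mm, `[`, "", 2L))
    we[hasWin] <- as.integer(sub("\\+", "", vapply(mm, `[`, "", 3L)))
  }
  strand <- ifelse(grepl("strand=-", headers, fixed = TRUE), "-", "+")
  expLen <- we - ws + 1L
  short <- nchar(seqs) < expLen
  if (any(short))
    warning(sum(short), " promoter(s) shorter than the declared window ",
            "(first: ", ids[short][1L], "); scanning uses available sequence")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- DataFrame(window_start = ws, window_end = we,
                          strand = strand)
  out
}

#' Write promoter sequences to FASTA
#'
#' @param promoters a named `DNAStringSet` (as from [readPromoters()] or
#'   [generatePromoters()]); `mcols()` `window_start`/`window_end`/`strand`
#'   are emitted in the headers when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePromoters <- function(promoters, path) {
  mc <- mcols(promoters)
  hdr <- names(promoters)
  if (!is.null(mc) && all(c("window_start", "window_end") %in% names(mc))) {
    st <- if ("strand" %in% names(mc)) mc$strand else "+"
    hdr <- sprintf("%s window=%d..%s%d strand=%s", names(promoters),
                   mc$window_start,
                   ifelse(mc$window_end >= 0, "+", ""), mc$window_end, st)
  }
  lines <- character(2L * length(promoters))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- as.character(promoters)
  writeLines(lines, path)
  invisible(path)
}
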