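# PASTAA-like engine: genes are ranked by predicted TF binding affinity of
# their promoters and, independently, by a condition-specificity score; the
# two rankings are associated by the minimum hypergeometric tail probability
# over a grid of rank-cutoff pairs ("iterated hypergeometric test").

#' Occupancy-style promoter binding affinity
#'
#' `affinity = sum over all windows and both strands of exp(log-odds)`, a
#' monotone, parameter-free occupancy proxy (the beta = 1 case of a
#' thermodynamic occupancy model). Log-odds use a 0-order background
#' estimated from the promoter set unless supplied. Windows containing
#' masked (`N`) bases contribute 0; a promoter shorter than the matrix width
#' scores 0 with a warning.
#'
#' @param pwm a [PWMotif-class].
#' @param promoters named `DNAStringSet` or character vector.
#' @param background optional length-4 background distribution.
#' @param bothStrands scan both strands (default TRUE).
#' @return numeric vector of affinities, one per promoter.
#' @export
promoterAffinity <- function(pwm, promoters, background = NULL,
                             bothStrands = TRUE) {
  codes <- .encodeSeqs(promoters)
  if (is.null(background)) background <- .backgroundFreq(codes)
  w <- motifWidth(pwm)
  short <- lengths(codes) < w
  if (any(short))
    warning(sum(short), " promoter(s) shorter than the matrix width score 0")
  sc <- .scanPWM(codes, pwm, background, bothStrands = bothStrands)
  aff <- numeric(length(codes))
  addStrand <- function(scores) {
    idx <- which(!is.na(scores))
    if (length(idx)) {
      tab <- rowsum(exp(scores[idx]), sc$layout$winseq[idx])
      aff[as.integer(rownames(tab))] <<-
        aff[as.integer(rownames(tab))] + tab[, 1L]
    }
  }
  addStrand(sc$fwd)
  if (bothStrands) addStrand(sc$rev)
  names(aff) <- names(promoters)
  aff
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` when `nDraw` genes are drawn without replacement from a
#' universe of `nUniverse` genes of which `nCategory` are in the category.
#'
#' @param k observed overlap (0 <= k <= min(nDraw, nCategory)).
#' @param nDraw,nCategory,nUniverse hypergeometric parameters.
#' @return the tail probability in `(0, 1]`.
#' @examples
#' hypergeometricTail(4, 4, 5, 10)  # 5/210
#' @export
hypergeometricTail <- function(k, nDraw, nCategory, nUniverse) {
  if (any(c(k, nDraw, nCategory, nUniverse) < 0) ||
      nDraw > nUniverse || nCategory > nUniverse ||
      k > min(nDraw, nCategory))
    stop("inconsistent hypergeometric arguments")
  if (k == 0) return(1)
  stats::phyper(k - 1, nCategory, nUniverse - nCategory, nDraw,
                lower.tail = FALSE)
}

#' Associate one PWM with a gene set by the iterated hypergeometric test
#'
#' Genes are ranked by promoter affinity for `pwm` (descending) and by the
#' supplied condition-specificity score (descending); ranking ties are broken
#' by gene identifier (lexicographic) for determinism. For every pair
#' `(i, j)` in `cutoffGrid x cutoffGrid`, the overlap `k` between the top-i
#' affinity genes and the top-j specificity genes is scored by
#' [hypergeometricTail()]`(k, i, j, n)`; the reported association is the
#' minimum p over the grid (uncorrected by default; `bonferroni = TRUE`
#' multiplies by the number of grid pairs, capped at 1). The test is
#' rank-based, hence invariant to monotone transforms of either score.
#'
#' @param pwm a [PWMotif-class].
#' @param promoters named `DNAStringSet`/character vector (one per gene).
#' @param specificity named numeric vector covering every promoter gene.
#' @param cutoffGrid candidate rank cutoffs; intersected with `[1, n]`
#'   (default `c(5, 10, 20, 50, 100, 200)`).
#' @param background optional background passed to [promoterAffinity()].
#' @param bonferroni multiply best p by the grid size (default FALSE).
#' @param affinity optional precomputed affinity vector (named), bypassing
#'   the promoter scan.
#' @return one-row data.frame: `accession`, `tf_name`, `best_p`, `i`, `j`,
#'   `k`.
#' @export
associateTF <- function(pwm, promoters, specificity,
                        cutoffGrid = c(5, 10, 20, 50, 100, 200),
                        background = NULL, bonferroni = FALSE,
                        affinity = NULL) {
  genes <- names(promoters)
  if (is.null(genes)) stop("promoters must be named by gene")
  if (!all(genes %in% names(specificity)))
    stop("specificity must be defined for every promoter gene")
  if (is.null(affinity))
    affinity <- promoterAffinity(pwm, promoters, background = background)
  n <- length(genes)
  grid <- sort(unique(cutoffGrid[cutoffGrid >= 1 & cutoffGrid <= n]))
  if (!length(grid)) stop("empty cutoff grid after intersection with [1, n]")
  affRank <- genes[order(-affinity[genes], genes)]
  specRank <- genes[order(-specificity[genes], genes)]
  best <- list(p = Inf, i = NA_integer_, j = NA_integer_, k = NA_integer_)
  for (i in grid) {
    topA <- affRank[seq_len(i)]
    for (j in grid) {
      k <- sum(topA %in% specRank[seq_len(j)])
      p <- hypergeometricTail(k, i, j, n)
      if (p < best$p) best <- list(p = p, i = i, j = j, k = k)
    }
  }
  p <- if (bonferroni) min(1, best$p * length(grid)^2) else best$p
  data.frame(accession = accession(pwm), tf_name = tfName(pwm),
             best_p = p, i = best$i, j = best$j, k = best$k,
             stringsAsFactors = FALSE)
}

#' Run [associateTF()] for every matrix in a library
#'
#' @param library list of [PWMotif-class].
#' @inheritParams associateTF
#' @return data.frame with one row per accession, sorted by `best_p`.
#' @export
associateLibrary <- function(library, promoters, specificity,
                             cutoffGrid = c(5, 10, 20, 50, 100, 200),
                             background = NULL, bonferroni = FALSE) {
  if (is.null(background))
    background <- .backgroundFreq(.encodeSeqs(promoters))
  rows <- lapply(library, function(pwm)
    associateTF(pwm, promoters, specificity, cutoffGrid = cutoffGrid,
                background = background, bonferroni = bonferroni))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$best_p, out$accession), , drop = FALSE]
}
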