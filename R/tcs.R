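# MotifModeler-like engine: occurrences of candidate motifs in promoters are
# regressed (least squares) against a per-gene expression response; iterating
# over seeded random motif subsets accumulates a transcription contribution
# score (TCS) per motif, with a stimulatory/inhibitory sign from the mean raw
# coefficient.

#' Count motif occurrences in promoters
#'
#' For a word motif (character), occurrences are exact matches, counted
#' overlapping, once per strand (`bothStrands` adds matches of the reverse
#' complement); positions containing `N` never match. For a [PWMotif-class],
#' a window counts as an occurrence when its log-odds score (0-order
#' background) reaches `threshold` times the maximum attainable score of the
#' matrix. A motif longer than a promoter yields count 0 with a warning.
#'
#' @param motif character word over A,C,G,T or a [PWMotif-class].
#' @param promoters `DNAStringSet` or character vector.
#' @param bothStrands count on both strands (default TRUE).
#' @param threshold PWM score fraction for calling a site (default 0.8).
#' @param background optional length-4 background for PWM scoring.
#' @return integer vector of counts, one per promoter.
#' @examples
#' countMotifOccurrences("ACGT", "TACGTACGTT")            # 2
#' countMotifOccurrences("GGCC", "GGCCAA")                # 2 (one per strand)
#' @export
countMotifOccurrences <- function(motif, promoters, bothStrands = TRUE,
                                  threshold = 0.8, background = NULL) {
  n <- length(promoters)
  if (is.character(motif) && length(motif) == 1L) {
    w <- nchar(motif)
    subj <- Biostrings::DNAStringSet(toupper(as.character(promoters)))
    cnt <- Biostrings::vcountPattern(motif, subj, fixed = TRUE)
    if (bothStrands) {
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(motif)))
      cnt <- cnt + Biostrings::vcountPattern(rc, subj, fixed = TRUE)
    }
    if (any(Biostrings::width(subj) < w)) {
      warning("motif longer than ", sum(Biostrings::width(subj) < w),
              " promoter(s); their count is 0")
      cnt[Biostrings::width(subj) < w] <- 0L
    }
    return(as.integer(cnt))
  }
  if (!is(motif, "PWMotif"))
    stop("motif must be a single character word or a PWMotif")
  codes <- .encodeSeqs(promoters)
  if (is.null(background)) background <- .backgroundFreq(codes)
  prof <- motifMatrix(motif)
  w <- ncol(prof)
  short <- lengths(codes) < w
  if (any(short))
    warning("motif wider than ", sum(short), " promoter(s); their count is 0")
  sc <- .scanPWM(codes, motif, background, bothStrands = bothStrands)
  lo <- .logOdds(prof, background)
  cut <- threshold * sum(apply(lo, 2L, max))
  counts <- integer(n)
  addHits <- function(scores) {
    idx <- which(!is.na(scores) & scores >= cut)
    if (length(idx)) {
      tab <- table(sc$layout$winseq[idx])
      counts[as.integer(names(tab))] <<-
        counts[as.integer(names(tab))] + as.integer(tab)
    }
  }
  addHits(sc$fwd)
  if (bothStrands) addHits(sc$rev)
  as.integer(counts)
}

#' Motif occurrence count matrix
#'
#' @param motifs character vector of words, list of [PWMotif-class], or a mix.
#' @param promoters named `DNAStringSet` or character vector.
#' @inheritParams countMotifOccurrences
#' @return integer matrix, promoters (genes) x motifs.
#' @export
motifCountMatrix <- function(motifs, promoters, bothStrands = TRUE,
                             threshold = 0.8, background = NULL) {
  if (is.character(motifs)) motifs <- as.list(motifs)
  ids <- vapply(motifs, function(m)
    if (is.character(m)) m else accession(m), character(1))
  codes <- .encodeSeqs(promoters)
  if (is.null(background)) background <- .backgroundFreq(codes)
  m <- vapply(motifs, function(mo)
    countMotifOccurrences(mo, promoters, bothStrands = bothStrands,
                          threshold = threshold, background = background),
    integer(length(promoters)))
  if (length(promoters) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(if (is.null(names(promoters)))
    as.character(seq_along(promoters)) else names(promoters), ids)
  m
}

#' The fixed-size word universe for the TCS engine
#'
#' All DNA words of size `k` present in at least `minPromoters` promoters
#' (on either strand). The pruning keeps the universe desk-scale.
#'
#' @param promoters `DNAStringSet` or character vector.
#' @param k word size (default 8).
#' @param minPromoters presence threshold (default 3).
#' @return character vector of words.
#' @export
wordUniverse <- function(promoters, k = 8, minPromoters = 3) {
  subj <- Biostrings::DNAStringSet(toupper(as.character(promoters)))
  freq <- Biostrings::oligonucleotideFrequency(subj, width = k)
  rcfreq <- Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(subj), width = k)
  present <- (freq + rcfreq) > 0
  words <- colnames(freq)[colSums(present) >= minPromoters]
  words
}

#' Ordinary least squares of a response on motif counts
#'
#' OLS with an intercept. Constant (zero-variance) predictor columns are
#' confounded with the intercept: their coefficient is reported as 0 and
#' flagged. If the design is otherwise rank-deficient, a ridge fallback
#' (`lambda = 1e-6 * trace(X'X)`) is used and flagged.
#'
#' @param counts numeric matrix, genes x motifs.
#' @param response numeric vector, one value per gene.
#' @return list with `coefficients` (named, one per motif), `intercept`,
#'   `confounded` (logical per motif), `ridge` (flag), `fitted`, `residuals`.
#' @examples
#' fitLinearModel(cbind(m1 = c(0, 1, 2)), c(1, 3, 5))  # coefficient 2
#' @export
fitLinearModel <- function(counts, response) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("m", seq_len(ncol(counts)))
  if (nrow(counts) != length(response))
    stop("response length must match the number of genes")
  sds <- apply(counts, 2L, stats::sd)
  confounded <- sds == 0
  coefs <- setNames(rep(0, ncol(counts)), colnames(counts))
  use <- which(!confounded)
  X <- cbind(`(Intercept)` = 1, counts[, use, drop = FALSE])
  ridge <- FALSE
  if (length(use)) {
    fit <- stats::lm.fit(X, response)
    if (fit$rank < ncol(X)) {
      ridge <- TRUE
      XtX <- crossprod(X)
      lambda <- 1e-6 * sum(diag(XtX))
      pen <- diag(ncol(X)) * lambda
      pen[1L, 1L] <- 0  # do not shrink the intercept
      beta <- solve(XtX + pen, crossprod(X, response))[, 1L]
    } else beta <- fit$coefficients
    coefs[use] <- beta[-1L]
    intercept <- beta[[1L]]
  } else intercept <- mean(response)
  fitted <- as.numeric(cbind(1, counts) %*% c(intercept, coefs))
  list(coefficients = coefs, intercept = intercept,
       confounded = confounded, ridge = ridge,
       fitted = fitted, residuals = response - fitted)
}

#' Seeded uniform random response values
#'
#' Uniform draws within the range of the test genes' expression values; used
#' for the random-gene background runs of the TCS engine.
#'
#' @param rangeMin,rangeMax range bounds (`rangeMin <= rangeMax`).
#' @param n number of draws (>= 0).
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
randomResponse <- function(rangeMin, rangeMax, n, seed = 1) {
  if (n < 0) stop("n must be >= 0")
  if (rangeMin > rangeMax) stop("rangeMin must be <= rangeMax")
  .withSeed(seed, stats::runif(n, rangeMin, rangeMax))
}

#' Iterated transcription contribution score (TCS)
#'
#' Repeatedly fits [fitLinearModel()] of the response on seeded random
#' subsets of the motif universe. Every sampled motif accumulates the
#' absolute standardized coefficient `|b| * sd(count) / sd(response)`; its
#' TCS is that accumulation divided by the number of times it was sampled
#' (`normalization = "mean"`, the default, removing sampling-frequency bias)
#' or the raw accumulation (`"sum"`). The sign comes from the mean raw
#' coefficient: stimulatory (positive), inhibitory (negative), or
#' indeterminate (never sampled, or mean coefficient ~ 0).
#'
#' @param promoters named `DNAStringSet` or character vector (one per gene).
#' @param response numeric response per gene (same order as `promoters`).
#' @param motifUniverse character words and/or [PWMotif-class] list; defaults
#'   to [wordUniverse()] of the promoters.
#' @param subsetSize motifs per iteration (default 20).
#' @param nIterations number of random subsets (default 500, >= 1).
#' @param seed RNG seed.
#' @param normalization `"mean"` or `"sum"`.
#' @inheritParams countMotifOccurrences
#' @return data.frame sorted by `tcs` descending: `motif`, `tcs`, `sign`,
#'   `times_sampled`, `mean_coef`.
#' @export
runTCS <- function(promoters, response, motifUniverse = NULL,
                   subsetSize = 20, nIterations = 500, seed = 1,
                   normalization = c("mean", "sum"), bothStrands = TRUE,
                   threshold = 0.8) {
  normalization <- match.arg(normalization)
  if (nIterations < 1) stop("nIterations must be >= 1")
  if (is.null(motifUniverse)) motifUniverse <- wordUniverse(promoters)
  if (is.character(motifUniverse)) motifUniverse <- as.list(motifUniverse)
  nu <- length(motifUniverse)
  if (subsetSize > nu)
    stop("subsetSize (", subsetSize, ") exceeds the motif universe (", nu, ")")
  counts <- motifCountMatrix(motifUniverse, promoters,
                             bothStrands = bothStrands, threshold = threshold)
  ids <- colnames(counts)
  sdy <- stats::sd(response)
  sdx <- apply(counts, 2L, stats::sd)
  acc <- setNames(rep(0, nu), ids)
  rawSum <- setNames(rep(0, nu), ids)
  times <- setNames(rep(0L, nu), ids)
  .withSeed(seed, {
    for (it in seq_len(nIterations)) {
      sub <- sample.int(nu, subsetSize)
      fit <- fitLinearModel(counts[, sub, drop = FALSE], response)
      std <- if (sdy > 0) abs(fit$coefficients) * sdx[sub] / sdy
             else rep(0, subsetSize)
      acc[sub] <- acc[sub] + std
      rawSum[sub] <- rawSum[sub] + fit$coefficients
      times[sub] <- times[sub] + 1L
    }
  })
  tcs <- ifelse(times > 0,
                if (normalization == "mean") acc / pmax(times, 1L) else acc,
                0)
  meanCoef <- ifelse(times > 0, rawSum / pmax(times, 1L), NA_real_)
  sgn <- ifelse(times == 0L | is.na(meanCoef) | abs(meanCoef) < 1e-12,
                "indeterminate",
                ifelse(meanCoef > 0, "stimulatory", "inhibitory"))
  out <- data.frame(motif = ids, tcs = unname(tcs), sign = unname(sgn),
                    times_sampled = unname(times),
                    mean_coef = unname(meanCoef),
                    stringsAsFactors = FALSE)
  out[order(-out$tcs, out$motif), , drop = FALSE]
}
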