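# De novo motif discovery: two-component finite mixture (motif + background)
# fitted by EM under the ZOOPS (zero-or-one occurrence per sequence) model,
# scanning both strands, with sequential multi-motif extraction by site
# erasure and a Monte-Carlo (dinucleotide-shuffle) E-value calibration.

# One evaluation of the ZOOPS E-step quantities at fixed parameters.
# Returns the log-likelihood ratio over the background-only model, the
# per-window responsibilities (split by strand) and per-sequence occupancy.
# No log-sum-exp shifting is needed: profile entries are <= 1 and the
# background is floored at 1e-3, so per-window log-odds are bounded well
# inside double range (underflow of hopeless windows to 0 is harmless).
.zoopsEStep <- function(layout, prof, background, gamma, revcomp) {
  lo <- .logOdds(prof, background)
  sF <- .scoreWindows(layout, lo)
  sR <- if (revcomp) .scoreWindows(layout, .revcompScoreMat(lo)) else NULL
  vidx <- which(!is.na(sF))
  if (!length(vidx))
    return(list(ll = 0, vidx = vidx, zF = numeric(), zR = numeric(),
                occ = rep(0, layout$nseq), Mi = rep(0L, layout$nseq)))
  vs <- layout$winseq[vidx]
  nseq <- layout$nseq
  strandFactor <- if (revcomp) 2L else 1L
  Mi <- tabulate(vs, nbins = nseq) * strandFactor
  exF <- exp(sF[vidx])
  exR <- if (revcomp) exp(sR[vidx]) else NULL
  Ai <- rep(0, nseq)
  rs <- rowsum(if (revcomp) exF + exR else exF, vs)
  Ai[as.integer(rownames(rs))] <- rs[, 1L]
  hasWin <- Mi > 0L
  denom <- rep(1, nseq)  # (1-gamma) + gamma/Mi * sum(exp(llr))
  denom[hasWin] <- (1 - gamma) + gamma * Ai[hasWin] / Mi[hasWin]
  lli <- rep(0, nseq)
  lli[hasWin] <- log(denom[hasWin])
  scale <- gamma / (Mi * denom)
  zF <- exF * scale[vs]
  zR <- if (revcomp) exR * scale[vs] else numeric()
  occ <- rep(0, nseq)
  occ[hasWin] <- pmin(1 - (1 - gamma) / denom[hasWin], 1)
  list(ll = sum(lli), vidx = vidx, zF = zF, zR = zR, occ = occ, Mi = Mi)
}

# M-step: weighted letter counts at each motif position (minus-strand
# responsibilities contribute complemented letters at mirrored positions).
.zoopsMStep <- function(layout, est, w, revcomp, pseudocount = 0.1) {
  counts <- .mstepCountsC(layout$long, est$vidx, est$zF,
                          if (revcomp) est$zR else numeric(0), w)
  dimnames(counts) <- list(.DNA_LETTERS, NULL)
  p <- counts + pseudocount
  sweep(p, 2L, colSums(p), "/")
}

# initial PWM from a seed word: matched letter 0.55, others 0.15
.seedProfile <- function(codes, w) {
  p <- matrix(0.15, nrow = 4L, ncol = w, dimnames = list(.DNA_LETTERS, NULL))
  p[cbind(codes, seq_len(w))] <- 0.55
  p
}

#' Fit one motif by EM under the ZOOPS model
#'
#' Fits a two-component finite mixture (motif vs 0-order background) to the
#' sequences, with at most one motif occurrence per sequence. The E-step
#' computes per-offset (and, with `revcomp`, reverse-strand) posterior site
#' probabilities and the per-sequence occurrence posterior; the M-step
#' re-estimates the probability columns and the occurrence prior. Iteration
#' stops when the log-likelihood-ratio improvement drops below `tol` or after
#' `maxIter` iterations. The objective is checked to be non-decreasing at
#' every step. Masked (`N`) positions contribute no likelihood and can never
#' be chosen as sites.
#'
#' Starting points: unless `start` is supplied, up to `nStarts` seed
#' subsequences are drawn (seeded RNG), each run for a few burn-in
#' iterations, and the best is continued to convergence — so the fit is
#' deterministic given `seed`.
#'
#' @param sequences a `DNAStringSet` or character vector over A,C,G,T,N.
#' @param width motif width (>= 4).
#' @param background optional length-4 background distribution (A,C,G,T);
#'   estimated from the input by default.
#' @param maxIter,tol EM stopping controls.
#' @param seed RNG seed for start selection.
#' @param revcomp scan both strands (default TRUE).
#' @param nStarts number of candidate seed subsequences tried.
#' @param start optional explicit start: a width-`width` word, a 4 x width
#'   probability matrix, or a [PWMotif-class].
#' @param accession accession assigned to the fitted motif.
#' @return A [DiscoveredMotif-class].
#' @examples
#' seqs <- rep(paste0(strrep("T", 20), "ACGTTGCAA", strrep("T", 20)), 5)
#' emZoops(seqs, width = 9, seed = 1)
#' @export
emZoops <- function(sequences, width, background = NULL, maxIter = 100,
                    tol = 1e-4, seed = 1, revcomp = TRUE, nStarts = 20,
                    start = NULL, accession = "DENOVO") {
  if (width < 4) stop("motif width must be >= 4")
  codes <- .encodeSeqs(sequences)
  usable <- vapply(codes, function(v) {
    r <- rle(!is.na(v)); any(r$values & r$lengths >= width)
  }, logical(1))
  if (sum(usable) < 2L)
    stop("need at least 2 sequences with >= ", width,
         " consecutive unmasked bases")
  if (is.null(background)) background <- .backgroundFreq(codes)
  background <- background / sum(background)
  layout <- .windowLayout(codes, width)

  # The M-step adds a pseudocount (Dirichlet regularization), so the
  # monotone EM objective is the penalized log-likelihood
  # ll + pseudo * sum(log f); that is what the trace stores and asserts.
  pseudo <- 0.1
  penalty <- function(prof) pseudo * sum(log(pmax(prof, 1e-12)))
  runEM <- function(prof, gamma, iters) {
    trace <- numeric(0)
    for (it in seq_len(iters)) {
      est <- .zoopsEStep(layout, prof, background, gamma, revcomp)
      obj <- est$ll + penalty(prof)
      if (length(trace) && obj < trace[length(trace)] - 1e-6)
        stop("EM objective decreased (", trace[length(trace)], " -> ",
             obj, ")")
      improved <- !length(trace) || obj - trace[length(trace)] >= tol
      trace <- c(trace, obj)
      prof <- .zoopsMStep(layout, est, width, revcomp, pseudocount = pseudo)
      gamma <- min(max(mean(est$occ[est$Mi > 0]), 1e-4), 1 - 1e-4)
      if (!improved && it > 1L) break
    }
    est <- .zoopsEStep(layout, prof, background, gamma, revcomp)
    list(prof = prof, gamma = gamma, ll = est$ll, est = est,
         trace = c(trace, est$ll + penalty(prof)))
  }

  # phase refinement: EM converges readily to column-shifted optima, so the
  # converged motif is re-run after +/-1 column shifts (vacated columns
  # filled with background) and the shift is adopted when it improves the
  # penalized objective
  shiftProfile <- function(prof, sh) {
    w <- ncol(prof)
    bgcol <- matrix(background, nrow = 4L,
                    dimnames = list(.DNA_LETTERS, NULL))
    if (sh > 0) cbind(bgcol, prof[, -w, drop = FALSE])
    else cbind(prof[, -1L, drop = FALSE], bgcol)
  }
  refinePhase <- function(cur) {
    objOf <- function(r) r$trace[length(r$trace)]
    for (round in 1:3) {
      cands <- lapply(c(-1L, 1L), function(sh)
        runEM(shiftProfile(cur$prof, sh), cur$gamma, maxIter))
      objs <- vapply(cands, objOf, numeric(1))
      if (max(objs) > objOf(cur) + 1e-6) cur <- cands[[which.max(objs)]]
      else break
    }
    cur
  }

  if (!is.null(start)) {
    prof0 <- if (is(start, "PWMotif")) motifMatrix(start)
             else if (is.character(start))
               .seedProfile(match(strsplit(toupper(start), "")[[1L]],
                                  .DNA_LETTERS), width)
             else as.matrix(start)
    if (ncol(prof0) != width) stop("start width does not match `width`")
    best <- runEM(prof0, 0.5, maxIter)
  } else {
    vwin <- which(!is.na(.scoreWindows(layout,
      matrix(0, 4L, width, dimnames = list(.DNA_LETTERS, NULL))))) # valid only
    if (!length(vwin)) stop("no sequence window of width ", width,
                            " free of masked bases")
    starts <- .withSeed(seed, {
      if (length(vwin) <= nStarts) vwin else sample(vwin, nStarts)
    })
    burn <- lapply(starts, function(g) {
      sc <- layout$long[g:(g + width - 1L)]
      runEM(.seedProfile(sc, width), 0.5, 3L)
    })
    # run the best few burned starts to convergence (different starts often
    # settle in different phases of the same motif), keep the best, then
    # phase-refine the winner
    burnObj <- vapply(burn, function(b) b$trace[length(b$trace)], numeric(1))
    top <- order(burnObj, decreasing = TRUE)[seq_len(min(3L, length(burn)))]
    finals <- lapply(top, function(i)
      runEM(burn[[i]]$prof, burn[[i]]$gamma, maxIter))
    objs <- vapply(finals, function(b) b$trace[length(b$trace)], numeric(1))
    # phase-refine the two best convergence points and keep the overall best
    refined <- lapply(order(objs, decreasing = TRUE)[seq_len(min(
      2L, length(finals)))], function(i) refinePhase(finals[[i]]))
    robjs <- vapply(refined, function(b) b$trace[length(b$trace)],
                    numeric(1))
    best <- refined[[which.max(robjs)]]
  }

  # per-sequence maximum-posterior site table
  est <- best$est
  nseq <- layout$nseq
  sites <- data.frame(seq = seq_len(nseq), offset = NA_integer_,
                      strand = NA_character_, posterior = 0,
                      occupancy = est$occ)
  if (length(est$vidx)) {
    vs <- layout$winseq[est$vidx]
    vp <- layout$winpos[est$vidx]
    # a window's site posterior sums both strand responsibilities (for a
    # palindromic motif the mass splits evenly between strands)
    zmax <- if (revcomp) est$zF + est$zR else est$zF
    strnd <- if (revcomp) ifelse(est$zF >= est$zR, "+", "-")
             else rep("+", length(est$zF))
    ord <- order(vs, -zmax)
    first <- !duplicated(vs[ord])
    pick <- ord[first]
    sites$offset[vs[pick]] <- vp[pick]
    sites$strand[vs[pick]] <- strnd[pick]
    sites$posterior[vs[pick]] <- zmax[pick]
  }
  new("DiscoveredMotif",
      motif = PWMotif(best$prof, accession = accession),
      llr = best$ll, eValue = NA_real_, occPrior = best$gamma,
      sites = sites, llTrace = best$trace,
      background = unname(background))
}

# ---- dinucleotide shuffle (Altschul-Erickson) -------------------------------

# Shuffle one integer code vector preserving exact dinucleotide counts
# (N treated as a 5th symbol, so masked-boundary structure is preserved).
.dinucShuffleCodes <- function(v) {
  x <- ifelse(is.na(v), 5L, v)
  out <- .eulerShuffleC(as.integer(x))
  ifelse(out == 5L, NA_integer_, out)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random shuffle of each sequence that exactly preserves its dinucleotide
#' (1st-order) composition, via the Altschul--Erickson Eulerian-path
#' construction. Masked `N` bases are treated as a fifth symbol so masked-run
#' boundaries are preserved too.
#'
#' @param sequences `DNAStringSet` or character vector.
#' @param seed RNG seed.
#' @return character vector of shuffled sequences.
#' @export
dinucleotideShuffle <- function(sequences, seed = 1) {
  codes <- .encodeSeqs(sequences)
  .withSeed(seed, vapply(codes, function(v) {
    s <- .dinucShuffleCodes(v)
    paste(ifelse(is.na(s), "N", .DNA_LETTERS[s]), collapse = "")
  }, character(1)))
}

#' Monte-Carlo E-value of a fitted motif
#'
#' Calibrates the motif's ZOOPS log-likelihood ratio against
#' dinucleotide-shuffled copies of the training sequences: the fitted PWM and
#' occurrence prior are re-scored (one E-step evaluation, no refit) on each
#' shuffled set, and
#' `E = (1 + #\{shuffled LLR >= observed\}) / (nShuffles + 1) * nWidths`,
#' where `nWidths` is the number of candidate widths searched (a Bonferroni
#' factor for the width selection). The attainable floor is
#' `nWidths / (nShuffles + 1)`; deterministic given `seed`.
#'
#' @param dm a [DiscoveredMotif-class] fitted on `sequences`.
#' @param sequences the training sequences.
#' @param nShuffles number of shuffled replicates (default 20, >= 1).
#' @param seed RNG seed.
#' @param nWidths width-grid multiplicity (default 1).
#' @param revcomp both-strand scoring, as in the fit.
#' @return the E-value (positive real).
#' @export
motifEValue <- function(dm, sequences, nShuffles = 20, seed = 1,
                        nWidths = 1, revcomp = TRUE) {
  if (nShuffles < 1) stop("nShuffles must be >= 1")
  prof <- motifMatrix(motifPWM(dm))
  w <- ncol(prof)
  obs <- dm@llr
  bg <- dm@background
  exceed <- 0L
  for (r in seq_len(nShuffles)) {
    sh <- dinucleotideShuffle(sequences, seed = .deriveSeed(seed, r))
    lay <- .windowLayout(.encodeSeqs(sh), w)
    ll <- .zoopsEStep(lay, prof, bg, dm@occPrior, revcomp)$ll
    if (ll >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (nShuffles + 1) * nWidths
}

#' Sequential de novo motif discovery
#'
#' Extracts up to `nMotifs` motifs: for each, EM is run over a grid of
#' candidate widths (default `{6, 8, 10, 12, 15}`, bounded by `maxWidth`),
#' the width with the best (lowest) Monte-Carlo E-value is kept (ties broken
#' by higher log-likelihood ratio), and the maximum-posterior site per
#' sequence (posterior > 0.5) is hard-masked to `N` before the next round.
#' The returned list is sorted by E-value ascending. If fewer motifs remain
#' discoverable than requested (too little unmasked sequence), a shorter list
#' is returned with a message.
#'
#' The `nShuffles` dinucleotide-shuffled calibration replicates are
#' generated once per run from the input sequences and shared across widths
#' and motif rounds (deterministic given `seed`); see [motifEValue()] for
#' the E-value definition.
#'
#' @inheritParams emZoops
#' @param nMotifs number of motifs to extract (default 30).
#' @param widths candidate width grid.
#' @param maxWidth maximum motif width (default 15).
#' @param nShuffles shuffled replicates per E-value.
#' @return list of [DiscoveredMotif-class], accessions `DENOVO_01`, ...
#' @export
discoverMotifs <- function(sequences, nMotifs = 30,
                           widths = c(6, 8, 10, 12, 15), maxWidth = 15,
                           revcomp = TRUE, seed = 1, nStarts = 20,
                           maxIter = 50, tol = 1e-3, nShuffles = 20,
                           background = NULL) {
  if (nMotifs == 0) return(list())
  widths <- widths[widths <= maxWidth]
  if (!length(widths)) stop("no candidate widths <= maxWidth")
  seqs <- toupper(as.character(sequences))
  nm <- names(sequences)
  codes0 <- .encodeSeqs(seqs)
  if (is.null(background)) background <- .backgroundFreq(codes0)
  shuffles <- lapply(seq_len(nShuffles), function(r)
    .withSeed(.deriveSeed(seed, 7L, r), lapply(codes0, .dinucShuffleCodes)))
  layCache <- new.env(parent = emptyenv())
  evalOnShuffles <- function(dm) {
    w <- motifWidth(motifPWM(dm))
    key <- as.character(w)
    lays <- layCache[[key]]
    if (is.null(lays)) {
      lays <- lapply(shuffles, .windowLayout, w = w)
      layCache[[key]] <- lays
    }
    prof <- motifMatrix(motifPWM(dm))
    exceed <- sum(vapply(lays, function(l)
      .zoopsEStep(l, prof, dm@background, dm@occPrior, revcomp)$ll >=
        dm@llr, logical(1)))
    (1 + exceed) / (nShuffles + 1) * length(widths)
  }
  out <- list()
  for (m in seq_len(nMotifs)) {
    usable <- vapply(.encodeSeqs(seqs), function(v) {
      r <- rle(!is.na(v)); any(r$values & r$lengths >= min(widths))
    }, logical(1))
    if (sum(usable) < 2L) {
      message("stopping after ", length(out),
              " motifs: not enough unmasked sequence left")
      break
    }
    cand <- list()
    for (wi in seq_along(widths)) {
      w <- widths[wi]
      dm <- tryCatch(
        emZoops(seqs, width = w, background = background,
                maxIter = maxIter, tol = tol,
                seed = .deriveSeed(seed, m, wi), revcomp = revcomp,
                nStarts = nStarts,
                accession = sprintf("DENOVO_%02d", m)),
        error = function(e) NULL)
      if (is.null(dm)) next
      dm@eValue <- evalOnShuffles(dm)
      cand[[length(cand) + 1L]] <- dm
    }
    if (!length(cand)) {
      message("stopping after ", length(out),
              " motifs: no width fit succeeded")
      break
    }
    evs <- vapply(cand, motifEValueOf, numeric(1))
    llrs <- vapply(cand, motifLLR, numeric(1))
    best <- cand[[order(evs, -llrs)[1L]]]
    out[[length(out) + 1L]] <- best
    # erase: hard-mask the best site per sequence where posterior > 0.5
    st <- motifSites(best)
    w <- motifWidth(motifPWM(best))
    hit <- which(st$posterior > 0.5 & !is.na(st$offset))
    if (!length(hit)) {
      message("stopping after ", length(out),
              " motifs: no confident sites left to erase")
      break
    }
    for (i in hit) {
      s <- seqs[st$seq[i]]
      substr(s, st$offset[i], st$offset[i] + w - 1L) <-
        strrep("N", w)
      seqs[st$seq[i]] <- s
    }
  }
  ord <- order(vapply(out, motifEValueOf, numeric(1)),
               -vapply(out, motifLLR, numeric(1)))
  out <- out[ord]
  if (!is.null(nm)) out <- lapply(out, function(d) {
    d@sites$seq_name <- nm[d@sites$seq]; d
  })
  out
}
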