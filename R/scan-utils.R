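# Internal sequence encoding and PWM window-scanning machinery shared by the
# discovery, TCS and affinity engines. Sequences are encoded as integer codes
# (A=1, C=2, G=3, T=4, anything else NA) and concatenated with NA spacers so
# that one vectorized pass scores every window of every sequence; windows that
# touch an NA (masked base or spacer) score NA and are treated as invalid —
# they contribute no likelihood and can never be chosen as sites.

.DNA_LETTERS <- c("A", "C", "G", "T")
.DNA_COMPLEMENT <- c(4L, 3L, 2L, 1L)

# character vector or DNAStringSet -> list of integer code vectors
.encodeSeqs <- function(seqs) {
  x <- toupper(as.character(seqs))
  out <- lapply(strsplit(x, "", fixed = TRUE),
                function(ch) match(ch, .DNA_LETTERS))
  names(out) <- names(x)
  out
}

# 0-order background composition of a sequence set (masked bases ignored),
# floored at 1e-3 and renormalized so log-odds stay finite.
.backgroundFreq <- function(codes) {
  tab <- tabulate(unlist(codes, use.names = FALSE), nbins = 4L)
  if (sum(tab) == 0) tab <- rep(1L, 4L)
  b <- tab / sum(tab)
  b <- pmax(b, 1e-3)
  b <- b / sum(b)
  names(b) <- .DNA_LETTERS
  b
}

# Concatenate code vectors with w NA spacers; precompute the window->sequence
# map for a given width. Window g starts at position g of `long`.
.windowLayout <- function(codes, w) {
  lens <- lengths(codes)
  pad <- rep(NA_integer_, w)
  long <- unlist(lapply(codes, function(v) c(v, pad)), use.names = FALSE)
  offsets <- cumsum(c(0L, utils::head(lens + w, -1L)))
  nw <- length(long) - w + 1L
  counts <- pmax(lens - w + 1L, 0L)
  winseq <- rep(NA_integer_, nw)
  winpos <- rep(NA_integer_, nw)
  idx <- unlist(mapply(function(o, k) if (k > 0) o + seq_len(k) else integer(),
                       offsets, counts, SIMPLIFY = FALSE), use.names = FALSE)
  winseq[idx] <- rep.int(seq_along(codes), counts)
  winpos[idx] <- unlist(lapply(counts, seq_len), use.names = FALSE)
  list(long = long, nw = nw, winseq = winseq, winpos = winpos,
       nseq = length(codes), lens = lens)
}

# Score every window of the layout under a 4 x w score matrix (e.g. log-odds).
# Returns a length-nw vector; NA marks invalid windows.
.scoreWindows <- function(layout, scoreMat) {
  .scoreWindowsC(layout$long, scoreMat)
}

# Reverse-strand score matrix: a minus-strand site at a forward window means
# the reverse complement of that window matches the motif.
.revcompScoreMat <- function(scoreMat) {
  scoreMat[4:1, rev(seq_len(ncol(scoreMat))), drop = FALSE]
}

.logOdds <- function(profile, background) {
  log(pmax(profile, 1e-12)) - log(background)
}

# Per-window log-odds scores on both strands for one PWM over a sequence set.
# Returns list(layout, fwd, rev); rev is NULL when bothStrands = FALSE.
.scanPWM <- function(codes, pwm, background, bothStrands = TRUE,
                     layout = NULL) {
  prof <- if (is(pwm, "PWMotif")) motifMatrix(pwm) else as.matrix(pwm)
  w <- ncol(prof)
  if (is.null(layout)) layout <- .windowLayout(codes, w)
  lo <- .logOdds(prof, background)
  fwd <- .scoreWindows(layout, lo)
  rev <- if (bothStrands) .scoreWindows(layout, .revcompScoreMat(lo)) else NULL
  list(layout = layout, fwd = fwd, rev = rev, width = w)
}

# run a block of code with a local, restored RNG state
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# small deterministic seed derivation that stays inside 32-bit integer range
.deriveSeed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(c(...)))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}
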