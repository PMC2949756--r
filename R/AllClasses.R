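#' Position weight matrix with library metadata
#'
#' A `PWMotif` holds a column-stochastic 4 x w nucleotide probability matrix
#' (rows A, C, G, T) together with a matrix accession and the profile-TF name
#' it is annotated with (empty for de novo motifs).
#'
#' @slot accession character(1); library accession (e.g. a TRANSFAC-style
#'   `M00062`) or an auto-assigned de novo identifier.
#' @slot tfName character(1); profile TF name, possibly `""`.
#' @slot profile numeric matrix, 4 rows named A,C,G,T; every column sums to 1
#'   within 1e-6 and all entries are non-negative.
#'
#' @seealso [pwmFromCounts()], [wordPWM()], [readPWMLibrary()]
#' @export
setClass("PWMotif",
  representation(accession = "character", tfName = "character",
                 profile = "matrix"))

setValidity("PWMotif", function(object) {
  p <- object@profile
  msg <- character()
  if (!is.numeric(p) || nrow(p) != 4L)
    msg <- c(msg, "profile must be a numeric matrix with 4 rows (A,C,G,T)")
  else {
    if (!identical(rownames(p), c("A", "C", "G", "T")))
      msg <- c(msg, "profile rows must be named A,C,G,T")
    if (ncol(p) < 2L)
      msg <- c(msg, "profile must have at least 2 columns")
    if (any(p < -1e-12))
      msg <- c(msg, "profile probabilities must be non-negative")
    cs <- colSums(p)
    if (any(abs(cs - 1) > 1e-6))
      msg <- c(msg, "every profile column must sum to 1 (within 1e-6)")
  }
  if (length(object@accession) != 1L || length(object@tfName) != 1L)
    msg <- c(msg, "accession and tfName must be length-1 character")
  if (length(msg)) msg else TRUE
})

#' Construct a PWMotif
#'
#' @param profile 4 x w numeric matrix of column probabilities, rows in
#'   A,C,G,T order (row names are set if absent).
#' @param accession accession string; `""` for anonymous motifs.
#' @param tfName profile TF name; `""` when unannotated.
#' @return A validated [PWMotif-class] object.
#' @examples
#' m <- matrix(c(.97,.01,.01,.01, .01,.97,.01,.01), nrow = 4)
#' PWMotif(m, accession = "M1", tfName = "TFX")
#' @export
PWMotif <- function(profile, accession = "", tfName = "") {
  profile <- as.matrix(profile)
  if (is.null(rownames(profile)) && nrow(profile) == 4L)
    rownames(profile) <- c("A", "C", "G", "T")
  new("PWMotif", accession = as.character(accession),
      tfName = as.character(tfName), profile = profile)
}

#' Build a PWMotif from a count matrix
#'
#' Counts are converted to probabilities after adding `pseudocount` to every
#' cell. A column with zero total count (before pseudocount) is an error: it
#' carries no information and signals a malformed matrix block.
#'
#' @param counts 4 x w matrix of non-negative counts (rows A,C,G,T).
#' @param pseudocount added to each cell before normalization (default 0.5).
#' @inheritParams PWMotif
#' @return A [PWMotif-class].
#' @export
pwmFromCounts <- function(counts, accession = "", tfName = "",
                          pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("count matrix must have 4 rows (A,C,G,T)")
  if (any(colSums(counts) <= 0))
    stop("PWM column with zero total count in '", accession, "'")
  p <- counts + pseudocount
  p <- sweep(p, 2L, colSums(p), "/")
  PWMotif(p, accession = accession, tfName = tfName)
}

#' Convert a DNA word into a near-deterministic PWMotif
#'
#' Each position puts probability `1 - 3 * eps` on the word's letter. Used to
#' treat fixed-size words (the TCS engine's default motif universe) with the
#' PWM machinery.
#'
#' @param word character(1) over A,C,G,T.
#' @param eps per-off-letter probability (default 0.001).
#' @inheritParams PWMotif
#' @return A [PWMotif-class].
#' @export
wordPWM <- function(word, accession = word, tfName = "", eps = 0.001) {
  ch <- strsplit(toupper(word), "", fixed = TRUE)[[1L]]
  code <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(code)) stop("word must contain only A,C,G,T: ", word)
  p <- matrix(eps, nrow = 4L, ncol = length(code),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p[cbind(code, seq_along(code))] <- 1 - 3 * eps
  PWMotif(p, accession = accession, tfName = tfName)
}

#' @describeIn PWMotif-class accession string
#' @param object,x a `PWMotif`
#' @export
setGeneric("accession", function(object) standardGeneric("accession"))
#' @rdname PWMotif-class
#' @export
setMethod("accession", "PWMotif", function(object) object@accession)

#' @describeIn PWMotif-class profile TF name
#' @export
setGeneric("tfName", function(object) standardGeneric("tfName"))
#' @rdname PWMotif-class
#' @export
setMethod("tfName", "PWMotif", function(object) object@tfName)

#' @describeIn PWMotif-class motif width (number of columns)
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))
#' @rdname PWMotif-class
#' @export
setMethod("motifWidth", "PWMotif", function(object) ncol(object@profile))

#' @describeIn PWMotif-class the 4 x w probability matrix
#' @export
setGeneric("motifMatrix", function(object) standardGeneric("motifMatrix"))
#' @rdname PWMotif-class
#' @export
setMethod("motifMatrix", "PWMotif", function(object) object@profile)

#' @describeIn PWMotif-class per-column argmax consensus string
#' @export
setGeneric("motifConsensus", function(object) standardGeneric("motifConsensus"))
#' @rdname PWMotif-class
#' @export
setMethod("motifConsensus", "PWMotif", function(object) {
  paste(c("A", "C", "G", "T")[apply(object@profile, 2L, which.max)],
        collapse = "")
})

#' @describeIn PWMotif-class information content (bits) summed over columns
#' @export
setGeneric("informationContent",
           function(object) standardGeneric("informationContent"))
#' @rdname PWMotif-class
#' @export
setMethod("informationContent", "PWMotif", function(object) {
  p <- object@profile
  sum(ifelse(p > 0, p * log2(p), 0)) + 2 * ncol(p)
})

#' @rdname PWMotif-class
#' @param ... ignored
#' @export
setMethod("reverseComplement", "PWMotif", function(x, ...) {
  p <- x@profile[4:1, rev(seq_len(ncol(x@profile))), drop = FALSE]
  rownames(p) <- c("A", "C", "G", "T")
  PWMotif(p, accession = x@accession, tfName = x@tfName)
})

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif ", if (nzchar(object@accession)) object@accession else "<anon>",
      if (nzchar(object@tfName)) paste0(" (", object@tfName, ")") else "",
      "  width=", ncol(object@profile),
      "  consensus=", motifConsensus(object),
      "  IC=", sprintf("%.2f", informationContent(object)), " bits\n",
      sep = "")
})

#' A de novo motif discovered by EM under the ZOOPS model
#'
#' @slot motif the fitted [PWMotif-class].
#' @slot llr final ZOOPS log-likelihood ratio of the mixture model over the
#'   background-only model on the training sequences.
#' @slot eValue Monte-Carlo E-value from dinucleotide-shuffle calibration
#'   (`NA` until computed; see [motifEValue()]).
#' @slot occPrior fitted per-sequence occurrence prior (the ZOOPS gamma).
#' @slot sites data.frame with one row per sequence: `seq`, `offset`,
#'   `strand`, `posterior` (the maximum-posterior site; `NA` offset when the
#'   no-site component dominates), and `occupancy`, the per-sequence
#'   occurrence posterior.
#' @slot llTrace per-iteration trace of the penalized (Dirichlet-regularized)
#'   EM objective; non-decreasing.
#' @slot background length-4 background letter distribution used in the fit.
#' @export
setClass("DiscoveredMotif",
  representation(motif = "PWMotif", llr = "numeric", eValue = "numeric",
                 occPrior = "numeric", sites = "data.frame",
                 llTrace = "numeric", background = "numeric"))

setValidity("DiscoveredMotif", function(object) {
  msg <- character()
  st <- object@sites
  if (nrow(st) &&
      (any(st$posterior < -1e-9 | st$posterior > 1 + 1e-9, na.rm = TRUE) ||
       any(st$occupancy < -1e-9 | st$occupancy > 1 + 1e-9, na.rm = TRUE)))
    msg <- c(msg, "site posteriors must lie in [0, 1]")
  if (length(object@occPrior) != 1L ||
      object@occPrior < 0 || object@occPrior > 1)
    msg <- c(msg, "occPrior must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn DiscoveredMotif-class the fitted PWMotif
#' @param object a `DiscoveredMotif`
#' @export
setGeneric("motifPWM", function(object) standardGeneric("motifPWM"))
#' @rdname DiscoveredMotif-class
#' @export
setMethod("motifPWM", "DiscoveredMotif", function(object) object@motif)

#' @describeIn DiscoveredMotif-class per-sequence best-site table
#' @export
setGeneric("motifSites", function(object) standardGeneric("motifSites"))
#' @rdname DiscoveredMotif-class
#' @export
setMethod("motifSites", "DiscoveredMotif", function(object) object@sites)

#' @describeIn DiscoveredMotif-class log-likelihood ratio of the fit
#' @export
setGeneric("motifLLR", function(object) standardGeneric("motifLLR"))
#' @rdname DiscoveredMotif-class
#' @export
setMethod("motifLLR", "DiscoveredMotif", function(object) object@llr)

#' @describeIn DiscoveredMotif-class Monte-Carlo E-value (NA until computed)
#' @export
setGeneric("motifEValueOf", function(object) standardGeneric("motifEValueOf"))
#' @rdname DiscoveredMotif-class
#' @export
setMethod("motifEValueOf", "DiscoveredMotif", function(object) object@eValue)

setMethod("show", "DiscoveredMotif", function(object) {
  cat("DiscoveredMotif ", accession(object@motif),
      "  width=", motifWidth(object@motif),
      "  consensus=", motifConsensus(object@motif),
      "  llr=", sprintf("%.2f", object@llr),
      "  gamma=", sprintf("%.3f", object@occPrior),
      "  E=", if (is.na(object@eValue)) "NA" else
        format(object@eValue, digits = 3),
      "  sites(p>0.5)=", sum(object@sites$posterior > 0.5, na.rm = TRUE),
      "\n", sep = "")
})
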