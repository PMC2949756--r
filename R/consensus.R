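# Cross-engine consensus: per-engine top-70% selection, mapping of de novo
# motifs to library accessions by an ungapped column-correlation comparator,
# the three-way accession intersection, and the test-vs-random score
# contrast table.

.ENGINE_ORIENTATION <- c(discovery = "lower_better", tcs = "higher_better",
                         affinity = "lower_better")

#' Retain the best fraction of an engine's predictions
#'
#' Keeps the best `ceiling(fraction * n)` predictions by score in the
#' engine's orientation; every prediction tied with the boundary score is
#' also retained (inclusive tie rule).
#'
#' @param predictions data.frame with a `score` column (and any id columns).
#' @param fraction fraction to retain, in `(0, 1]` (default 0.70).
#' @param orientation `"lower_better"` (E-values, p-values) or
#'   `"higher_better"` (TCS).
#' @return the retained rows, sorted best-first.
#' @examples
#' df <- data.frame(id = letters[1:10], score = 1:10)
#' nrow(topFraction(df, 0.7))  # 7
#' @export
topFraction <- function(predictions, fraction = 0.70,
                        orientation = c("lower_better", "higher_better")) {
  orientation <- match.arg(orientation)
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(predictions)
  if (!n) return(predictions)
  s <- predictions$score
  if (is.null(s)) stop("predictions must have a 'score' column")
  ord <- if (orientation == "lower_better") order(s) else order(-s)
  m <- ceiling(fraction * n)
  cutoff <- s[ord[m]]
  keep <- if (orientation == "lower_better") s <= cutoff else s >= cutoff
  out <- predictions[ord[keep[ord]], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# mean Pearson correlation of aligned probability columns at one offset;
# zero-variance (e.g. uniform) columns contribute 0
.alignmentSimilarity <- function(q, l, shift, minOverlap) {
  wq <- ncol(q); wl <- ncol(l)
  qs <- max(1L, 1L - shift); qe <- min(wq, wl - shift)
  if (qe - qs + 1L < minOverlap) return(NA_real_)
  cols <- qs:qe
  sims <- vapply(cols, function(jq) {
    a <- q[, jq]; b <- l[, jq + shift]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  }, numeric(1))
  mean(sims)
}

#' Match a PWM against a matrix library (TOMTOM-like)
#'
#' Slides the query over every library matrix in both orientations; at each
#' offset with at least `minOverlap` aligned columns the similarity is the
#' mean Pearson correlation of the aligned probability columns (uniform
#' columns contribute 0). The best library hit is returned iff its similarity
#' reaches `threshold`; ties are broken by accession (lexicographic). Absence
#' of a match is a value (`NULL`), not an error.
#'
#' @param query a [PWMotif-class].
#' @param library list of [PWMotif-class].
#' @param minOverlap minimum aligned columns (default 4).
#' @param threshold similarity threshold (default 0.75).
#' @return `NULL` or a list with `accession`, `tf_name`, `similarity`,
#'   `orientation` (`"+"`/`"-"`), `offset`.
#' @export
matchPWMToLibrary <- function(query, library, minOverlap = 4,
                              threshold = 0.75) {
  if (!length(library)) stop("library must be non-empty")
  q <- motifMatrix(query)
  qr <- motifMatrix(reverseComplement(query))
  best <- NULL
  accs <- vapply(library, accession, character(1))
  for (li in order(accs)) {
    l <- motifMatrix(library[[li]])
    for (ori in c("+", "-")) {
      qq <- if (ori == "+") q else qr
      for (shift in (minOverlap - ncol(qq)):(ncol(l) - minOverlap)) {
        sim <- .alignmentSimilarity(qq, l, shift, minOverlap)
        if (!is.na(sim) && (is.null(best) || sim > best$similarity)) {
          best <- list(accession = accs[li],
                       tf_name = tfName(library[[li]]),
                       similarity = sim, orientation = ori, offset = shift)
        }
      }
    }
  }
  if (is.null(best) || best$similarity < threshold) return(NULL)
  best
}

#' Map de novo discovery output to library accessions
#'
#' Applies [matchPWMToLibrary()] to each discovered motif; unmatched motifs
#' keep `accession = NA` (and are dropped, with a message, by
#' [intersectEngines()]). De novo motifs mapping to the same accession are
#' merged keeping the best (lowest) E-value.
#'
#' @param discovered list of [DiscoveredMotif-class].
#' @inheritParams matchPWMToLibrary
#' @return data.frame `denovo`, `accession`, `tf_name`, `similarity`,
#'   `score` (the E-value).
#' @export
mapDiscoveryToLibrary <- function(discovered, library, minOverlap = 4,
                                  threshold = 0.75) {
  rows <- lapply(discovered, function(d) {
    hit <- matchPWMToLibrary(motifPWM(d), library, minOverlap = minOverlap,
                             threshold = threshold)
    data.frame(denovo = accession(motifPWM(d)),
               accession = if (is.null(hit)) NA_character_ else hit$accession,
               tf_name = if (is.null(hit)) NA_character_ else hit$tf_name,
               similarity = if (is.null(hit)) NA_real_ else hit$similarity,
               score = motifEValueOf(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(denovo = character(), accession = character(),
                      tf_name = character(), similarity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  mapped <- out[!is.na(out$accession), , drop = FALSE]
  mapped <- mapped[order(mapped$accession, mapped$score), , drop = FALSE]
  merged <- mapped[!duplicated(mapped$accession), , drop = FALSE]
  unmapped <- out[is.na(out$accession), , drop = FALSE]
  res <- rbind(merged, unmapped)
  rownames(res) <- NULL
  res[order(res$score), , drop = FALSE]
}

#' Intersect the three engines' retained predictions
#'
#' Accessions present in all three retained sets qualify; per-engine scores
#' are attached. Predictions without an accession (unmapped de novo motifs)
#' are dropped with a message.
#'
#' @param discovery,tcs,affinity retained prediction data.frames (after
#'   [topFraction()]), each with `accession` and `score` columns.
#' @param library optional list of [PWMotif-class] used to fill `tf_name`.
#' @return data.frame `accession`, `tf_name`, `score_discovery`,
#'   `score_tcs`, `score_affinity`, sorted by accession.
#' @export
intersectEngines <- function(discovery, tcs, affinity, library = NULL) {
  sets <- list(discovery = discovery, tcs = tcs, affinity = affinity)
  sets <- lapply(names(sets), function(en) {
    df <- sets[[en]]
    if (!nrow(df)) return(df)
    if (is.null(df$accession))
      stop("engine '", en, "' predictions lack an accession column")
    drop <- is.na(df$accession)
    if (any(drop))
      message(sum(drop), " unmapped prediction(s) dropped from '", en, "'")
    df[!drop, , drop = FALSE]
  })
  names(sets) <- c("discovery", "tcs", "affinity")
  common <- Reduce(intersect, lapply(sets, function(df) df$accession))
  common <- sort(common)
  tf <- rep("", length(common))
  if (!is.null(library) && length(common)) {
    accs <- vapply(library, accession, character(1))
    hit <- match(common, accs)
    tf[!is.na(hit)] <- vapply(library[hit[!is.na(hit)]], tfName, character(1))
  }
  getScore <- function(df, acc) df$score[match(acc, df$accession)]
  data.frame(accession = common, tf_name = tf,
             score_discovery = getScore(sets$discovery, common),
             score_tcs = getScore(sets$tcs, common),
             score_affinity = getScore(sets$affinity, common),
             stringsAsFactors = FALSE)
}

#' Test-vs-random score contrast for consensus motifs
#'
#' For each consensus accession and engine, pairs the score obtained on the
#' test gene set with the score from the random-gene companion run executed
#' under the identical engine configuration. When the engine did not retain
#' the accession on the random data, the random side is marked absent.
#'
#' @param consensus data.frame from [intersectEngines()] (test run).
#' @param testRetained,randomRetained named lists (`discovery`, `tcs`,
#'   `affinity`) of retained prediction data.frames from the test and random
#'   runs. Both lists must name the same engines.
#' @return data.frame `accession`, `engine`, `test_score`, `random_score`,
#'   `better` (`"test"`, `"random"`, `"tie"`, `"absent"`).
#' @export
contrastTestVsRandom <- function(consensus, testRetained, randomRetained) {
  engines <- names(testRetained)
  if (!setequal(engines, names(randomRetained)))
    stop("test and random runs cover different engines (config mismatch)")
  rows <- list()
  for (acc in consensus$accession) {
    for (en in engines) {
      ori <- .ENGINE_ORIENTATION[[en]]
      ts <- testRetained[[en]]$score[match(acc, testRetained[[en]]$accession)]
      rs <- randomRetained[[en]]$score[
        match(acc, randomRetained[[en]]$accession)]
      better <- if (is.na(rs)) "absent"
        else if (isTRUE(all.equal(ts, rs))) "tie"
        else if ((ori == "lower_better") == (ts < rs)) "test" else "random"
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, engine = en, test_score = ts, random_score = rs,
        better = better, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(), engine = character(),
                      test_score = numeric(), random_score = numeric(),
                      better = character(), stringsAsFactors = FALSE)
  out
}
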