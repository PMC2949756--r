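#' Per-condition average intensities
#'
#' Arithmetic mean of replicate intensities per condition for every probe.
#'
#' @param se a `SummarizedExperiment` from [readExpressionMatrix()].
#' @param conditions which conditions to average (default: all declared).
#' @return numeric matrix, probes x conditions.
#' @export
conditionAverages <- function(se, conditions = unique(colData(se)$condition)) {
  out <- vapply(conditions,
                function(cc) rowMeans(conditionIntensities(se, cc)),
                numeric(nrow(se)))
  if (nrow(se) == 1L)
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(se), conditions))
  out
}

#' Welch's unequal-variance two-tailed t-test
#'
#' Two-sided p-value from the t statistic with Welch--Satterthwaite degrees
#' of freedom. Degenerate limits follow fixed conventions: when both groups
#' have zero variance, identical means give p = 1 (t = 0) and distinct means
#' give p = 0 (the t -> Inf limit); when exactly one group has zero variance
#' the ordinary formula applies (its variance term is 0).
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return two-tailed p-value in `[0, 1]`.
#' @examples
#' welchTTest(c(1, 3), c(6, 8))  # ~ 0.0715
#' @export
welchTTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (anyNA(a) || anyNA(b)) stop("missing values in t-test input")
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  sa <- va / na; sb <- vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Classify probes into pro-inflammatory / antibacterial / unclassified
#'
#' Implements the three-condition filtering paradigm. With per-probe
#' condition averages `X = N_avg`, `Y = (N+L)_avg`, `Z = (T+L)_avg` and
#' ratios `r1 = Y/X`, `r2 = Z/Y`:
#' \itemize{
#'   \item pro-inflammatory (tolerizable): `r1 > 1`, `r2 < 1`, p < alpha;
#'   \item antibacterial (non-tolerizable): `r1 > 1`, `r2 > 1` (strict),
#'     p < alpha;
#'   \item otherwise unclassified.
#' }
#' The p-value is Welch's two-tailed t-test between the naive and tolerant
#' replicate groups — N vs T+L by default, optionally N vs N+L. Probes whose
#' ratio denominators are zero are unclassified with a recorded reason. No
#' multiple-testing correction is applied by default (`adjust = "none"`); a
#' Benjamini--Hochberg option exists.
#'
#' @param se a `SummarizedExperiment` with N, NL, TL conditions.
#' @param alpha significance threshold, default 0.05.
#' @param contrast which replicate groups the t-test compares.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `PhenotypeCalls`: a list with `calls` (per-probe
#'   data.frame: `probe_id`, `gene_symbol`, `n_avg`, `nl_avg`, `tl_avg`,
#'   `r1`, `r2`, `p_value`, `label`, `reason`), symbol-collapsed gene sets
#'   `proGenes` / `antiGenes`, probe-level sets `proProbes` / `antiProbes`,
#'   and the parameters used.
#' @export
classifyGenes <- function(se, alpha = 0.05,
                          contrast = c("N_vs_TL", "N_vs_NL"),
                          adjust = c("none", "BH")) {
  contrast <- match.arg(contrast)
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(se) == 0L) {
    calls <- data.frame(probe_id = character(), gene_symbol = character(),
                        n_avg = numeric(), nl_avg = numeric(),
                        tl_avg = numeric(), r1 = numeric(), r2 = numeric(),
                        p_value = numeric(), label = character(),
                        reason = character(), stringsAsFactors = FALSE)
    return(structure(list(calls = calls, proGenes = character(),
                          antiGenes = character(), proProbes = character(),
                          antiProbes = character(), alpha = alpha,
                          contrast = contrast),
                     class = "PhenotypeCalls"))
  }
  av <- conditionAverages(se, c("N", "NL", "TL"))
  nMat <- conditionIntensities(se, "N")
  otherMat <- conditionIntensities(se, if (contrast == "N_vs_TL") "TL" else "NL")
  p <- vapply(seq_len(nrow(se)),
              function(i) welchTTest(nMat[i, ], otherMat[i, ]),
              numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  r1 <- ifelse(av[, "N"] > 0, av[, "NL"] / av[, "N"], NA_real_)
  r2 <- ifelse(av[, "NL"] > 0, av[, "TL"] / av[, "NL"], NA_real_)
  label <- rep("unclassified", nrow(se))
  reason <- rep("", nrow(se))
  zero <- is.na(r1) | is.na(r2)
  reason[zero] <- "zero denominator"
  ok <- !zero & p < alpha
  label[ok & r1 > 1 & r2 < 1] <- "pro_inflammatory"
  label[ok & r1 > 1 & r2 > 1] <- "antibacterial"
  reason[label == "unclassified" & !zero] <- "filter not met"
  calls <- data.frame(probe_id = rowData(se)$probe_id,
                      gene_symbol = rowData(se)$gene_symbol,
                      n_avg = unname(av[, "N"]), nl_avg = unname(av[, "NL"]),
                      tl_avg = unname(av[, "TL"]),
                      r1 = unname(r1), r2 = unname(r2), p_value = unname(p),
                      label = label, reason = reason,
                      stringsAsFactors = FALSE)
  collapseSet <- function(lab) {
    idx <- which(label == lab & rowData(se)$annotated)
    if (!length(idx)) return(character())
    key <- toupper(trimws(calls$gene_symbol[idx]))
    means <- rowMeans(assay(se, "intensity"))[idx]
    keep <- idx[order(key, -means)][!duplicated(sort(key))]
    sym <- calls$gene_symbol[keep]
    sym[order(toupper(sym))]
  }
  structure(list(calls = calls,
                 proGenes = collapseSet("pro_inflammatory"),
                 antiGenes = collapseSet("antibacterial"),
                 proProbes = calls$probe_id[label == "pro_inflammatory"],
                 antiProbes = calls$probe_id[label == "antibacterial"],
                 alpha = alpha, contrast = contrast),
            class = "PhenotypeCalls")
}

#' @export
print.PhenotypeCalls <- function(x, ...) {
  cat("PhenotypeCalls:", nrow(x$calls), "probes; alpha =", x$alpha,
      "; contrast =", x$contrast, "\n")
  cat("  pro-inflammatory:", length(x$proProbes), "probes /",
      length(x$proGenes), "genes\n")
  cat("  antibacterial:   ", length(x$antiProbes), "probes /",
      length(x$antiGenes), "genes\n")
  invisible(x)
}

#' Relaxed two-fold pro-inflammatory expression signature
#'
#' Genes with at least two-fold induction from N to N+L and at least two-fold
#' repression from N+L to T+L (`nl_avg/n_avg >= fold` and
#' `nl_avg/tl_avg >= fold`), with no p-value threshold. Boundaries are
#' inclusive. Probes with zero denominators are excluded with a reason.
#'
#' @param se a `SummarizedExperiment` with N, NL, TL conditions.
#' @param fold fold-change cutoff (default 2).
#' @return character vector of gene symbols (symbol-collapsed, deduplicated
#'   case-insensitively) with attributes `probes` (passing probe ids) and
#'   `excluded` (data.frame of probes excluded for zero denominators).
#' @export
twofoldSignature <- function(se, fold = 2) {
  stopifnot(fold > 0)
  av <- conditionAverages(se, c("N", "NL", "TL"))
  zeroN <- av[, "N"] <= 0
  zeroTL <- av[, "TL"] <= 0
  pass <- !zeroN & !zeroTL &
    av[, "NL"] / pmax(av[, "N"], .Machine$double.xmin) >= fold &
    av[, "NL"] / pmax(av[, "TL"], .Machine$double.xmin) >= fold
  probes <- rowData(se)$probe_id[pass]
  sym <- rowData(se)$gene_symbol[pass & rowData(se)$annotated]
  sym <- sym[!duplicated(toupper(trimws(sym)))]
  sym <- sym[order(toupper(sym))]
  excluded <- data.frame(
    probe_id = rowData(se)$probe_id[zeroN | zeroTL],
    reason = ifelse(zeroN[zeroN | zeroTL], "zero N average",
                    "zero TL average"),
    stringsAsFactors = FALSE)
  structure(sym, probes = probes, excluded = excluded)
}

#' Relative expression profiles against the global N maximum
#'
#' Condition averages divided by the single largest N-condition average in
#' the full matrix, so the most N-expressed probe maps to 1. Genes absent
#' from the matrix are skipped with a warning.
#'
#' @param se the full `SummarizedExperiment` (the normalizer is computed over
#'   all of it, not over the subset).
#' @param genes character vector of gene symbols (case-insensitive match).
#' @return data.frame with `gene`, `rel_n`, `rel_nl`, `rel_tl`.
#' @export
relativeProfiles <- function(se, genes) {
  if (!length(genes))
    return(data.frame(gene = character(), rel_n = numeric(),
                      rel_nl = numeric(), rel_tl = numeric(),
                      stringsAsFactors = FALSE))
  av <- conditionAverages(se, c("N", "NL", "TL"))
  normN <- max(av[, "N"])
  if (normN <= 0) stop("all N-condition averages are zero")
  g <- collapseToGenes(se)
  key <- toupper(trimws(rowData(g)$gene_symbol))
  idx <- match(toupper(trimws(genes)), key)
  if (anyNA(idx)) {
    warning("gene(s) absent from matrix skipped: ",
            paste(genes[is.na(idx)], collapse = ", "))
    genes <- genes[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  gav <- conditionAverages(g, c("N", "NL", "TL"))
  data.frame(gene = genes,
             rel_n = unname(gav[idx, "N"]) / normN,
             rel_nl = unname(gav[idx, "NL"]) / normN,
             rel_tl = unname(gav[idx, "TL"]) / normN,
             stringsAsFactors = FALSE)
}

#' Cross-dataset tolerizability check on a four-condition design
#'
#' For a matrix that also contains the tolerant (T) state, a gene is flagged
#' tolerizable when its first-treatment induction exceeds its re-stimulation
#' response: `(NL/N) > 1` and `(TL/T) < (NL/N)` (both strict). Genes with a
#' zero denominator are excluded with a reason.
#'
#' @param se a `SummarizedExperiment` whose design includes N, NL, T, TL.
#' @param genes gene symbols to check (case-insensitive).
#' @return data.frame `gene`, `induction` (NL/N), `restim` (TL/T),
#'   `tolerizable`, `reason`; attribute `n_tolerizable` is the flag count.
#' @export
crossDatasetPattern <- function(se, genes) {
  need <- c("N", "NL", "T", "TL")
  have <- unique(colData(se)$condition)
  if (!all(need %in% have))
    stop("four-condition design required (missing: ",
         paste(setdiff(need, have), collapse = ", "), ")")
  g <- collapseToGenes(se)
  key <- toupper(trimws(rowData(g)$gene_symbol))
  idx <- match(toupper(trimws(genes)), key)
  av <- conditionAverages(g, need)
  induction <- restim <- rep(NA_real_, length(genes))
  tolerizable <- rep(NA, length(genes))
  reason <- character(length(genes))
  for (i in seq_along(genes)) {
    if (is.na(idx[i])) { reason[i] <- "gene absent"; next }
    r <- av[idx[i], ]
    if (r[["N"]] <= 0 || r[["T"]] <= 0) {
      reason[i] <- "zero denominator"; next
    }
    induction[i] <- r[["NL"]] / r[["N"]]
    restim[i] <- r[["TL"]] / r[["T"]]
    tolerizable[i] <- induction[i] > 1 && restim[i] < induction[i]
  }
  out <- data.frame(gene = genes, induction = induction, restim = restim,
                    tolerizable = tolerizable, reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "n_tolerizable") <- sum(tolerizable, na.rm = TRUE)
  out
}

#' Pattern counts in random gene sets (null for the target-overlap check)
#'
#' Samples `nSets` gene sets of size `setSize` without replacement (within a
#' set) from the symbol-collapsed matrix and counts, per set, how many
#' members pass the two-fold pro-inflammatory pattern.
#'
#' @param se a `SummarizedExperiment` with N, NL, TL.
#' @param setSize genes per random set (default 18).
#' @param nSets number of sets (default 10).
#' @param seed RNG seed; fixed seed gives identical sets across runs.
#' @param fold fold cutoff for the pattern (default 2).
#' @return integer vector of per-set counts, with the sampled sets in
#'   attribute `sets`.
#' @export
randomGenePatternNull <- function(se, setSize = 18, nSets = 10, seed = 1,
                                  fold = 2) {
  g <- collapseToGenes(se)
  syms <- rowData(g)$gene_symbol
  if (setSize > length(syms))
    stop("setSize (", setSize, ") exceeds number of genes (", length(syms), ")")
  sig <- toupper(twofoldSignature(se, fold = fold))
  sets <- .withSeed(seed, lapply(seq_len(nSets), function(i)
    sample(syms, setSize)))
  counts <- vapply(sets, function(s) sum(toupper(s) %in% sig), integer(1))
  attr(counts, "sets") <- sets
  counts
}
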