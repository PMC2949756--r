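# Shared in-code fixtures: tiny expression matrices, promoter sets and PWM
# text blocks built programmatically at test time.

# A SummarizedExperiment from a plain matrix whose columns follow the
# <condition>_<replicate> naming convention.
makeSE <- function(m, symbols = rownames(m)) {
  probes <- if (is.null(rownames(m))) sprintf("probe_%03d", seq_len(nrow(m)))
            else rownames(m)
  rownames(m) <- probes
  cond <- sub("_[0-9]+$", "", colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    rowData = S4Vectors::DataFrame(probe_id = probes,
                                   gene_symbol = symbols,
                                   annotated = nzchar(symbols),
                                   row.names = probes),
    colData = S4Vectors::DataFrame(condition = cond,
                                   replicate = as.integer(sub("^.*_", "",
                                                              colnames(m))),
                                   row.names = colnames(m)))
}

# one-row-per-gene toy matrix: each row is c(N1,N2,NL1,NL2,TL1,TL2)
makeSE3 <- function(rows, symbols = names(rows)) {
  m <- do.call(rbind, rows)
  colnames(m) <- c("N_1", "N_2", "NL_1", "NL_2", "TL_1", "TL_2")
  rownames(m) <- names(rows)
  makeSE(m, symbols = symbols)
}

# random promoter set as a named character vector
randomPromoters <- function(n, len, seed = 1, prefix = "G") {
  set.seed(seed)
  out <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  names(out) <- sprintf("%s%03d", prefix, seq_len(n))
  out
}

insertWord <- function(seqs, word, at = NULL, seed = 1) {
  set.seed(seed)
  vapply(seqs, function(s) {
    off <- if (is.null(at)) sample(nchar(s) - nchar(word) + 1L, 1L) else at
    substr(s, off, off + nchar(word) - 1L) <- word
    s
  }, "")
}

# TRANSFAC-style text block for parser tests (matrix values synthetic)
transfacBlock <- function(acc, tf, counts) {
  rows <- vapply(seq_len(ncol(counts)), function(j)
    sprintf("%02d  %g  %g  %g  %g", j, counts[1, j], counts[2, j],
            counts[3, j], counts[4, j]), "")
  c(paste("AC", acc), "XX", paste("NA", tf), "XX",
    "P0      A       C       G       T", rows, "XX", "//")
}

curatedTargetsPath <- function() {
  system.file("extdata", "profile_tf_targets.tsv", package = "MotifTriad",
              mustWork = TRUE)
}

.withSeedForTest <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# brute-force single-record phenotype re-derivation used as the
# classification oracle (independent of classifyGenes internals)
oracleClassify <- function(vals, alpha = 0.05, contrast = "N_vs_TL") {
  nAvg <- mean(vals[1:2]); nlAvg <- mean(vals[3:4]); tlAvg <- mean(vals[5:6])
  other <- if (contrast == "N_vs_TL") vals[5:6] else vals[3:4]
  p <- tryCatch(stats::t.test(vals[1:2], other)$p.value,
                error = function(e) {
                  if (mean(vals[1:2]) == mean(other)) 1 else 0
                })
  if (nAvg <= 0 || nlAvg <= 0) return("unclassified")
  r1 <- nlAvg / nAvg; r2 <- tlAvg / nlAvg
  if (r1 > 1 && r2 < 1 && p < alpha) "pro_inflammatory"
  else if (r1 > 1 && r2 > 1 && p < alpha) "antibacterial"
  else "unclassified"
}
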