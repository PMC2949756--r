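# helpers local to the EM tests -------------------------------------------

plantWord <- function(n, len, word, seed, revcompPlant = FALSE) {
  set.seed(seed)
  w <- nchar(word)
  if (revcompPlant)
    word <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(word)))
  offs <- integer(n)
  seqs <- vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    off <- sample(len - w + 1L, 1L)
    substr(s, off, off + w - 1L) <- word
    offs[i] <<- off
    s
  }, "")
  list(seqs = seqs, offsets = offs)
}

revcompStr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("a noiseless planted word is recovered exactly with sites located", {
  word <- "ACGTTGCAA"
  pl <- plantWord(10, 49, word, seed = 3)
  seqs <- pl$seqs
  offs <- pl$offsets
  dm <- emZoops(seqs, width = 9, seed = 1)
  cons <- motifConsensus(motifPWM(dm))
  expect_true(cons %in% c(word, revcompStr(word)))
  st <- motifSites(dm)
  expect_true(all(st$posterior > 0.9))
  expect_equal(st$offset, offs)
  expect_true(all(dm@llTrace == cummax(dm@llTrace)))  # likelihood ascent
})

test_that("one EM iteration reproduces hand-computed E/M updates", {
  # two length-7 sequences, width 4, fixed start profile, forward strand,
  # uniform background; the oracle enumerates all offsets directly
  seqs <- c("ACGTACG", "GGACGTT")
  p0 <- matrix(c(0.7, 0.1, 0.1, 0.1,
                 0.1, 0.7, 0.1, 0.1,
                 0.1, 0.1, 0.7, 0.1,
                 0.1, 0.1, 0.1, 0.7), nrow = 4,
               dimnames = list(c("A", "C", "G", "T"), NULL))  # ~ACGT
  gamma <- 0.5
  w <- 4L
  lett <- lapply(strsplit(seqs, ""), match, table = c("A", "C", "G", "T"))
  counts <- matrix(0, 4, w)
  llOracle <- 0
  for (v in lett) {
    nwin <- length(v) - w + 1L
    lr <- vapply(seq_len(nwin), function(j)
      prod(p0[cbind(v[j:(j + w - 1L)], 1:w)] / 0.25), 0)
    denom <- (1 - gamma) + gamma * sum(lr) / nwin
    llOracle <- llOracle + log(denom)
    z <- gamma * lr / (nwin * denom)
    for (j in seq_len(nwin))
      for (k in seq_len(w))
        counts[v[j + k - 1L], k] <- counts[v[j + k - 1L], k] + z[j]
  }
  expProf <- sweep(counts + 0.1, 2, colSums(counts + 0.1), "/")
  dm <- emZoops(seqs, width = 4, seed = 1, revcomp = FALSE,
                start = p0, maxIter = 1, background = rep(0.25, 4))
  expect_equal(unname(motifMatrix(motifPWM(dm))), unname(expProf),
               tolerance = 1e-12)
  # the trace stores the Dirichlet-penalized objective
  expect_equal(dm@llTrace[1], llOracle + 0.1 * sum(log(p0)),
               tolerance = 1e-12)
})

test_that("EM input validation matches the contract", {
  expect_error(emZoops(c("ACGTACGT", "ACGTACGT"), width = 3), ">= 4")
  expect_error(emZoops("ACGTACGTAC", width = 6), "at least 2 sequences")
  expect_error(emZoops(c("NNNNNNNN", "NNNNNNNN"), width = 6),
               "at least 2 sequences")
})

test_that("random sequences yield weaker motifs than planted ones", {
  word <- "TGACGTCA"
  ics <- gammas <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    planted <- plantWord(8, 60, word, seed = 100 + s)$seqs
    set.seed(200 + s)
    rand <- vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
    dmP <- emZoops(planted, width = 8, seed = s)
    dmR <- emZoops(rand, width = 8, seed = s)
    ics[s, ] <- c(informationContent(motifPWM(dmP)),
                  informationContent(motifPWM(dmR)))
    gammas[s, ] <- c(dmP@occPrior, dmR@occPrior)
  }
  expect_gt(mean(ics[, 1]), mean(ics[, 2]))
  expect_gte(mean(gammas[, 1]), mean(gammas[, 2]))
})

test_that("strand handling: reverse-only plants are found, symmetry holds", {
  word <- "ACGTTGCAA"
  pl <- plantWord(10, 60, word, seed = 7, revcompPlant = TRUE)
  dm <- emZoops(pl$seqs, width = 9, seed = 2)
  expect_true(motifConsensus(motifPWM(dm)) %in% c(word, revcompStr(word)))
  # reverse-complementing every input recovers the same motif family
  rcseqs <- vapply(pl$seqs, revcompStr, "")
  dm2 <- emZoops(rcseqs, width = 9, seed = 2)
  expect_true(motifConsensus(motifPWM(dm2)) %in% c(word, revcompStr(word)))
})

test_that("masked bases are never chosen as sites", {
  word <- "ACGTTGCAA"
  pl <- plantWord(10, 80, word, seed = 13)
  seqs <- pl$seqs
  # mask a 20 nt block in each sequence away from the plant
  for (i in seq_along(seqs)) {
    maskAt <- if (pl$offsets[i] > 40) 5L else 55L
    substr(seqs[i], maskAt, maskAt + 19L) <- strrep("N", 20)
  }
  dm <- emZoops(seqs, width = 9, seed = 1)
  st <- motifSites(dm)
  for (i in seq_len(nrow(st))) {
    if (is.na(st$offset[i])) next
    site <- substr(seqs[i], st$offset[i], st$offset[i] + 8L)
    expect_false(grepl("N", site))
  }
  expect_true(all(st$occupancy <= 1 + 1e-9))
  expect_true(all(st$posterior <= st$occupancy + 1e-9))
})

test_that("dinucleotide shuffling preserves exact doublet composition", {
  set.seed(31)
  seqs <- c(paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                         prob = c(.4, .1, .1, .4)), collapse = ""),
            paste0(strrep("A", 20), strrep("N", 10),
                   paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                         collapse = "")))
  sh <- dinucleotideShuffle(seqs, seed = 5)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    d0 <- table(substring(seqs[i], 1:(n - 1), 2:n))
    d1 <- table(substring(sh[i], 1:(n - 1), 2:n))
    expect_identical(sort(names(d0)), sort(names(d1)))
    expect_identical(as.integer(d0[sort(names(d0))]),
                     as.integer(d1[sort(names(d0))]))
  }
  expect_identical(sh, dinucleotideShuffle(seqs, seed = 5))
  expect_false(identical(sh, dinucleotideShuffle(seqs, seed = 6)))
})

test_that("Monte-Carlo E-values hit the floor on strong plants and are seeded", {
  word <- "ACGTTGCAA"
  pl <- plantWord(10, 60, word, seed = 3)
  dm <- emZoops(pl$seqs, width = 9, seed = 1)
  ev <- motifEValue(dm, pl$seqs, nShuffles = 20, seed = 4, nWidths = 3)
  expect_equal(ev, 3 / 21)  # floor = nWidths / (nShuffles + 1)
  expect_identical(ev, motifEValue(dm, pl$seqs, nShuffles = 20, seed = 4,
                                   nWidths = 3))
  expect_error(motifEValue(dm, pl$seqs, nShuffles = 0), ">= 1")
})

test_that("sequential discovery separates two planted words", {
  wordA <- "TGACGTCA"
  wordB <- "CCAATTGG"
  hits <- 0L
  for (s in 1:10) {
    a <- plantWord(10, 50, wordA, seed = 300 + s)$seqs
    b <- plantWord(10, 50, wordB, seed = 400 + s)$seqs
    dms <- discoverMotifs(c(a, b), nMotifs = 2, widths = 8, seed = s,
                          nShuffles = 10)
    cons <- vapply(dms, function(d) motifConsensus(motifPWM(d)), "")
    near <- function(x, target) {
      tg <- c(target, revcompStr(target))
      any(vapply(tg, function(t)
        sum(strsplit(x, "")[[1]] != strsplit(t, "")[[1]]) <= 1, NA))
    }
    if (length(dms) == 2 &&
        ((near(cons[1], wordA) && near(cons[2], wordB)) ||
         (near(cons[1], wordB) && near(cons[2], wordA))))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  expect_identical(discoverMotifs(letters, nMotifs = 0), list())
})
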