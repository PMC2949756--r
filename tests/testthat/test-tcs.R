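test_that("word occurrence counting matches enumeration, per strand", {
  expect_equal(countMotifOccurrences("ACGT", "TACGTACGTT",
                                     bothStrands = FALSE), 2L)
  # GGCC: one forward match, one via the reverse strand at the same site
  expect_equal(countMotifOccurrences("GGCC", "GGCCAA", bothStrands = TRUE),
               2L)
  expect_equal(countMotifOccurrences("ACGT", "NNNNNNNN"), 0L)
  expect_warning(cnt <- countMotifOccurrences("ACGTACGT", "ACG"), "longer")
  expect_equal(cnt, 0L)
  # brute-force both-strand oracle on random sequences
  set.seed(17)
  word <- "GATC"
  rcword <- "GATC"  # GATC is its own reverse complement
  word2 <- "GGAT"
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(word2)))
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    naive <- function(wrd) {
      k <- nchar(wrd)
      sum(vapply(1:(60 - k + 1), function(j)
        substr(s, j, j + k - 1) == wrd, NA))
    }
    expect_equal(countMotifOccurrences(word2, s, bothStrands = TRUE),
                 naive(word2) + naive(rc2))
    expect_equal(countMotifOccurrences(word, s, bothStrands = TRUE),
                 naive(word) * 2L)  # palindrome counted once per strand
  }
})

test_that("PWM occurrence counting respects the score threshold", {
  pwm <- wordPWM("ACGTAC", accession = "W1")
  prom <- c(hit = paste0("TTTTT", "ACGTAC", "TTTTT"),
            none = strrep("T", 16))
  cnt <- countMotifOccurrences(pwm, prom, bothStrands = TRUE,
                               background = rep(0.25, 4))
  expect_equal(unname(cnt), c(1L, 0L))
  m <- motifCountMatrix(list("ACGTAC", pwm), prom,
                        background = rep(0.25, 4))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m[, 1]), c(1L, 0L))
})

test_that("word universe pruning keeps words present in enough promoters", {
  proms <- c(a = strrep("ACGTACGT", 5), b = strrep("ACGTACGT", 5),
             c = strrep("ACGTACGT", 5), d = strrep("TTTTTTTT", 5))
  u <- wordUniverse(proms, k = 8, minPromoters = 3)
  expect_true("ACGTACGT" %in% u)
  expect_false("TTTTTTTT" %in% u)  # present in 1 promoter only
})

test_that("least squares recovers exact coefficients and flags degeneracy", {
  fit <- fitLinearModel(cbind(m1 = c(0, 1, 2)), c(1, 3, 5))
  expect_equal(unname(fit$coefficients), 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)

  # noiseless two-motif design; oracle = normal equations solved directly
  X <- cbind(m1 = c(0, 1, 2, 3, 1, 2), m2 = c(2, 0, 1, 1, 3, 0))
  y <- 2 * X[, 1] - 1 * X[, 2] + 4
  fit2 <- fitLinearModel(X, y)
  Xd <- cbind(1, X)
  oracle <- solve(crossprod(Xd), crossprod(Xd, y))[, 1]
  expect_equal(unname(fit2$coefficients), unname(oracle[2:3]),
               tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients), c(2, -1), tolerance = 1e-8)

  # random well-conditioned designs agree with the oracle to 1e-8
  set.seed(23)
  for (i in 1:5) {
    Xr <- matrix(rpois(10 * 3, 2), nrow = 10)
    colnames(Xr) <- paste0("w", 1:3)
    yr <- rnorm(10)
    fr <- fitLinearModel(Xr, yr)
    Xd <- cbind(1, Xr)
    or <- solve(crossprod(Xd), crossprod(Xd, yr))[, 1]
    expect_equal(unname(c(fr$intercept, fr$coefficients)), unname(or),
                 tolerance = 1e-8)
  }

  # constant predictor: coefficient 0, flagged confounded
  fc <- fitLinearModel(cbind(m1 = rep(1, 4), m2 = c(0, 1, 2, 3)),
                       c(1, 2, 3, 4))
  expect_equal(unname(fc$coefficients["m1"]), 0)
  expect_true(fc$confounded[["m1"]])
  expect_false(fc$confounded[["m2"]])
})

test_that("random responses are uniform draws within the stated range", {
  r <- randomResponse(0, 1, 5, seed = 2)
  expect_length(r, 5L)
  expect_true(all(r >= 0 & r <= 1))
  expect_identical(r, randomResponse(0, 1, 5, seed = 2))
  expect_equal(randomResponse(3, 3, 4, seed = 1), rep(3, 4))
  big <- randomResponse(-2, 7, 1e4, seed = 9)
  expect_gte(min(big), -2)
  expect_lte(max(big), 7)
  expect_error(randomResponse(0, 1, -1), ">= 0")
  expect_error(randomResponse(2, 1, 5), "<=")
})

test_that("TCS reduces to standardized coefficients for a whole-universe fit", {
  set.seed(4)
  proms <- randomPromoters(12, 120, seed = 4)
  universe <- c("ACGTACGT", "TTGACGTC", "GGGCCCAA")
  counts <- motifCountMatrix(universe, proms)
  resp <- rnorm(12)
  tcs <- runTCS(proms, resp, universe, subsetSize = 3, nIterations = 1,
                seed = 1)
  fit <- fitLinearModel(counts, resp)
  std <- abs(fit$coefficients) * apply(counts, 2, sd) / sd(resp)
  expect_equal(tcs$tcs[match(universe, tcs$motif)], unname(std),
               tolerance = 1e-12)
  expect_error(runTCS(proms, resp, universe, subsetSize = 10), "exceeds")
  expect_error(runTCS(proms, resp, universe, subsetSize = 2,
                      nIterations = 0), ">= 1")
})

test_that("a planted noiseless driver tops the TCS ranking across seeds", {
  word <- "TGACGTCA"
  topRank <- beatsPermuted <- logical(10)
  for (s in 1:10) {
    set.seed(500 + s)
    proms <- randomPromoters(30, 150, seed = 500 + s)
    # plant the driver 0-3 times per promoter so counts vary
    nsites <- sample(0:3, 30, TRUE)
    for (i in which(nsites > 0))
      for (k in seq_len(nsites[i]))
        proms[i] <- insertWord(proms[i], word, seed = s * 100 + i * 10 + k)
    counts <- countMotifOccurrences(word, proms)
    resp <- 3 * counts  # noiseless driver
    set.seed(600 + s)
    decoys <- vapply(1:9, function(i)
      paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""), "")
    universe <- c(word, decoys)
    tcs <- runTCS(proms, resp, universe, subsetSize = 4, nIterations = 80,
                  seed = s)
    topRank[s] <- tcs$motif[1] == word
    permResp <- resp[.withSeedForTest(700 + s, sample(30))]
    tcsP <- runTCS(proms, permResp, universe, subsetSize = 4,
                   nIterations = 80, seed = s)
    beatsPermuted[s] <- tcs$tcs[tcs$motif == word] >
      tcsP$tcs[tcsP$motif == word]
    expect_equal(tcs$sign[tcs$motif == word], "stimulatory")
  }
  expect_gte(sum(topRank), 9L)
  expect_gte(sum(beatsPermuted), 9L)
})

test_that("TCS standardization is scale-equivariant", {
  set.seed(8)
  proms <- randomPromoters(15, 100, seed = 8)
  universe <- c("ACGTACGT", "TTGACGTC", "GGGCCCAA", "CACACACA")
  resp <- rnorm(15)
  a <- runTCS(proms, resp, universe, subsetSize = 2, nIterations = 40,
              seed = 3)
  b <- runTCS(proms, resp * 10, universe, subsetSize = 2, nIterations = 40,
              seed = 3)
  expect_equal(a$tcs, b$tcs, tolerance = 1e-12)          # invariant
  expect_equal(b$mean_coef, a$mean_coef * 10, tolerance = 1e-9)  # raw scales
})
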