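test_that("condition averages are per-condition arithmetic means", {
  se <- makeSE3(list(p1 = c(100, 110, 400, 420, 150, 160)))
  av <- conditionAverages(se, c("N", "NL", "TL"))
  expect_equal(unname(av[1, ]), c(105, 410, 155))
  se0 <- makeSE3(list(p1 = rep(0, 6)))
  expect_equal(unname(conditionAverages(se0, c("N", "NL", "TL"))[1, ]),
               c(0, 0, 0))
  expect_error(conditionIntensities(se, "T"), "absent")
})

test_that("Welch t-test matches the independent t-distribution oracle", {
  # frozen from the closed form: t = -5/sqrt(2), Welch df = 2
  expect_equal(welchTTest(c(1, 3), c(6, 8)), 0.07152331, tolerance = 1e-6)
  expect_equal(welchTTest(c(1, 3), c(6, 8)),
               stats::t.test(c(1, 3), c(6, 8), var.equal = FALSE)$p.value)
  # random-input cross-check against stats::t.test
  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), mean = runif(1))
    expect_equal(welchTTest(a, b), stats::t.test(a, b)$p.value,
                 tolerance = 1e-12)
  }
  # degenerate conventions
  expect_equal(welchTTest(c(5, 9), c(5, 9)), 1)
  expect_equal(welchTTest(c(2, 2), c(3, 3)), 0)
  expect_equal(welchTTest(c(2, 2), c(2, 2)), 1)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})

test_that("single records classify per the three-condition filter rules", {
  se <- makeSE3(list(
    pro = c(100, 110, 400, 420, 150, 160),  # up then down, N != TL
    anti = c(10, 12, 30, 32, 90, 95),       # up then further up
    flat = c(50, 50, 50, 50, 50, 50),       # r1 = 1 fails strict > 1
    zero = c(0, 0, 10, 10, 5, 5)))          # zero denominator
  ph <- classifyGenes(se, alpha = 0.05)
  calls <- ph$calls
  expect_equal(calls$label,
               c("pro_inflammatory", "antibacterial", "unclassified",
                 "unclassified"))
  expect_equal(calls$reason[4], "zero denominator")
  expect_equal(calls$r1[1], 410 / 105)
  # p-values equal the Welch oracle on the N vs TL contrast
  expect_equal(calls$p_value[1], welchTTest(c(100, 110), c(150, 160)))
  expect_lt(calls$p_value[2], 0.05)
})

test_that("matrix classification equals brute-force per-record re-derivation", {
  set.seed(42)
  for (rep in 1:4) {
    n <- sample(20:50, 1)
    m <- matrix(stats::rlnorm(n * 6, log(50), 1), nrow = n)
    # sprinkle in structured rows so both labels occur
    m[1, ] <- c(10, 11, 60, 62, 20, 21)
    m[2, ] <- c(10, 11, 40, 41, 90, 95)
    colnames(m) <- c("N_1", "N_2", "NL_1", "NL_2", "TL_1", "TL_2")
    rownames(m) <- sprintf("p%02d", 1:n)
    se <- makeSE(m, symbols = rownames(m))
    for (contrast in c("N_vs_TL", "N_vs_NL")) {
      ph <- classifyGenes(se, contrast = contrast)
      oracle <- apply(m, 1, oracleClassify, contrast = contrast)
      expect_equal(ph$calls$label, unname(oracle))
    }
  }
})

test_that("every probe gets exactly one label and alpha is monotone", {
  set.seed(9)
  m <- matrix(stats::rlnorm(40 * 6, log(50), 0.8), nrow = 40)
  m[1:6, 3:4] <- m[1:6, 1:2] * 5
  m[1:3, 5:6] <- m[1:3, 1:2]
  colnames(m) <- c("N_1", "N_2", "NL_1", "NL_2", "TL_1", "TL_2")
  se <- makeSE(m, symbols = sprintf("G%02d", 1:40))
  ph <- classifyGenes(se)
  expect_equal(length(ph$calls$label), 40L)
  expect_true(all(ph$calls$label %in%
    c("pro_inflammatory", "antibacterial", "unclassified")))
  expect_length(intersect(ph$proProbes, ph$antiProbes), 0L)
  loose <- classifyGenes(se, alpha = 0.5)
  strict <- classifyGenes(se, alpha = 0.01)
  expect_true(all(strict$proProbes %in% loose$proProbes))
  expect_true(all(strict$antiProbes %in% loose$antiProbes))
  # empty matrix -> empty sets
  e <- classifyGenes(se[integer(0), ])
  expect_length(e$proGenes, 0L)
  expect_length(e$antiGenes, 0L)
})

test_that("two-fold signature uses inclusive boundaries and no p-value", {
  se <- makeSE3(list(
    boundary = c(10, 10, 20, 20, 10, 10),   # exactly two-fold both ways: in
    under = c(10, 10, 15, 15, 10, 10),      # 1.5-fold: out
    strong = c(10, 10, 80, 80, 10, 10),     # in
    zero = c(0, 0, 20, 20, 10, 10)))        # excluded, zero N
  sig <- twofoldSignature(se)
  expect_setequal(as.character(sig), c("boundary", "strong"))
  expect_equal(attr(sig, "excluded")$probe_id, "zero")
  expect_setequal(attr(sig, "probes"), c("boundary", "strong"))
})

test_that("relative profiles normalize to the global N maximum", {
  se <- makeSE3(list(big = c(5000, 5000, 5000, 5000, 5000, 5000),
                     g1 = c(500, 500, 2000, 2000, 600, 600)))
  prof <- relativeProfiles(se, c("g1", "big"))
  expect_equal(prof$rel_n[prof$gene == "g1"], 0.1)
  expect_equal(prof$rel_nl[prof$gene == "g1"], 0.4)
  expect_equal(prof$rel_tl[prof$gene == "g1"], 0.12)
  expect_equal(prof$rel_n[prof$gene == "big"], 1)  # normalization anchor
  expect_equal(nrow(relativeProfiles(se, character())), 0L)
  expect_warning(relativeProfiles(se, c("g1", "nosuch")), "absent")
})

test_that("cross-dataset tolerizability uses strict fold comparison", {
  m <- rbind(tol = c(10, 10, 40, 40, 10, 10, 10, 10),
             eq = c(10, 10, 40, 40, 10, 10, 40, 40),
             zero = c(10, 10, 40, 40, 0, 0, 10, 10))
  colnames(m) <- c("N_1", "N_2", "NL_1", "NL_2", "T_1", "T_2",
                   "TL_1", "TL_2")
  se <- makeSE(m, symbols = rownames(m))
  out <- crossDatasetPattern(se, c("tol", "eq", "zero"))
  expect_true(out$tolerizable[out$gene == "tol"])    # (NL/N)=4, (TL/T)=1
  expect_false(out$tolerizable[out$gene == "eq"])    # 4 vs 4: equality fails
  expect_equal(out$reason[out$gene == "zero"], "zero denominator")
  expect_equal(attr(out, "n_tolerizable"), 1L)
  se3 <- makeSE3(list(p1 = c(1, 1, 2, 2, 1, 1)))
  expect_error(crossDatasetPattern(se3, "p1"), "four-condition")
})

test_that("random gene-set pattern null is seeded and calibrated", {
  # 400 genes, 5% carrying the two-fold pattern
  set.seed(5)
  rows <- lapply(1:400, function(i) {
    if (i <= 20) c(10, 10, 40, 40, 10, 10) else c(10, 10, 11, 11, 10, 10)
  })
  names(rows) <- sprintf("G%03d", 1:400)
  se <- makeSE3(rows)
  counts <- randomGenePatternNull(se, setSize = 18, nSets = 10, seed = 3)
  expect_length(counts, 10L)
  # binomial expectation 18 x 0.05 = 0.9
  expect_lt(mean(counts), 3)
  expect_identical(as.integer(counts),
                   as.integer(randomGenePatternNull(se, 18, 10, seed = 3)))
  expect_false(identical(as.integer(counts),
                         as.integer(randomGenePatternNull(se, 18, 10,
                                                          seed = 4))))
  expect_equal(as.integer(randomGenePatternNull(se, 0, 3, seed = 1)),
               c(0L, 0L, 0L))
  expect_error(randomGenePatternNull(se, 1000, 2, seed = 1), "exceeds")
})

test_that("planted classes are recovered from low-noise synthetic data", {
  # classify_matrix recovery property: low replicate noise, 4-fold effects
  cfg <- syntheticConfig(nGenes = 600, fracPro = 50 / 600, fracAnti = 10 / 600,
                         replicateCV = 0.02, seed = 21)
  e <- generateExpression(cfg)
  ph <- classifyGenes(e$se, contrast = "N_vs_NL")
  cls <- e$manifest$classes
  proTruth <- names(cls)[cls == "pro"]
  antiTruth <- names(cls)[cls == "anti"]
  expect_gte(mean(proTruth %in% ph$proGenes), 0.95)
  expect_gte(mean(antiTruth %in% ph$antiGenes), 0.95)
})
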