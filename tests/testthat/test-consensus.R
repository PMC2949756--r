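test_that("top-fraction selection uses ceiling counts with tie inclusion", {
  df <- data.frame(id = letters[1:10], score = (1:10) / 10)
  expect_equal(nrow(topFraction(df, 0.7, "lower_better")), 7L)
  expect_equal(topFraction(df, 0.7, "lower_better")$id, letters[1:7])
  df3 <- data.frame(id = letters[1:3], score = c(3, 1, 2))
  expect_equal(nrow(topFraction(df3, 0.7, "lower_better")), 3L)  # ceil(2.1)
  # boundary tie at positions 7 and 8 -> both retained
  tie <- data.frame(id = letters[1:10],
                    score = c(0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5, 0.5,
                              0.9, 1))
  expect_equal(nrow(topFraction(tie, 0.7, "lower_better")), 8L)
  # fraction 1.0 is the identity; orientation flips the kept end
  expect_equal(sort(topFraction(df, 1.0, "lower_better")$id), df$id)
  expect_equal(topFraction(df, 0.2, "higher_better")$id, c("j", "i"))
  expect_equal(nrow(topFraction(df[0, ], 0.7, "lower_better")), 0L)
})

test_that("library matching finds identical and reverse-complement matrices", {
  set.seed(41)
  lib <- lapply(1:4, function(i) {
    p <- matrix(runif(4 * 8) + diag(4)[sample(4, 8, TRUE), ] * 3, nrow = 4)
    p <- sweep(p, 2, colSums(p), "/")
    rownames(p) <- c("A", "C", "G", "T")
    PWMotif(p, accession = sprintf("M%02d", i), tfName = paste0("TF", i))
  })
  hit <- matchPWMToLibrary(lib[[2]], lib)
  expect_equal(hit$accession, "M02")
  expect_equal(hit$similarity, 1)
  expect_equal(hit$offset, 0L)
  rc <- reverseComplement(lib[[3]])
  hit2 <- matchPWMToLibrary(rc, lib)
  expect_equal(hit2$accession, "M03")
  expect_equal(hit2$orientation, "-")
  expect_equal(hit2$similarity, 1)
  # uniform query: correlations are 0, below any sensible threshold
  unif <- PWMotif(matrix(0.25, 4, 6,
                         dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_null(matchPWMToLibrary(unif, lib))
  # symmetry under joint reverse-complement of query and library
  rcLib <- lapply(lib, reverseComplement)
  hit3 <- matchPWMToLibrary(reverseComplement(lib[[2]]), rcLib)
  expect_equal(hit3$accession, "M02")
  expect_equal(hit3$similarity, 1)
})

test_that("engine intersection requires presence in all three retained sets", {
  d <- data.frame(accession = c("M1", "M2", "M3"), score = c(.1, .2, .3))
  t <- data.frame(accession = c("M2", "M3", "M4"), score = c(9, 8, 7))
  a <- data.frame(accession = c("M3", "M2", "M5"), score = c(.01, .02, .5))
  cons <- intersectEngines(d, t, a)
  expect_equal(cons$accession, c("M2", "M3"))
  expect_equal(cons$score_discovery, c(.2, .3))
  expect_equal(cons$score_tcs, c(9, 8))
  expect_equal(cons$score_affinity, c(.02, .01))
  expect_lte(nrow(cons), min(nrow(d), nrow(t), nrow(a)))
  # disjoint sets -> empty
  empty <- intersectEngines(d, data.frame(accession = "MX", score = 1), a)
  expect_equal(nrow(empty), 0L)
  # unmapped de novo predictions are dropped with a message
  d2 <- rbind(d, data.frame(accession = NA, score = .05))
  expect_message(cons2 <- intersectEngines(d2, t, a), "unmapped")
  expect_equal(cons2$accession, cons$accession)
})

test_that("de novo accession mapping merges duplicates keeping best E-value", {
  planted <- MotifTriad:::.defaultPlantedPWM()
  lib <- list(planted,
              MotifTriad:::.withSeed(5, MotifTriad:::.decoyPWM(
                planted, "DC01", "D1")))
  mkdm <- function(pwm, acc, ev) {
    dm <- new("DiscoveredMotif", motif = PWMotif(motifMatrix(pwm), acc),
              llr = 1, eValue = ev, occPrior = 0.5,
              sites = data.frame(seq = 1L, offset = 1L, strand = "+",
                                 posterior = 1, occupancy = 1),
              llTrace = 1, background = rep(0.25, 4))
    dm
  }
  dms <- list(mkdm(planted, "DENOVO_01", 0.2),
              mkdm(planted, "DENOVO_02", 0.05),
              mkdm(reverseComplement(planted), "DENOVO_03", 0.6))
  mapped <- mapDiscoveryToLibrary(dms, lib)
  hit <- mapped[!is.na(mapped$accession), ]
  expect_equal(nrow(hit), 1L)                  # merged to one accession
  expect_equal(hit$accession, accession(planted))
  expect_equal(hit$score, 0.05)                # best E-value kept
})

test_that("test-vs-random contrast marks absent accessions and ties", {
  cons <- data.frame(accession = c("M1", "M2"), tf_name = "",
                     score_discovery = c(.1, .2), score_tcs = c(5, 4),
                     score_affinity = c(.01, .02))
  test <- list(discovery = data.frame(accession = c("M1", "M2"),
                                      score = c(.1, .2)),
               tcs = data.frame(accession = c("M1", "M2"), score = c(5, 4)),
               affinity = data.frame(accession = c("M1", "M2"),
                                     score = c(.01, .02)))
  rand <- list(discovery = data.frame(accession = "M1", score = .5),
               tcs = data.frame(accession = c("M1", "M2"), score = c(2, 6)),
               affinity = data.frame(accession = "M2", score = .02))
  ct <- contrastTestVsRandom(cons, test, rand)
  expect_equal(ct$better[ct$accession == "M1" & ct$engine == "discovery"],
               "test")       # lower E on test
  expect_equal(ct$better[ct$accession == "M2" & ct$engine == "discovery"],
               "absent")
  expect_equal(ct$better[ct$accession == "M1" & ct$engine == "tcs"], "test")
  expect_equal(ct$better[ct$accession == "M2" & ct$engine == "tcs"],
               "random")     # higher TCS on random
  expect_equal(ct$better[ct$accession == "M2" & ct$engine == "affinity"],
               "tie")
  # self-contrast: everything ties
  self <- contrastTestVsRandom(cons, test, test)
  expect_true(all(self$better == "tie"))
  expect_error(contrastTestVsRandom(cons, test, rand[1:2]),
               "config mismatch")
})
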