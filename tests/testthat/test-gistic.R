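test_that("G-scores sum capped aberrant amplitudes per probe", {
  seg <- matrix(c(0.8, 0.0, 0.5), nrow = 1)
  calls <- matrix(c(1L, 0L, 1L), nrow = 1)
  expect_equal(unname(gscore(seg, calls, "gain")), 1.3)
  # no aberrant samples -> 0
  expect_equal(unname(gscore(seg, matrix(0L, 1, 3), "gain")), 0)
  # amplitude ceiling limits single-sample dominance
  seg2 <- matrix(5.0, nrow = 1)
  expect_equal(unname(gscore(seg2, matrix(1L, 1, 1), "gain", cap = 2)), 2)
  # losses scored on |segment mean|
  seg3 <- matrix(c(-0.4, -1.0), nrow = 1)
  expect_equal(unname(gscore(seg3, matrix(-1L, 1, 2), "loss")), 1.4)
  expect_error(gscore(seg, calls, "both"), "gain.*loss")
})

test_that("the cyclic-shift null gives p = 1 on flat cohorts and valid bounds", {
  seg <- matrix(0, nrow = 30, ncol = 5)
  calls <- matrix(0L, nrow = 30, ncol = 5)
  res <- gisticPermutationNull(seg, calls, "gain", nperm = 100, seed = 1)
  expect_true(all(res$p == 1))
  # p-values always in (0, 1]
  set.seed(2)
  seg2 <- matrix(rnorm(150, 0, 0.3), 30)
  calls2 <- matrix(sample(c(-1L, 0L, 1L), 150, replace = TRUE), 30)
  res2 <- gisticPermutationNull(seg2, calls2, "gain", nperm = 100, seed = 2)
  expect_true(all(res2$p > 0 & res2$p <= 1))
})

test_that("per-probe null exceedance matches exhaustive shift enumeration", {
  # 2 carriers of a 6-probe block on a 30-probe genome: at an event probe
  # m the null score reaches the observed G(m)=2 exactly when both
  # samples' shifted blocks cover m; enumerate all 30^2 offset pairs to
  # get that probability exactly and check the permutation estimate
  M <- 30
  seg <- matrix(0, M, 5); calls <- matrix(0L, M, 5)
  seg[11:16, 1:2] <- 1.0; calls[11:16, 1:2] <- 1L
  m <- 13
  hits <- 0
  for (o1 in 0:(M - 1)) for (o2 in 0:(M - 1)) {
    c1 <- m %in% ((((11:16) - 1 + o1) %% M) + 1)
    c2 <- m %in% ((((11:16) - 1 + o2) %% M) + 1)
    if (c1 && c2) hits <- hits + 1
  }
  pTrue <- hits / M^2  # = (6/30)^2 = 0.04
  expect_equal(pTrue, 0.04)
  res <- gisticPermutationNull(seg, calls, "gain", nperm = 2000, seed = 3)
  expect_equal(unname(res$p[m]), pTrue, tolerance = 0.35)
})

test_that("a widely recurrent event on an empty background attains minimal p", {
  # 8 of 20 samples (40%) carry a 4-probe event on a 60-probe genome; a
  # null configuration matches the observed score at an event probe only
  # if all 8 shifted blocks cover it, probability (4/60)^8 ~ 4e-10 per
  # permutation -- effectively unreachable, so p is the estimator floor
  M <- 60
  seg <- matrix(0, M, 20); calls <- matrix(0L, M, 20)
  seg[21:24, 1:8] <- 0.8; calls[21:24, 1:8] <- 1L
  res <- gisticPermutationNull(seg, calls, "gain", nperm = 1000, seed = 4)
  expect_equal(unname(res$p[21:24]), rep(1 / 1001, 4))
})

test_that("BH q-values match the hand computation and are monotone", {
  expect_equal(qValues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(qValues(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(50)
  q <- qValues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("peel-off extracts planted amplicons as separate regions", {
  M <- 120
  probes <- tinyProbes(M)
  nS <- 20
  seg <- matrix(0, M, nS)
  calls <- matrix(0L, M, nS)
  # one amplicon, probes 40-60, 30% of samples
  carriers <- 1:6
  seg[40:60, carriers] <- 0.8
  calls[40:60, carriers] <- 1L
  cn <- cnWithCalls(seg, calls, probes)
  g1 <- runGistic(cn, nperm = 200, seed = 5)
  gr1 <- gisticRegions(g1)
  gains <- gr1[gr1$kind == "gain"]
  expect_length(gains, 1)
  expect_gte(gains$peak_probe_first, 40)
  expect_lte(gains$peak_probe_last, 60)
  # two disjoint events on one chromosome, different carriers
  seg2 <- matrix(0, M, nS); calls2 <- matrix(0L, M, nS)
  seg2[20:30, 1:6] <- 0.8;  calls2[20:30, 1:6] <- 1L
  seg2[80:95, 7:12] <- 0.8; calls2[80:95, 7:12] <- 1L
  cn2 <- cnWithCalls(seg2, calls2, probes)
  g2 <- runGistic(cn2, nperm = 200, seed = 6)
  gains2 <- gisticRegions(g2)
  gains2 <- gains2[gains2$kind == "gain"]
  expect_length(gains2, 2)
  # flat cohort -> empty table
  g0 <- runGistic(cnWithCalls(matrix(0, M, nS), matrix(0L, M, nS), probes),
                  nperm = 200, seed = 7)
  expect_length(gisticRegions(g0), 0)
})

test_that("gain and loss analyses are symmetric under negation", {
  set.seed(8)
  coh <- generateCohort(nSamples = 30, seed = 8, probeCount = 1200,
                        transGenes = 0)
  cn <- segmentCohort(coh$cn, seed = 8)
  cn <- callCohort(cn)
  gPos <- runGistic(cn, nperm = 300, seed = 9)
  # negate: flip segment means and calls
  neg <- cn
  SummarizedExperiment::assay(neg, "seg") <- -segMeans(cn)
  SummarizedExperiment::assay(neg, "calls") <- -cnCalls(cn)
  gNeg <- runGistic(neg, nperm = 300, seed = 9)
  a <- gisticRegions(gPos); b <- gisticRegions(gNeg)
  swap <- c(gain = "loss", loss = "gain")
  expect_equal(length(a), length(b))
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_identical(unname(swap[a$kind]), b$kind)
  expect_equal(a$Gscore, b$Gscore, tolerance = 1e-12)
  expect_equal(a$q, b$q, tolerance = 1e-12)
})

test_that("adding an aberrant sample never decreases G at its probes", {
  set.seed(10)
  seg <- matrix(rnorm(200, 0, 0.2), 40, 5)
  calls <- matrix(sample(c(0L, 1L), 200, TRUE), 40, 5)
  g0 <- gscore(seg, calls, "gain")
  seg2 <- cbind(seg, 0.7)
  calls2 <- cbind(calls, 1L)
  g1 <- gscore(seg2, calls2, "gain")
  expect_true(all(g1 >= g0 - 1e-12))
})
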