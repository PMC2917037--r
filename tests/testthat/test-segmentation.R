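# independent oracle: exhaustive maximization of the circular-arc t
# statistic over all boundary pairs, in plain R
oracleMaxArc <- function(x, minSeg = 2) {
  x <- x - mean(x)
  n <- length(x)
  S <- c(0, cumsum(x))
  best <- c(stat = -1, i = 0, j = 0)
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    k <- j - i
    if (k < minSeg || k > n - minSeg) next
    d <- abs(S[j + 1] - S[i + 1]) * sqrt(n / (k * (n - k)))
    if (d > best["stat"]) best <- c(stat = d, i = i, j = j)
  }
  best
}

test_that("a noise-free step yields exactly two segments at the true breakpoint", {
  pm <- tinyProbes(100)
  x <- c(rep(0, 50), rep(1, 50))
  res <- cbsSegment(x, pm, seed = 1)
  expect_equal(nrow(res$segments), 2)
  expect_equal(res$segments$seg_mean, c(0, 1))
  expect_equal(res$segments$n_probes, c(50, 50))
  expect_equal(res$segMean, c(rep(0, 50), rep(1, 50)))
})

test_that("a constant profile stays a single segment", {
  pm <- tinyProbes(100)
  res <- cbsSegment(rep(0.3, 100), pm, seed = 1)
  expect_equal(nrow(res$segments), 1)
  expect_equal(res$segments$seg_mean, 0.3)
})

test_that("the split search agrees with the exhaustive arc-statistic oracle", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(60, 0, 0.1)
    x[30:45] <- x[30:45] + 0.6
    fast <- .cbs_max_arc(x, 2L)
    slow <- oracleMaxArc(x)
    expect_equal(fast$stat, unname(slow["stat"]), tolerance = 1e-10)
    expect_equal(fast$i, unname(slow["i"]))
    expect_equal(fast$j, unname(slow["j"]))
  }
})

test_that("a noisy planted step is localized within two probes", {
  pm <- tinyProbes(100)
  set.seed(5)
  for (rep in 1:5) {
    x <- rnorm(100, 0, 0.1)
    x[51:100] <- x[51:100] + 0.6
    res <- cbsSegment(x, pm, seed = rep)
    bp <- res$segments$n_probes[1]
    expect_true(abs(bp - 50) <= 2)
  }
})

test_that("missing probes are excluded and all-missing chromosomes skipped", {
  pm <- tinyProbes(40)
  x <- c(rep(0, 20), rep(0.8, 20))
  x[c(3, 25)] <- NA
  res <- cbsSegment(x, pm, seed = 1)
  expect_true(all(is.na(res$segMean[c(3, 25)])))
  expect_equal(sum(res$segments$n_probes), 38)
  pm2 <- c(tinyProbes(20), tinyProbes(20, chrom = "chr2"))
  names(pm2) <- sprintf("p%03d", 1:40)
  x2 <- c(rep(0.2, 20), rep(NA_real_, 20))
  expect_message(res2 <- cbsSegment(x2, pm2, seed = 1), "skipped")
  expect_equal(nrow(res2$segments), 1)
})

test_that("positional smoothing averages within the bp window only", {
  pm <- tinyProbes(3, spacing = 1e5)  # midpoints 100kb apart
  expect_equal(smoothWindow(rep(0.5, 3), pm, 250000), rep(0.5, 3))
  v <- c(0, 3, 0)
  sm <- smoothWindow(v, pm, 250000)
  expect_equal(sm[2], 1)  # mean of all three
  # a lone probe on its own chromosome keeps its value
  one <- tinyProbes(1, chrom = "chr5")
  expect_equal(smoothWindow(2.2, one, 250000), 2.2)
  # window smaller than the spacing leaves values untouched
  expect_equal(smoothWindow(v, pm, 50000), v)
})

test_that("adaptive thresholds floor at tauMin and track the noise scale", {
  expect_equal(adaptiveThresholds(rep(0, 100)),
               c(tau_gain = 0.1, tau_loss = -0.1))
  set.seed(8)
  v <- rnorm(5000, 0, 0.12)
  th <- adaptiveThresholds(v)
  expect_equal(th[["tau_gain"]], 2.5 * 0.12, tolerance = 0.1)
  expect_equal(th[["tau_loss"]], -2.5 * 0.12, tolerance = 0.1)
  # robust to 5% outliers
  v2 <- v
  v2[sample(5000, 250)] <- 2.0
  th2 <- adaptiveThresholds(v2)
  expect_lt(abs(th2[["tau_gain"]] - th[["tau_gain"]]) / th[["tau_gain"]],
            0.15)
  expect_error(adaptiveThresholds(rnorm(5)), ">= 10")
})

test_that("call states follow thresholds, the amp cut, and the 4-probe rule", {
  pm <- tinyProbes(10)
  segs <- data.frame(sample_id = "s", chrom = "chr1",
                     start = c(GenomicRanges::start(pm)[1],
                               GenomicRanges::start(pm)[8]),
                     end = c(GenomicRanges::end(pm)[7],
                             GenomicRanges::end(pm)[10]),
                     n_probes = c(7L, 3L), seg_mean = c(1.2, 2.0))
  segMean <- c(rep(1.2, 7), rep(2.0, 3))
  th <- c(tau_gain = 0.2, tau_loss = -0.2)
  cs <- callStates(segMean, segs, th, pm)
  expect_equal(cs$state[1:7], rep(1L, 7))
  expect_true(all(cs$highAmp[1:7]))
  # 3-probe segment at mean 2.0 is forced neutral (min-probe rule)
  expect_equal(cs$state[8:10], rep(0L, 3))
  expect_false(any(cs$highAmp[8:10]))
  # loss below tau_loss, no high-amp flag
  cs2 <- callStates(rep(-0.3, 10),
                    data.frame(sample_id = "s", chrom = "chr1",
                               start = GenomicRanges::start(pm)[1],
                               end = GenomicRanges::end(pm)[10],
                               n_probes = 10L, seg_mean = -0.3),
                    th, pm)
  expect_equal(cs2$state, rep(-1L, 10))
  expect_false(any(cs2$highAmp))
})

test_that("FGA counts altered probes and decomposes into gain + loss", {
  calls <- c(rep(1L, 250), rep(-1L, 150), rep(0L, 600))
  f <- fga(calls)
  expect_equal(unname(unlist(f)), c(0.40, 0.25, 0.15))
  expect_equal(f$fga, f$fga_gain + f$fga_loss)
  expect_equal(unname(unlist(fga(rep(0L, 10)))), c(0, 0, 0))
  expect_equal(unname(unlist(fga(rep(1L, 10)))), c(1, 1, 0))
  expect_error(fga(rep(NA_integer_, 5)), "non-missing")
})

test_that("FGA is monotone as thresholds shrink toward zero", {
  pm <- tinyProbes(200)
  set.seed(3)
  segMean <- rep(rnorm(20, 0, 0.3), each = 10)
  segs <- NULL
  fgas <- vapply(c(0.5, 0.3, 0.15, 0.05), function(tau) {
    cs <- callStates(segMean, segs, c(tau_gain = tau, tau_loss = -tau), pm)
    fga(cs$state)$fga
  }, numeric(1))
  expect_true(all(diff(fgas) >= 0))
})

test_that("computed FGA tracks planted FGA across a cohort", {
  coh <- generateCohort(nSamples = 40, seed = 21, probeCount = 1500,
                        transGenes = 0)
  cn <- segmentCohort(coh$cn, seed = 21)
  cn <- callCohort(cn)
  f <- fga(cn)
  expect_gte(cor(f$fga, coh$truth$fga), 0.95)
})
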