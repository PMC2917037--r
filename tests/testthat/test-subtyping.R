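makeRegionGistic <- function(probes, firsts, lasts, kinds) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(rep("chr1", length(firsts)),
                      levels = c(paste0("chr", 1:22), "chrX")),
    ranges = IRanges::IRanges(
      start = GenomicRanges::start(probes)[firsts],
      end = GenomicRanges::end(probes)[lasts]))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = kinds, peak_start = GenomicRanges::start(probes)[firsts],
    peak_end = GenomicRanges::end(probes)[lasts],
    probe_first = firsts, probe_last = lasts,
    peak_probe_first = firsts, peak_probe_last = lasts,
    Gscore = 10, q = 0.01, freq = 0.3)
  names(gr) <- paste0("R", seq_along(gr))
  new("GisticResults", regions = gr,
      probeStats = S4Vectors::DataFrame(row.names = names(probes)),
      params = list(qThreshold = 0.25))
}

test_that("region matrices average peak probes and scale per region", {
  probes <- tinyProbes(20)
  seg <- matrix(0, 20, 4, dimnames = list(names(probes), paste0("S", 1:4)))
  seg[1:5, ] <- rep(c(0.2, 0.4, 0.0, -0.2), each = 5)
  seg[11:15, ] <- rep(c(1, 1, 1, 1), each = 5)  # constant region
  cn <- cnWithCalls(seg, matrix(0L, 20, 4), probes)
  g <- makeRegionGistic(probes, c(1, 11), c(5, 15), c("gain", "gain"))
  raw <- buildRegionMatrix(g, cn, scale = "none")
  expect_equal(unname(raw[1, ]), c(0.2, 0.4, 0.0, -0.2))
  # sd scaling: zero stays zero, unit variance
  expect_message(sc <- buildRegionMatrix(g, cn), "constant across samples")
  expect_equal(sd(sc[1, ]), 1, tolerance = 1e-9)
  expect_equal(sc[1, 3][[1]], 0)
  expect_equal(unname(sc[2, ]), rep(0, 4))  # degenerate row -> zeros
  # z mode centers too
  expect_message(z <- buildRegionMatrix(g, cn, scale = "z"))
  expect_equal(mean(z[1, ]), 0, tolerance = 1e-9)
  expect_equal(sd(z[1, ]), 1, tolerance = 1e-9)
})

test_that("clustering separates two noise-free archetypes perfectly", {
  rm2 <- cbind(matrix(rep(c(2, 2, 0, 0), 5), 4), # 5 samples of pattern A
               matrix(rep(c(0, 0, 2, 2), 5), 4)) # 5 of pattern B
  rm2 <- rm2 + matrix(rnorm(40, 0, 0.01), 4)
  rownames(rm2) <- paste0("R", 1:4)
  colnames(rm2) <- paste0("S", 1:10)
  as2 <- clusterSubtypes(rm2, k = 2)
  labs <- subtypeLabels(as2)
  expect_equal(mclust::adjustedRandIndex(labs, rep(c("A", "B"), each = 5)),
               1)
})

test_that("correlation distance is invariant to per-sample affine maps", {
  set.seed(41)
  base <- matrix(rnorm(60), 6, 10,
                 dimnames = list(paste0("R", 1:6), paste0("S", 1:10)))
  shifted <- 2 * base + 3
  d1 <- as.matrix(stats::as.dist(1 - cor(base)))
  d2 <- as.matrix(stats::as.dist(1 - cor(shifted)))
  expect_equal(d1, d2, tolerance = 1e-12)
  a1 <- clusterSubtypes(base, k = 3)
  a2 <- clusterSubtypes(shifted, k = 3)
  expect_equal(mclust::adjustedRandIndex(subtypeLabels(a1),
                                         subtypeLabels(a2)), 1)
})

test_that("zero-variance sample vectors are rejected by name", {
  rm2 <- matrix(rnorm(20), 4, 5,
                dimnames = list(paste0("R", 1:4), paste0("S", 1:5)))
  rm2[, 3] <- 7
  expect_error(clusterSubtypes(rm2, k = 2), "S3")
  expect_error(clusterSubtypes(rm2[, 1:2], k = 5), "exceeds sample count")
})

test_that("supervised region tests keep Bonferroni-significant frequent regions", {
  set.seed(42)
  probes <- tinyProbes(100)
  nA <- 20; nB <- 20
  groups <- rep(c("A", "B"), c(nA, nB))
  # 10 regions; region 1 differential (Delta = 1.0 scaled units, sd 0.2)
  rm10 <- matrix(rnorm(10 * 40, 0, 0.2), 10, 40,
                 dimnames = list(paste0("R", 1:10),
                                 sprintf("S%02d", 1:40)))
  rm10[1, groups == "A"] <- rm10[1, groups == "A"] + 1.0
  # calls: region 1 aberrant in group A at its peak probe (probe 1)
  calls <- matrix(0L, 100, 40,
                  dimnames = list(names(probes), colnames(rm10)))
  calls[1, groups == "A"] <- 1L
  seg <- matrix(0, 100, 40, dimnames = dimnames(calls))
  cn <- cnWithCalls(seg, calls, probes)
  g <- makeRegionGistic(probes, seq(1, 92, by = 10), seq(5, 96, by = 10),
                        rep("gain", 10))
  names(g@regions) <- paste0("R", 1:10)
  res <- supervisedRegionTests(rm10, groups, g, cn)
  expect_equal(res$region, "R1")
  expect_lt(res$p_adj, 0.05)
  expect_identical(res$higher_group, "A")
  # identical distributions -> empty
  rm0 <- matrix(rnorm(400, 0, 0.2), 10, 40, dimnames = dimnames(rm10))
  expect_equal(nrow(supervisedRegionTests(rm0, groups, g, cn)), 0)
  # significant but below the frequency filter -> excluded
  callsLow <- calls; callsLow[1, ] <- 0L
  callsLow[1, which(groups == "A")[1:2]] <- 1L  # 10% in A
  cnLow <- cnWithCalls(seg, callsLow, probes)
  expect_equal(nrow(supervisedRegionTests(rm10, groups, g, cnLow)), 0)
})

test_that("centroids are member means over the gene list", {
  em <- matrix(c(1, 10, 3, 20, 8, 30), nrow = 2,
               dimnames = list(c("gA", "gB"), c("S1", "S2", "S3")))
  genes <- GenomicRanges::GRanges(
    seqnames = factor(c("chr1", "chr2"),
                      levels = c(paste0("chr", 1:22), "chrX")),
    ranges = IRanges::IRanges(start = c(1e6, 1e6), width = 1000))
  names(genes) <- rownames(em)
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = em), rowRanges = genes)
  labels <- setNames(factor(c("x", "x", "y")), colnames(em))
  cents <- buildCentroids(expr, labels, c("gA", "gB", "gMissing"))
  expect_equal(dim(cents), c(2, 2))       # missing gene dropped everywhere
  expect_equal(unname(cents[, "x"]), c(mean(c(1, 3)), mean(c(10, 20))))
  expect_equal(unname(cents[, "y"]), c(8, 30))
  # single-member subtype centroid is that sample's vector
  labels2 <- setNames(factor(c("x", "y", "z")), colnames(em))
  c2 <- buildCentroids(expr, labels2, c("gA", "gB"))
  expect_equal(unname(c2[, "z"]), c(8, 30))
})

test_that("nearest-centroid classification follows correlation, ties and minR", {
  cents <- cbind(alpha = c(1, 2, 3, 4, 5), beta = c(5, 4, 3, 2, 1))
  rownames(cents) <- paste0("g", 1:5)
  em <- cbind(S1 = c(1, 2, 3, 4, 5),        # = alpha
              S2 = c(2, 4, 6, 8, 10),       # affine alpha, tie-free
              S3 = c(1, 1, 1, 2, 1))        # weak
  rownames(em) <- paste0("g", 1:5)
  res <- classifyByCentroid(em, cents)
  expect_equal(unname(res$label["S1"]), "alpha")
  expect_equal(unname(res$label["S2"]), "alpha")
  expect_equal(unname(res$correlations["S1", "alpha"]), 1)
  # min_r turns uncorrelated samples into "unclassified"
  res2 <- classifyByCentroid(em[, "S3", drop = FALSE], cents, minR = 0.9)
  expect_equal(unname(res2$label), "unclassified")
  # exact tie resolves to the first declared centroid with a notice
  emT <- cbind(S4 = c(0, 0, 1, 0, 0))
  rownames(emT) <- paste0("g", 1:5)
  expect_message(res3 <- classifyByCentroid(emT, cents), "tie")
  expect_equal(unname(res3$label), "alpha")
  expect_error(classifyByCentroid(em[1:3, ], cents[1:3, ]), "5 shared")
})

test_that("cluster naming recovers archetype identities on a clean cohort", {
  coh <- generateCohort(nSamples = 120, seed = 43, probeCount = 1500,
                        noiseSd = 0.1, transGenes = 0)
  cn <- segmentCohort(coh$cn, seed = 43)
  cn <- callCohort(cn)
  g <- runGistic(cn, nperm = 500, seed = 43)
  rm6 <- buildRegionMatrix(g, cn)
  as6 <- clusterSubtypes(rm6, k = 6)
  naming <- matchArchetypeNames(as6, g, cn)
  labs <- attr(naming, "labels")
  truth <- coh$truth$subtype
  # the named labels agree with truth for a clear majority of samples
  expect_gte(mean(as.character(labs) == as.character(truth)), 0.6)
  # all six archetype names assigned to distinct clusters
  expect_setequal(unname(naming), names(defaultArchetypes()))
})

test_that("held-out expression samples classify to their planted subtype", {
  props <- setNames(rep(1 / 6, 6), names(defaultArchetypes()))
  train <- generateCohort(nSamples = 150, seed = 61, probeCount = 1500,
                          proportions = props, transGenes = 50)
  test <- generateCohort(nSamples = 300, seed = 62, probeCount = 1500,
                         proportions = props, transGenes = 50)
  cents <- buildCentroids(train$expr, train$truth$subtype,
                          train$truth$cisGenes)
  res <- classifyByCentroid(test$expr, cents)
  acc <- mean(res$label[names(test$truth$subtype)] ==
                as.character(test$truth$subtype))
  expect_gte(acc, 0.8)
})
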