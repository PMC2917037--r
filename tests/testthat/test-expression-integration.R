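# small fixture: 40-probe genome, one significant region spanning probes
# 10-20, built directly as a GisticResults
miniGistic <- function(probes, first, last, kind = "gain") {
  gr <- GenomicRanges::GRanges(
    seqnames = factor("chr1", levels = c(paste0("chr", 1:22), "chrX")),
    ranges = IRanges::IRanges(start = GenomicRanges::start(probes)[first],
                              end = GenomicRanges::end(probes)[last]))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = kind, peak_start = GenomicRanges::start(probes)[first],
    peak_end = GenomicRanges::end(probes)[last],
    probe_first = first, probe_last = last,
    peak_probe_first = first, peak_probe_last = last,
    Gscore = 10, q = 0.01, freq = 0.3)
  names(gr) <- paste0(kind, "_chr1")
  new("GisticResults", regions = gr,
      probeStats = S4Vectors::DataFrame(row.names = names(probes)),
      params = list(qThreshold = 0.25))
}

geneGR <- function(starts, ends, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = c(paste0("chr", 1:22), "chrX")),
    ranges = IRanges::IRanges(start = starts, end = ends))
  names(gr) <- paste0("g", seq_along(gr))
  gr
}

test_that("genes map to regions expanded by exactly one probe", {
  probes <- tinyProbes(40, spacing = 1e5, width = 5e4)  # probe i: [i*1e5, i*1e5+5e4]
  g <- miniGistic(probes, 10, 20)
  genes <- geneGR(starts = c(1.5e6,  # inside the region
                             9.02e5, # overlaps only probe 9 (the flank)
                             8.02e5, # overlaps only probe 8 (beyond flank)
                             3.0e6), # far away
                  ends = c(1.51e6, 9.3e5, 8.3e5, 3.01e6))
  map <- mapGenesToRegions(genes, g, probes)
  expect_setequal(map$gene_id, c("g1", "g2"))
})

test_that("dosage correlation passes perfect cis genes and rejects anti-correlated", {
  set.seed(31)
  n <- 60
  rv <- matrix(rnorm(n), 1, dimnames = list("gain_chr1", sprintf("S%02d", 1:n)))
  em <- rbind(perfect = rv[1, ],
              anti = -rv[1, ],
              noise = rnorm(n))
  colnames(em) <- colnames(rv)
  genes <- geneGR(starts = c(1e6, 1.1e6, 1.2e6), ends = c(1e6, 1.1e6, 1.2e6) + 999)
  names(genes) <- rownames(em)
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = em), rowRanges = genes)
  assignment <- data.frame(gene_id = rownames(em), region = "gain_chr1")
  dc <- dosageCorrelation(expr, rv, assignment, nperm = 100, seed = 1)
  tab <- dc$table
  expect_equal(tab$r[tab$gene_id == "perfect"], 1)
  expect_true(tab$pass[tab$gene_id == "perfect"])
  expect_equal(tab$r[tab$gene_id == "anti"], -1)
  expect_false(tab$pass[tab$gene_id == "anti"])  # one-sided rule
  # two-sided flag admits strong negative correlation
  dc2 <- dosageCorrelation(expr, rv, assignment, nperm = 100, seed = 1,
                           twoSided = TRUE)
  expect_true(dc2$table$pass[dc2$table$gene_id == "anti"])
})

test_that("zero-variance genes are skipped with a notice", {
  set.seed(32)
  n <- 30
  rv <- matrix(rnorm(n), 1, dimnames = list("gain_chr1", sprintf("S%02d", 1:n)))
  em <- rbind(flat = rep(1, n), ok = rv[1, ] + rnorm(n, 0, 0.1))
  colnames(em) <- colnames(rv)
  genes <- geneGR(c(1e6, 1.2e6), c(1e6, 1.2e6) + 999)
  names(genes) <- rownames(em)
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = em), rowRanges = genes)
  assignment <- data.frame(gene_id = rownames(em), region = "gain_chr1")
  expect_message(dc <- dosageCorrelation(expr, rv, assignment, nperm = 100,
                                         seed = 2), "zero variance")
  expect_true(is.na(dc$table$r[dc$table$gene_id == "flat"]))
  expect_false(dc$table$pass[dc$table$gene_id == "flat"])
})

test_that("the null cutoff approximates the analytic one-sided quantile", {
  # independent normal gene and region vectors, n = 100 samples: r* should
  # land near 1.64/sqrt(n)
  set.seed(33)
  n <- 100
  rv <- matrix(rnorm(n), 1, dimnames = list("gain_chr1", sprintf("S%03d", 1:n)))
  em <- matrix(rnorm(200 * n), 200, n,
               dimnames = list(paste0("g", 1:200), colnames(rv)))
  genes <- geneGR(seq(1e6, by = 2e3, length.out = 200),
                  seq(1e6, by = 2e3, length.out = 200) + 999)
  names(genes) <- rownames(em)
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = em), rowRanges = genes)
  assignment <- data.frame(gene_id = rownames(em), region = "gain_chr1")
  dc <- dosageCorrelation(expr, rv, assignment, nperm = 100, seed = 3)
  expect_equal(dc$rStar, 1.64 / sqrt(n), tolerance = 0.2)
})

test_that("probe-level correlation matches gene-probe construction", {
  coh <- generateCohort(nSamples = 50, seed = 34, probeCount = 1500,
                        transGenes = 20)
  cn <- segmentCohort(coh$cn, seed = 34)
  gp <- globalProbeCorrelation(coh$expr, cn)
  cis <- gp[gp$gene_id %in% coh$truth$cisGenes, ]
  expect_gte(median(cis$r, na.rm = TRUE), 0.6)
  trans <- gp[!gp$gene_id %in% coh$truth$cisGenes, ]
  expect_lt(abs(median(trans$r, na.rm = TRUE)), 0.25)
})

test_that("signature scores behave as means or centroid correlations", {
  em <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  genes <- geneGR(c(1e6, 2e6, 3e6), c(1e6, 2e6, 3e6) + 999)
  names(genes) <- rownames(em)
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = em), rowRanges = genes)
  # centroid-free single-gene list: the score is that gene's value
  expect_equal(unname(signatureScore(expr, "a")), c(1, 2))
  # centroid-free list: mean expression
  expect_equal(unname(signatureScore(expr, c("a", "b", "c"))),
               c(mean(c(1, 3, 5)), mean(c(2, 4, 6))))
  # sample equal to the centroid scores r = 1; shift invariance
  cen <- c(a = 1, b = 3, c = 5)
  sc <- signatureScore(expr, c("a", "b", "c"), centroid = cen)
  expect_equal(unname(sc["s1"]), 1)
  expect_equal(unname(sc["s2"]), 1)  # s2 = centroid + 1
  expect_error(signatureScore(expr, "zz"), "no listed genes")
})
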