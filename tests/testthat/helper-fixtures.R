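# Small builders used across the suite.

# n probes on a single chromosome, evenly spaced `spacing` bp apart
tinyProbes <- function(n, chrom = "chr1", spacing = 1e5, width = 5e4) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(rep(chrom, n),
                      levels = c(paste0("chr", 1:22), "chrX")),
    ranges = IRanges::IRanges(start = seq_len(n) * spacing, width = width))
  names(gr) <- sprintf("p%03d", seq_len(n))
  gr
}

# CopyNumberExperiment carrying precomputed segment means and calls, for
# exercising the scoring stages without running CBS
cnWithCalls <- function(seg, calls, probes = NULL) {
  if (is.null(probes)) probes <- tinyProbes(nrow(seg))
  if (is.null(colnames(seg)))
    colnames(seg) <- sprintf("S%02d", seq_len(ncol(seg)))
  rownames(seg) <- names(probes)
  dimnames(calls) <- dimnames(seg)
  cn <- CopyNumberExperiment(seg, probes)
  SummarizedExperiment::assay(cn, "seg") <- seg
  SummarizedExperiment::assay(cn, "calls") <- calls
  S4Vectors::metadata(cn)$segments <- data.frame()
  cn
}

# a tiny two-archetype catalog for fast recovery tests
miniArchetypes <- function() {
  a <- defaultArchetypes()[c("luminal-simple", "basal-complex")]
  a[["luminal-simple"]]$proportion <- 0.5
  a[["basal-complex"]]$proportion <- 0.5
  a
}
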