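#' @include AllGenerics.R
#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @useDynLib CNAsubtypes, .registration = TRUE
NULL

.validChroms <- function() c(paste0("chr", 1:22), "chrX")

#' CopyNumberExperiment: per-probe log2 ratios for a tumor cohort
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. Rows are array probes
#' (the probe map, a \linkS4class{GRanges} in natural chromosome order
#' chr1..chr22, chrX; internal coordinates 1-based inclusive), columns are
#' samples. The \code{"lr"} assay holds normalized log2 copy-number ratios;
#' \code{\link{segmentCohort}} adds a \code{"seg"} assay (per-probe segment
#' means) and \code{\link{callCohort}} a \code{"calls"} assay (-1 loss,
#' 0 neutral, 1 gain) plus per-sample thresholds in \code{colData}.
#'
#' @export
setClass("CopyNumberExperiment", contains = "RangedSummarizedExperiment")

setValidity("CopyNumberExperiment", function(object) {
  msg <- character()
  rr <- SummarizedExperiment::rowRanges(object)
  if (!"lr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'lr' (log2 ratios) is required")
  if (is.null(names(rr)) || anyDuplicated(names(rr)))
    msg <- c(msg, "probe ids (rowRanges names) must be present and unique")
  chr <- as.character(GenomicRanges::seqnames(rr))
  bad <- setdiff(unique(chr), .validChroms())
  if (length(bad))
    msg <- c(msg, paste0("unsupported chromosome(s): ",
                         paste(bad, collapse = ", ")))
  ord <- order(match(chr, .validChroms()), GenomicRanges::start(rr))
  if (!identical(as.integer(ord), seq_len(length(rr))))
    msg <- c(msg, "probes must be sorted by (chrom, start)")
  if (any(GenomicRanges::start(rr) > GenomicRanges::end(rr)))
    msg <- c(msg, "probe start must be <= end")
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  lr <- SummarizedExperiment::assay(object, "lr")
  if (any(is.infinite(lr)))
    msg <- c(msg, "log2 ratios must be finite where present")
  if (length(msg)) msg else TRUE
})

#' Construct a CopyNumberExperiment
#'
#' @param lr numeric matrix of log2 ratios, probes x samples (NA allowed).
#' @param probes \code{GRanges} probe map, named by probe id, same order and
#'   length as \code{nrow(lr)}.
#' @param colData optional per-sample \code{DataFrame} (e.g. clinical table).
#' @return A \linkS4class{CopyNumberExperiment}.
#' @export
CopyNumberExperiment <- function(lr, probes, colData = NULL) {
  lr <- as.matrix(lr)
  if (length(probes) != nrow(lr))
    stop("probe map length (", length(probes),
         ") does not match matrix rows (", nrow(lr), ")")
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(lr))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lr = lr), rowRanges = probes, colData = colData)
  new("CopyNumberExperiment", se)
}

#' @describeIn CopyNumberExperiment probe map accessor (GRanges)
#' @param x a CopyNumberExperiment
#' @export
setMethod("probeMap", "CopyNumberExperiment", function(x)
  SummarizedExperiment::rowRanges(x))

#' @describeIn CopyNumberExperiment log2-ratio assay accessor
#' @export
setMethod("log2Ratios", "CopyNumberExperiment", function(x)
  SummarizedExperiment::assay(x, "lr"))

#' @describeIn CopyNumberExperiment per-probe CBS segment means (after
#'   \code{segmentCohort})
#' @export
setMethod("segMeans", "CopyNumberExperiment", function(x) {
  if (!"seg" %in% SummarizedExperiment::assayNames(x))
    stop("no 'seg' assay: run segmentCohort() first")
  SummarizedExperiment::assay(x, "seg")
})

#' @describeIn CopyNumberExperiment per-probe call states, -1/0/1 (after
#'   \code{callCohort})
#' @export
setMethod("cnCalls", "CopyNumberExperiment", function(x) {
  if (!"calls" %in% SummarizedExperiment::assayNames(x))
    stop("no 'calls' assay: run callCohort() first")
  SummarizedExperiment::assay(x, "calls")
})

#' @describeIn CopyNumberExperiment per-sample segment table (after
#'   \code{segmentCohort})
#' @export
setMethod("segmentTable", "CopyNumberExperiment", function(x) {
  seg <- S4Vectors::metadata(x)$segments
  if (is.null(seg)) stop("no segment table: run segmentCohort() first")
  seg
})

#' @describeIn CopyNumberExperiment per-sample gain/loss thresholds (after
#'   \code{callCohort})
#' @export
setMethod("callThresholds", "CopyNumberExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("tau_gain", "tau_loss") %in% colnames(cd)))
    stop("no thresholds: run callCohort() first")
  cd[, c("tau_gain", "tau_loss")]
})

setMethod("show", "CopyNumberExperiment", function(object) {
  cat("CopyNumberExperiment:", nrow(object), "probes x",
      ncol(object), "samples\n")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
  chr <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(object)))
  cat("  chromosomes:", length(unique(chr)), "\n")
  invisible(object)
})

#' GisticResults: significant recurrent gain/loss regions
#'
#' Holds the retained regions (a \code{GRanges} of wide-region bounds with
#' peak bounds, probe spans, G-scores, q-values and cohort frequencies in
#' \code{mcols}) together with the per-probe score tables and the parameters
#' used. Created by \code{\link{runGistic}}.
#'
#' @slot regions GRanges of retained regions (wide bounds; mcols: kind,
#'   peak_start/peak_end in bp, probe_first/probe_last and
#'   peak_probe_first/peak_probe_last as indices into the probe map, Gscore,
#'   q, freq).
#' @slot probeStats per-probe DataFrame: G, p, q for each of gain and loss.
#' @slot params list of scoring parameters.
#' @export
setClass("GisticResults",
  representation(regions = "GRanges", probeStats = "DataFrame",
                 params = "list"))

#' @describeIn GisticResults retained region table (GRanges)
#' @param x a GisticResults
#' @export
setMethod("gisticRegions", "GisticResults", function(x) x@regions)

#' @describeIn GisticResults per-probe G/p/q table
#' @export
setMethod("probeScores", "GisticResults", function(x) x@probeStats)

setMethod("show", "GisticResults", function(object) {
  k <- table(factor(object@regions$kind, levels = c("gain", "loss")))
  cat("GisticResults:", length(object@regions), "regions (",
      k[["gain"]], "gain,", k[["loss"]], "loss ) at q <",
      object@params$qThreshold, "\n")
  invisible(object)
})

#' SubtypeAssignment: genomic-subtype labels from region-level clustering
#'
#' Produced by \code{\link{clusterSubtypes}}: hierarchical clustering
#' (1 - Pearson correlation, complete linkage) of samples on the
#' region x sample matrix of average scaled log2 ratios, cut at k clusters.
#'
#' @slot labels factor of cluster labels, named by sample id.
#' @slot k integer, number of clusters.
#' @slot tree the hclust dendrogram.
#' @slot regionMatrix the (scaled) region x sample matrix clustered.
#' @export
setClass("SubtypeAssignment",
  representation(labels = "factor", k = "integer", tree = "ANY",
                 regionMatrix = "matrix"))

setValidity("SubtypeAssignment", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (nlevels(object@labels) > object@k)
    msg <- c(msg, "more labels than clusters")
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample id")
  if (length(msg)) msg else TRUE
})

#' @describeIn SubtypeAssignment sample label accessor
#' @param x a SubtypeAssignment
#' @export
setMethod("subtypeLabels", "SubtypeAssignment", function(x) x@labels)

setMethod("show", "SubtypeAssignment", function(object) {
  cat("SubtypeAssignment: ", length(object@labels), " samples in ",
      object@k, " clusters\n", sep = "")
  print(table(object@labels))
  invisible(object)
})
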