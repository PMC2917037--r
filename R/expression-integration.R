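#' @include AllClasses.R
NULL

#' Map genes to significant regions
#'
#' A gene is assigned to a region if its interval overlaps the region's
#' probe span expanded by one probe on each side (to capture borderline
#' genes); genes may map to several regions. Genes on chromosomes absent
#' from the probe map are excluded with a notice.
#'
#' @param genes named GRanges of gene coordinates.
#' @param gistic a \linkS4class{GisticResults}.
#' @param probes the GRanges probe map the regions are indexed against.
#' @param flankProbes number of probes to expand on each side (default 1).
#' @return data.frame with columns gene_id, region.
#' @export
mapGenesToRegions <- function(genes, gistic, probes, flankProbes = 1) {
  gr <- gisticRegions(gistic)
  if (!length(gr))
    return(data.frame(gene_id = character(0), region = character(0)))
  M <- length(probes)
  first <- pmax(1L, gr$probe_first - as.integer(flankProbes))
  last <- pmin(M, gr$probe_last + as.integer(flankProbes))
  # keep the flank on the region's own chromosome
  chromOf <- as.character(GenomicRanges::seqnames(probes))
  regChrom <- as.character(GenomicRanges::seqnames(gr))
  off <- chromOf[first] != regChrom
  first[off] <- gr$probe_first[off]
  off <- chromOf[last] != regChrom
  last[off] <- gr$probe_last[off]
  expanded <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = GenomicRanges::start(probes)[first],
                              end = GenomicRanges::end(probes)[last]))
  names(expanded) <- names(gr)
  bad <- is.na(GenomicRanges::start(genes))
  if (any(bad)) {
    message(sum(bad), " gene(s) without coordinates excluded")
    genes <- genes[!bad]
  }
  ov <- GenomicRanges::findOverlaps(genes, expanded, ignore.strand = TRUE)
  data.frame(gene_id = names(genes)[S4Vectors::queryHits(ov)],
             region = names(expanded)[S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Per-sample average log2 value of each region
#'
#' Mean CBS segment value over the region's probes, per sample (the
#' unscaled counterpart of \code{\link{buildRegionMatrix}}).
#'
#' @param gistic a \linkS4class{GisticResults}.
#' @param x a segmented \linkS4class{CopyNumberExperiment}.
#' @param usePeak use peak probe span (default) or the wide region span.
#' @return region x sample numeric matrix.
#' @export
regionValues <- function(gistic, x, usePeak = TRUE) {
  gr <- gisticRegions(gistic)
  if (!length(gr)) stop("no regions")
  seg <- segMeans(x)
  vals <- matrix(NA_real_, length(gr), ncol(seg),
                 dimnames = list(names(gr), colnames(seg)))
  for (r in seq_along(gr)) {
    first <- if (usePeak) gr$peak_probe_first[r] else gr$probe_first[r]
    last <- if (usePeak) gr$peak_probe_last[r] else gr$probe_last[r]
    if (last < first) stop("region ", names(gr)[r], " spans zero probes")
    vals[r, ] <- colMeans(seg[first:last, , drop = FALSE], na.rm = TRUE)
  }
  vals
}

#' Dosage correlation of gene expression with region copy number
#'
#' Pearson correlation of each mapped gene's expression with its region's
#' per-sample average log2 value. Significance cutoff r* is the upper
#' \code{alpha} quantile of the pooled null correlation distribution
#' obtained by permuting the copy-number sample labels \code{nperm} times
#' and recomputing all gene correlations. By default the rule is one-sided
#' (dosage-driven expression in the direction of the aberration): pass if
#' r >= r*; with \code{twoSided = TRUE}, |r| is compared against the
#' |r|-quantile.
#'
#' @param expr RangedSummarizedExperiment with assay \code{"exprs"}.
#' @param regionVals region x sample matrix from \code{\link{regionValues}}.
#' @param assignment gene-to-region table from
#'   \code{\link{mapGenesToRegions}}.
#' @param nperm label permutations (default 100).
#' @param alpha pass-rate target under the null (default 0.05).
#' @param seed optional integer seed.
#' @param twoSided use |r| (default FALSE).
#' @return list: \code{table} (gene_id, region, r, pass), \code{rStar},
#'   \code{nullR} pooled null correlations.
#' @export
dosageCorrelation <- function(expr, regionVals, assignment, nperm = 100,
                              alpha = 0.05, seed = NULL, twoSided = FALSE) {
  if (nperm < 100) stop("nperm must be >= 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  em <- SummarizedExperiment::assay(expr, "exprs")
  shared <- intersect(colnames(em), colnames(regionVals))
  if (length(shared) < 10) stop("need >= 10 shared samples")
  em <- em[, shared, drop = FALSE]
  rv <- regionVals[, shared, drop = FALSE]
  assignment <- assignment[assignment$gene_id %in% rownames(em) &
                             assignment$region %in% rownames(rv), ,
                           drop = FALSE]
  gv <- em[assignment$gene_id, , drop = FALSE]
  rr <- rv[assignment$region, , drop = FALSE]
  degenerate <- apply(gv, 1, stats::sd) == 0 |
    apply(rr, 1, stats::sd) == 0
  if (any(degenerate))
    message(sum(degenerate), " gene-region pair(s) with zero variance ",
            "skipped")
  rowCor <- function(a, b) {
    a <- a - rowMeans(a); b <- b - rowMeans(b)
    rowSums(a * b) / sqrt(rowSums(a * a) * rowSums(b * b))
  }
  robs <- rowCor(gv, rr)
  robs[degenerate] <- NA_real_
  ns <- length(shared)
  nullR <- matrix(NA_real_, nrow(gv), nperm)
  for (p in seq_len(nperm)) {
    perm <- sample.int(ns)
    nullR[, p] <- rowCor(gv, rr[, perm, drop = FALSE])
  }
  nullPool <- nullR[!degenerate, , drop = FALSE]
  rStar <- if (twoSided)
    stats::quantile(abs(nullPool), 1 - alpha, na.rm = TRUE, names = FALSE)
  else stats::quantile(nullPool, 1 - alpha, na.rm = TRUE, names = FALSE)
  pass <- if (twoSided) abs(robs) >= rStar else robs >= rStar
  list(table = data.frame(gene_id = assignment$gene_id,
                          region = assignment$region, r = robs,
                          pass = !is.na(pass) & pass,
                          stringsAsFactors = FALSE),
       rStar = rStar, nullR = nullPool)
}

#' Gene-wise correlation with the covering probe's CBS log2 ratio
#'
#' Each gene is matched to the probe covering it (or the nearest probe on
#' the same chromosome) and its expression correlated with that probe's
#' per-sample CBS segment value.
#'
#' @param expr RangedSummarizedExperiment with assay \code{"exprs"}.
#' @param x a segmented \linkS4class{CopyNumberExperiment}.
#' @return data.frame: gene_id, probe, r (NA for constant probes, with a
#'   notice).
#' @export
globalProbeCorrelation <- function(expr, x) {
  em <- SummarizedExperiment::assay(expr, "exprs")
  seg <- segMeans(x)
  probes <- probeMap(x)
  genes <- SummarizedExperiment::rowRanges(expr)
  shared <- intersect(colnames(em), colnames(seg))
  if (length(shared) < 10) stop("need >= 10 shared samples")
  near <- GenomicRanges::nearest(genes, probes, ignore.strand = TRUE)
  keep <- !is.na(near)
  if (any(!keep)) message(sum(!keep), " gene(s) without a matched probe ",
                          "excluded")
  r <- rep(NA_real_, length(genes))
  nskip <- 0
  for (g in which(keep)) {
    pv <- seg[near[g], shared]
    ev <- em[names(genes)[g], shared]
    if (stats::sd(pv, na.rm = TRUE) == 0 || is.na(stats::sd(pv, na.rm = TRUE))) {
      nskip <- nskip + 1; next
    }
    r[g] <- stats::cor(ev, pv, use = "complete.obs")
  }
  if (nskip) message(nskip, " gene(s) on constant probes skipped")
  data.frame(gene_id = names(genes),
             probe = ifelse(keep, names(probes)[near], NA_character_),
             r = r, stringsAsFactors = FALSE)
}

#' Score samples against a gene signature
#'
#' With a centroid, the score is the Pearson correlation of each sample's
#' listed-gene expression vector with the centroid (shift and scale
#' invariant); without one, the mean expression over the listed genes.
#'
#' @param expr RangedSummarizedExperiment with assay \code{"exprs"}.
#' @param geneList character vector of gene ids.
#' @param centroid optional named numeric per-gene reference profile.
#' @return named per-sample score vector.
#' @export
signatureScore <- function(expr, geneList, centroid = NULL) {
  em <- SummarizedExperiment::assay(expr, "exprs")
  present <- intersect(geneList, rownames(em))
  if (!length(present)) stop("no listed genes present in expression matrix")
  sub <- em[present, , drop = FALSE]
  if (is.null(centroid)) return(colMeans(sub))
  cen <- centroid[present]
  if (any(is.na(cen))) stop("centroid missing values for listed genes")
  apply(sub, 2, function(v) stats::cor(v, cen))
}
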