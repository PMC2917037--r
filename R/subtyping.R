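#' @include AllClasses.R
NULL

#' Region x sample matrix of average scaled log2 ratios
#'
#' Per region and sample, the mean CBS log2 value over the region's peak
#' probes, scaled per region across samples. The default scaling divides
#' by the region's standard deviation without centering, so the neutral
#' copy-number state stays at zero: with mean-centering ("z"), every
#' unaberrated sample shares a frequency-dependent nonzero baseline across
#' regions, and that common component dominates sample-sample correlations
#' for genomically quiet tumors, degrading subtype separation. Regions
#' constant across samples are emitted as all-zero rows with a notice.
#'
#' @param gistic a \linkS4class{GisticResults}.
#' @param x a segmented \linkS4class{CopyNumberExperiment}.
#' @param scale one of "sd" (default: divide by per-region sd, keep zero
#'   neutral), "z" (center and scale), or "none" (raw region means).
#' @return region x sample numeric matrix.
#' @export
buildRegionMatrix <- function(gistic, x, scale = c("sd", "z", "none")) {
  if (is.logical(scale)) scale <- if (scale) "sd" else "none"
  scale <- match.arg(scale)
  vals <- regionValues(gistic, x)
  if (scale == "none") return(vals)
  for (r in seq_len(nrow(vals))) {
    s <- stats::sd(vals[r, ])
    if (is.na(s) || s == 0) {
      message("region ", rownames(vals)[r],
              " constant across samples; emitted as zeros")
      vals[r, ] <- 0
    } else if (scale == "z") {
      vals[r, ] <- (vals[r, ] - mean(vals[r, ])) / s
    } else {
      vals[r, ] <- vals[r, ] / s
    }
  }
  vals
}

#' Cluster samples into genomic subtypes
#'
#' Agglomerative clustering of samples on their region vectors with
#' distance 1 - Pearson correlation and complete linkage, cut at k
#' clusters (deterministic: hclust ties resolve by sample order).
#'
#' @param regionMatrix region x sample matrix from
#'   \code{\link{buildRegionMatrix}}.
#' @param k number of clusters (default 6).
#' @return a \linkS4class{SubtypeAssignment} with labels C1..Ck (ordered by
#'   cluster size, largest first).
#' @export
clusterSubtypes <- function(regionMatrix, k = 6) {
  k <- as.integer(k)
  if (k > ncol(regionMatrix)) stop("k exceeds sample count")
  sds <- apply(regionMatrix, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region vector for sample(s): ",
         paste(colnames(regionMatrix)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(regionMatrix))
  tree <- stats::hclust(d, method = "complete")
  cut <- stats::cutree(tree, k = k)
  sizes <- sort(table(cut), decreasing = TRUE)
  relab <- stats::setNames(paste0("C", seq_len(k)), names(sizes))
  labels <- factor(relab[as.character(cut)],
                   levels = paste0("C", seq_len(k)))
  names(labels) <- colnames(regionMatrix)
  new("SubtypeAssignment", labels = labels, k = k, tree = tree,
      regionMatrix = regionMatrix)
}

#' Name clusters by matching archetype aberration templates
#'
#' Each archetype's expected per-probe log2 profile (event probability x
#' amplitude, marginalizing conditional events) is summarized over the
#' significant regions and correlated with each cluster's mean raw region
#' profile; clusters are greedily assigned the best-matching archetype
#' name (highest correlation first).
#'
#' @param assignment a \linkS4class{SubtypeAssignment}.
#' @param gistic the \linkS4class{GisticResults} the region matrix came
#'   from.
#' @param x the segmented \linkS4class{CopyNumberExperiment}.
#' @param archetypes archetype list (default \code{defaultArchetypes()}).
#' @return named character vector cluster -> archetype name; attribute
#'   \code{"labels"} carries the relabeled per-sample factor.
#' @export
matchArchetypeNames <- function(assignment, gistic, x,
                                archetypes = defaultArchetypes()) {
  probes <- probeMap(x)
  cat2 <- .regionCatalog()
  M <- length(probes)
  templates <- vapply(archetypes, function(a) {
    prof <- numeric(M)
    ev <- a$events
    for (i in seq_len(nrow(ev))) {
      idx <- .probesInInterval(probes,
                               cat2$chrom[match(ev$region[i], cat2$region)],
                               cat2$lo[match(ev$region[i], cat2$region)],
                               cat2$hi[match(ev$region[i], cat2$region)])
      p <- ev$prob[i]
      if (!is.na(ev$given[i])) {  # marginal probability of conditional event
        gi <- which(ev$region == ev$given[i])[1]
        pg <- if (!is.na(gi)) ev$prob[gi] else 0
        p <- pg * ev$prob_given[i] + (1 - pg) * ev$prob[i]
      }
      prof[idx] <- prof[idx] + p * ev$mean[i]
    }
    prof
  }, numeric(M))
  gr <- gisticRegions(gistic)
  regTemplates <- vapply(seq_along(gr), function(r)
    colMeans(templates[gr$peak_probe_first[r]:gr$peak_probe_last[r], ,
                       drop = FALSE]), numeric(length(archetypes)))
  raw <- regionValues(gistic, x)
  labels <- subtypeLabels(assignment)
  clusterMeans <- vapply(levels(labels), function(cl)
    rowMeans(raw[, labels == cl, drop = FALSE]), numeric(nrow(raw)))
  cors <- suppressWarnings(stats::cor(clusterMeans, t(regTemplates)))
  cors[is.na(cors)] <- -1  # constant template or cluster profile
  mapping <- stats::setNames(rep(NA_character_, nlevels(labels)),
                             levels(labels))
  pool <- cors
  for (i in seq_len(min(nrow(cors), ncol(cors)))) {
    best <- which(pool == max(pool, na.rm = TRUE), arr.ind = TRUE)[1, ]
    mapping[rownames(pool)[best[1]]] <- colnames(pool)[best[2]]
    pool[best[1], ] <- NA; pool[, best[2]] <- NA
  }
  mapping[is.na(mapping)] <- names(mapping)[is.na(mapping)]
  out <- mapping
  relab <- factor(unname(mapping[as.character(labels)]),
                  levels = unique(unname(mapping)))
  names(relab) <- names(labels)
  attr(out, "labels") <- relab
  out
}

#' Regions differing between two sample groups
#'
#' Per region, a two-sample Welch t-test on the scaled region values,
#' Bonferroni-adjusted over tested regions; retained are regions with
#' adjusted P below \code{pCut} whose aberration frequency (calls matching
#' the region's direction at its peak) reaches \code{freqCut} in at least
#' one group, annotated with the more-aberrant group.
#'
#' @param regionMatrix scaled region x sample matrix.
#' @param groups factor/vector of two group labels, named by or aligned to
#'   samples.
#' @param gistic the \linkS4class{GisticResults}.
#' @param x the called \linkS4class{CopyNumberExperiment}.
#' @param freqCut minimum per-group aberration frequency (default 0.2).
#' @param pCut adjusted-P threshold (default 0.05).
#' @param pooledVar use the pooled-variance t-test instead of Welch.
#' @return data.frame: region, t, p, p_adj, mean_diff, direction,
#'   higher_group, freq per group.
#' @export
supervisedRegionTests <- function(regionMatrix, groups, gistic, x,
                                  freqCut = 0.2, pCut = 0.05,
                                  pooledVar = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("both groups need >= 2 samples")
  gA <- levels(groups)[1]; gB <- levels(groups)[2]
  calls <- cnCalls(x)
  gr <- gisticRegions(gistic)
  res <- lapply(rownames(regionMatrix), function(rn) {
    v <- regionMatrix[rn, ]
    a <- v[groups == gA]; b <- v[groups == gB]
    if (stats::sd(c(a, b)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- tryCatch(stats::t.test(a, b, var.equal = pooledVar),
                     error = function(e)  # both groups internally constant
                       list(statistic = Inf * sign(mean(a) - mean(b)),
                            p.value = 0))
    }
    r <- match(rn, names(gr))
    mode <- gr$peak_probe_first[r]
    want <- if (gr$kind[r] == "gain") 1L else -1L
    st <- calls[mode, ]
    fA <- mean(st[groups == gA] == want, na.rm = TRUE)
    fB <- mean(st[groups == gB] == want, na.rm = TRUE)
    md <- mean(a) - mean(b)
    data.frame(region = rn, t = unname(tt$statistic),
               p = tt$p.value, mean_diff = md,
               direction = gr$kind[r],
               higher_group = if ((md > 0) == (want == 1L)) gA else gB,
               freq_A = fA, freq_B = fB, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  keep <- out$p_adj < pCut & pmax(out$freq_A, out$freq_B) >= freqCut
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("region", "t", "p", "p_adj", "mean_diff", "direction",
          "higher_group", "freq_A", "freq_B")]
}

#' Per-subtype gene-expression centroids
#'
#' For each subtype, the mean expression over member samples, restricted
#' to a supplied gene list; genes absent from the expression matrix are
#' dropped from all centroids symmetrically.
#'
#' @param expr RangedSummarizedExperiment with assay \code{"exprs"}.
#' @param assignment \linkS4class{SubtypeAssignment} or named label
#'   factor.
#' @param geneList character vector of gene ids.
#' @return gene x subtype numeric matrix.
#' @export
buildCentroids <- function(expr, assignment, geneList) {
  labels <- if (is(assignment, "SubtypeAssignment"))
    subtypeLabels(assignment) else assignment
  em <- SummarizedExperiment::assay(expr, "exprs")
  genes <- intersect(geneList, rownames(em))
  if (!length(genes)) stop("no listed genes present in expression matrix")
  shared <- intersect(colnames(em), names(labels))
  cents <- list()
  for (cl in levels(factor(labels))) {
    members <- intersect(shared, names(labels)[labels == cl])
    if (!length(members)) {
      message("subtype ", cl, " has no expression samples; excluded")
      next
    }
    cents[[cl]] <- rowMeans(em[genes, members, drop = FALSE])
  }
  do.call(cbind, cents)
}

#' Nearest-centroid classification of expression samples
#'
#' Each sample gets the label of the centroid with maximal Pearson
#' correlation over shared genes; if \code{minR} is given and no centroid
#' reaches it, the sample is "unclassified". Ties resolve to the first
#' centroid in column order (logged).
#'
#' @param expr RangedSummarizedExperiment (or plain matrix) of samples to
#'   classify.
#' @param centroids gene x subtype matrix from \code{\link{buildCentroids}}.
#' @param minR optional minimum correlation.
#' @return list: \code{label} named character vector, \code{correlations}
#'   sample x subtype matrix.
#' @export
classifyByCentroid <- function(expr, centroids, minR = NULL) {
  em <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "exprs") else as.matrix(expr)
  genes <- intersect(rownames(centroids), rownames(em))
  if (length(genes) < 5) stop("fewer than 5 shared genes with centroids")
  cors <- stats::cor(em[genes, , drop = FALSE],
                     centroids[genes, , drop = FALSE])
  label <- apply(cors, 1, function(v) {
    best <- which(v == max(v))
    if (length(best) > 1)
      message("centroid tie; resolved by declared order")
    colnames(cors)[best[1]]
  })
  if (!is.null(minR)) label[apply(cors, 1, max) < minR] <- "unclassified"
  list(label = label, correlations = cors)
}
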