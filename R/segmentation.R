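#' @include AllClasses.R
NULL

# Recursive circular binary segmentation of one chromosome's non-missing
# values (indices into the full probe vector are carried along).
.cbsChromosome <- function(vals, alpha, nperm, minSeg = 2L) {
  n <- length(vals)
  bounds <- list()
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len >= 2L * minSeg) {
      res <- .cbs_split_test(vals[lo:hi], nperm, alpha, minSeg)
      if (isTRUE(res$significant)) {
        i <- res$i; j <- res$j  # arc covers local probes i+1 .. j (1-based)
        pieces <- integer(0)
        if (i > 0L) pieces <- c(pieces, lo, lo + i - 1L)
        pieces <- c(pieces, lo + i, lo + j - 1L)
        if (j < len) pieces <- c(pieces, lo + j, hi)
        for (k in seq(1, length(pieces), by = 2))
          recurse(pieces[k], pieces[k + 1])
        return(invisible(NULL))
      }
    }
    bounds[[length(bounds) + 1L]] <<- c(lo, hi)
    invisible(NULL)
  }
  recurse(1L, n)
  b <- do.call(rbind, bounds)
  b[order(b[, 1]), , drop = FALSE]
}

#' Segment one log2 profile by circular binary segmentation
#'
#' Recursive circular binary splits per chromosome: the maximal circular-arc
#' t statistic is referred to a within-segment permutation distribution
#' (\code{nperm} draws, seeded through R's RNG); splits are accepted at
#' p < \code{alpha}, and no change-point creating a segment of fewer than 2
#' probes is considered. Missing probes are excluded and retain NA segment
#' means.
#'
#' @param x numeric per-probe log2 vector (NA allowed), in probe-map order.
#' @param probes named GRanges probe map aligned to \code{x}.
#' @param alpha split significance level (default 0.01).
#' @param nperm permutations per split test (default 1000).
#' @param sampleId sample id recorded in the segment table.
#' @param seed optional integer seed (set once before all tests).
#' @return list with \code{segments} (data.frame: sample_id, chrom, start,
#'   end, n_probes, seg_mean) and \code{segMean} (per-probe segment-mean
#'   vector, NA at missing probes).
#' @export
cbsSegment <- function(x, probes, alpha = 0.01, nperm = 1000,
                       sampleId = "sample", seed = NULL) {
  stopifnot(length(x) == length(probes), alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  chrom <- as.character(GenomicRanges::seqnames(probes))
  segMean <- rep(NA_real_, length(x))
  rows <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ok <- idx[!is.na(x[idx])]
    if (length(ok) == 0) {
      message("chromosome ", ch, " all missing for ", sampleId, "; skipped")
      next
    }
    if (length(ok) == 1) {
      b <- matrix(c(1L, 1L), nrow = 1)
    } else {
      b <- .cbsChromosome(x[ok], alpha, nperm)
    }
    for (r in seq_len(nrow(b))) {
      members <- ok[b[r, 1]:b[r, 2]]
      m <- mean(x[members])
      segMean[members] <- m
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sampleId, chrom = ch,
        start = GenomicRanges::start(probes)[members[1]],
        end = GenomicRanges::end(probes)[members[length(members)]],
        n_probes = length(members), seg_mean = m,
        stringsAsFactors = FALSE)
    }
  }
  list(segments = do.call(rbind, rows), segMean = segMean)
}

#' Segment every sample of a cohort
#'
#' Runs \code{\link{cbsSegment}} per sample and stores the per-probe segment
#' means as assay \code{"seg"} and the pooled segment table in
#' \code{metadata(x)$segments}.
#'
#' @param x a \linkS4class{CopyNumberExperiment}.
#' @param alpha,nperm see \code{\link{cbsSegment}}.
#' @param seed integer seed for the permutation reference (default 1).
#' @return the updated \linkS4class{CopyNumberExperiment}.
#' @export
segmentCohort <- function(x, alpha = 0.01, nperm = 1000, seed = 1) {
  set.seed(as.integer(seed))
  lr <- log2Ratios(x)
  probes <- probeMap(x)
  seg <- matrix(NA_real_, nrow(lr), ncol(lr), dimnames = dimnames(lr))
  tabs <- vector("list", ncol(lr))
  for (s in seq_len(ncol(lr))) {
    res <- cbsSegment(lr[, s], probes, alpha = alpha, nperm = nperm,
                      sampleId = colnames(lr)[s])
    seg[, s] <- res$segMean
    tabs[[s]] <- res$segments
  }
  SummarizedExperiment::assay(x, "seg") <- seg
  S4Vectors::metadata(x)$segments <- do.call(rbind, tabs)
  S4Vectors::metadata(x)$cbs_params <- list(alpha = alpha, nperm = nperm,
                                            seed = seed)
  x
}

#' Positional smoothing of a log2 profile
#'
#' Replaces each probe's value by the mean of all non-missing probes whose
#' midpoints lie within +/- \code{windowBp}/2 of its midpoint, within the
#' same chromosome (250-kb default window).
#'
#' @param x per-probe numeric vector.
#' @param probes aligned GRanges probe map.
#' @param windowBp full window width in bp (default 250000).
#' @return smoothed numeric vector (NA where input is NA).
#' @export
smoothWindow <- function(x, probes, windowBp = 250000) {
  stopifnot(windowBp > 0, length(x) == length(probes))
  chrom <- as.character(GenomicRanges::seqnames(probes))
  mid <- .probeMid(probes)
  out <- rep(NA_real_, length(x))
  half <- windowBp / 2
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- mid[idx]; v <- x[idx]
    good <- !is.na(v)
    cs <- cumsum(ifelse(good, v, 0))
    cn <- cumsum(good)
    lo <- findInterval(m - half, m, left.open = TRUE) + 1L
    hi <- findInterval(m + half, m)
    sum0 <- function(p) ifelse(p >= 1, cs[pmax(p, 1)], 0)
    cnt0 <- function(p) ifelse(p >= 1, cn[pmax(p, 1)], 0)
    tot <- sum0(hi) - sum0(lo - 1L)
    cnt <- cnt0(hi) - cnt0(lo - 1L)
    out[idx] <- ifelse(cnt > 0, tot / cnt, NA_real_)
    out[idx][is.na(v)] <- NA_real_
  }
  out
}

#' Sample-adaptive gain/loss thresholds
#'
#' Robust noise-scale rule on positionally smoothed data: with s the
#' Gaussian-consistent MAD of the smoothed values about their median,
#' tau_gain = median + max(k*s, tauMin) and tau_loss = median -
#' max(k*s, tauMin).
#'
#' @param smoothed smoothed per-probe vector (e.g. \code{smoothWindow}).
#' @param k noise-scale multiplier (default 2.5).
#' @param tauMin minimum log2 offset from the median (default 0.1).
#' @return named numeric c(tau_gain, tau_loss).
#' @export
adaptiveThresholds <- function(smoothed, k = 2.5, tauMin = 0.1) {
  v <- smoothed[!is.na(smoothed)]
  if (length(v) < 10)
    stop("need >= 10 non-missing smoothed values (got ", length(v), ")")
  med <- stats::median(v)
  s <- stats::mad(v, center = med)  # 1.4826 * MAD
  off <- max(k * s, tauMin)
  c(tau_gain = med + off, tau_loss = med - off)
}

#' Discrete gain/loss calls from segment means
#'
#' Per-probe state from its CBS segment mean: gain if >= tau_gain, loss if
#' <= tau_loss, else neutral; probes in segments spanning fewer than
#' \code{minProbes} probes are forced neutral. High-level amplification is
#' flagged where a called gain's segment mean reaches \code{ampCut}.
#'
#' @param segMean per-probe segment-mean vector.
#' @param segments segment table for this sample (from
#'   \code{\link{cbsSegment}}).
#' @param thresholds c(tau_gain, tau_loss) from
#'   \code{\link{adaptiveThresholds}}.
#' @param probes aligned GRanges probe map.
#' @param ampCut high-level amplification cut in log2 (default 1.0).
#' @param minProbes minimum probes per usable segment (default 4).
#' @return list: \code{state} integer vector (-1 loss, 0 neutral, 1 gain,
#'   NA missing), \code{highAmp} logical vector, \code{thresholds}.
#' @export
callStates <- function(segMean, segments, thresholds, probes,
                       ampCut = 1.0, minProbes = 4) {
  stopifnot(length(segMean) == length(probes))
  state <- ifelse(segMean >= thresholds[["tau_gain"]], 1L,
                  ifelse(segMean <= thresholds[["tau_loss"]], -1L, 0L))
  # neutralize small segments
  if (!is.null(segments) && nrow(segments)) {
    small <- segments[segments$n_probes < minProbes, , drop = FALSE]
    if (nrow(small)) {
      chrom <- as.character(GenomicRanges::seqnames(probes))
      pstart <- GenomicRanges::start(probes)
      for (r in seq_len(nrow(small))) {
        hit <- chrom == small$chrom[r] & pstart >= small$start[r] &
          pstart <= small$end[r]
        state[hit] <- 0L
      }
    }
  }
  state[is.na(segMean)] <- NA_integer_
  highAmp <- !is.na(state) & state == 1L & segMean >= ampCut
  list(state = state, highAmp = highAmp, thresholds = thresholds)
}

#' Call gains and losses across a segmented cohort
#'
#' For each sample: smooth the raw log2 ratios (250-kb window), derive
#' adaptive thresholds, and call per-probe states from the CBS segment
#' means. Stores assay \code{"calls"} (-1/0/1) and per-sample thresholds in
#' \code{colData}.
#'
#' @param x a segmented \linkS4class{CopyNumberExperiment}.
#' @param windowBp smoothing window. The default (NULL) is
#'   resolution-aware: the larger of 250 kb and five median probe
#'   spacings, so that the window always averages the same ~5-probe
#'   neighborhood a 250-kb window covers on a densely tiled (~100-kb
#'   spacing) BAC array.
#' @param k,tauMin threshold parameters, see
#'   \code{\link{adaptiveThresholds}}.
#' @param ampCut,minProbes see \code{\link{callStates}}.
#' @return the updated \linkS4class{CopyNumberExperiment}.
#' @export
callCohort <- function(x, windowBp = NULL, k = 2.5, tauMin = 0.1,
                       ampCut = 1.0, minProbes = 4) {
  lr <- log2Ratios(x)
  seg <- segMeans(x)
  segtab <- segmentTable(x)
  probes <- probeMap(x)
  if (is.null(windowBp)) {
    mids <- .probeMid(probes)
    chr <- as.character(GenomicRanges::seqnames(probes))
    sameChr <- chr[-1] == chr[-length(chr)]
    spacing <- stats::median(diff(mids)[sameChr])
    windowBp <- max(250000, 5 * spacing)
  }
  calls <- matrix(NA_integer_, nrow(lr), ncol(lr), dimnames = dimnames(lr))
  tg <- tl <- numeric(ncol(lr))
  for (s in seq_len(ncol(lr))) {
    sm <- smoothWindow(lr[, s], probes, windowBp)
    th <- adaptiveThresholds(sm, k = k, tauMin = tauMin)
    cs <- callStates(seg[, s],
                     segtab[segtab$sample_id == colnames(lr)[s], ,
                            drop = FALSE],
                     th, probes, ampCut = ampCut, minProbes = minProbes)
    calls[, s] <- cs$state
    tg[s] <- th[["tau_gain"]]; tl[s] <- th[["tau_loss"]]
  }
  SummarizedExperiment::assay(x, "calls") <- calls
  SummarizedExperiment::colData(x)$tau_gain <- tg
  SummarizedExperiment::colData(x)$tau_loss <- tl
  S4Vectors::metadata(x)$call_params <- list(windowBp = windowBp, k = k,
                                             tauMin = tauMin, ampCut = ampCut,
                                             minProbes = minProbes)
  x
}

#' High-level amplification flags per probe
#'
#' @param x a called \linkS4class{CopyNumberExperiment}.
#' @param ampCut log2 cut (default 1.0).
#' @return logical matrix, TRUE where a called gain has segment mean >=
#'   \code{ampCut}.
#' @export
highAmpCalls <- function(x, ampCut = 1.0) {
  calls <- cnCalls(x)
  seg <- segMeans(x)
  !is.na(calls) & calls == 1L & !is.na(seg) & seg >= ampCut
}

#' Fraction of the genome altered
#'
#' Probe-count-weighted altered fractions per sample: gained, lost, and
#' total (their sum), over non-missing called probes. Set
#' \code{weightBp = TRUE} to weight probes by their bp footprint instead.
#'
#' @param x a called \linkS4class{CopyNumberExperiment}, or an integer state
#'   vector for a single sample.
#' @param weightBp weight by probe length rather than probe count.
#' @return data.frame with columns fga, fga_gain, fga_loss (one row per
#'   sample).
#' @export
fga <- function(x, weightBp = FALSE) {
  if (is(x, "CopyNumberExperiment")) {
    calls <- cnCalls(x)
    w <- if (weightBp) GenomicRanges::width(probeMap(x)) else
      rep(1, nrow(calls))
  } else {
    calls <- matrix(as.integer(x), ncol = 1)
    w <- rep(1, nrow(calls))
  }
  res <- t(vapply(seq_len(ncol(calls)), function(s) {
    st <- calls[, s]
    ok <- !is.na(st)
    if (!any(ok)) stop("no non-missing called probes for sample ",
                       colnames(calls)[s])
    tot <- sum(w[ok])
    g <- sum(w[ok & st == 1L]) / tot
    l <- sum(w[ok & st == -1L]) / tot
    c(fga = g + l, fga_gain = g, fga_loss = l)
  }, numeric(3)))
  out <- as.data.frame(res)
  rownames(out) <- colnames(calls)
  out
}
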