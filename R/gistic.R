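#' @include AllClasses.R
NULL

# Per-probe, per-sample score contributions for one aberration kind:
# |segment mean| where the probe is called in that direction (amplitude
# capped), else 0. G is the row sum: frequency x average amplitude.
.gisticContrib <- function(seg, calls, kind, cap = 2.0) {
  if (!kind %in% c("gain", "loss")) stop("kind must be 'gain' or 'loss'")
  want <- if (kind == "gain") 1L else -1L
  contrib <- ifelse(!is.na(calls) & calls == want & !is.na(seg),
                    pmin(abs(seg), cap), 0)
  dimnames(contrib) <- dimnames(seg)
  contrib
}

#' Per-probe G-scores for recurrent gains or losses
#'
#' G(probe) = sum over samples called aberrant (in the requested direction)
#' of their |segment mean| at that probe, capped at \code{cap} to limit
#' single-sample dominance.
#'
#' @param seg probe x sample matrix of CBS segment means.
#' @param calls probe x sample integer matrix of states (-1/0/1).
#' @param kind "gain" or "loss".
#' @param cap amplitude ceiling in log2 units (default 2.0).
#' @return numeric per-probe G-score vector.
#' @export
gscore <- function(seg, calls, kind, cap = 2.0) {
  rowSums(.gisticContrib(seg, calls, kind, cap))
}

#' Permutation null and p-values for G-scores
#'
#' The null preserves within-sample segmental structure and aberration
#' load: each sample's per-probe contribution profile is cyclically shifted
#' by an independent uniform offset; p(m) = (1 + #\{perm G(m) >= observed
#' G(m)\}) / (nperm + 1).
#'
#' @param seg,calls,kind,cap as in \code{\link{gscore}}.
#' @param nperm number of shift permutations (default 1000, minimum 100).
#' @param seed optional integer seed.
#' @param returnNull also return the probe x nperm null score matrix.
#' @return list: \code{G} observed scores, \code{p} per-probe p-values, and
#'   (optionally) \code{null}.
#' @export
gisticPermutationNull <- function(seg, calls, kind, nperm = 1000,
                                  cap = 2.0, seed = NULL,
                                  returnNull = FALSE) {
  if (nperm < 100) stop("nperm must be >= 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  contrib <- .gisticContrib(seg, calls, kind, cap)
  G <- rowSums(contrib)
  nullG <- .gistic_null_G(contrib, as.integer(nperm))
  p <- (1 + rowSums(nullG >= G - 1e-12)) / (nperm + 1)
  out <- list(G = G, p = p)
  if (returnNull) out$null <- nullG
  out
}

#' Benjamini-Hochberg q-values
#'
#' @param p vector of p-values in (0, 1].
#' @return monotone BH-adjusted q-values.
#' @export
qValues <- function(p) stats::p.adjust(p, method = "BH")

# Merge regions of the same kind and chromosome whose peak probe spans are
# separated by fewer than mergeGap probes.
.mergeRegions <- function(reg, mergeGap) {
  if (nrow(reg) < 2) return(reg)
  out <- list()
  for (kd in unique(reg$kind)) for (ch in unique(reg$chrom)) {
    sub <- reg[reg$kind == kd & reg$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$peak_probe_first), , drop = FALSE]
    cur <- sub[1, , drop = FALSE]
    for (r in seq_len(nrow(sub))[-1]) {
      nxt <- sub[r, , drop = FALSE]
      if (nxt$peak_probe_first - cur$peak_probe_last <= mergeGap) {
        cur$peak_probe_last <- max(cur$peak_probe_last, nxt$peak_probe_last)
        cur$probe_first <- min(cur$probe_first, nxt$probe_first)
        cur$probe_last <- max(cur$probe_last, nxt$probe_last)
        cur$peak_end <- max(cur$peak_end, nxt$peak_end)
        cur$peak_start <- min(cur$peak_start, nxt$peak_start)
        cur$start <- min(cur$start, nxt$start)
        cur$end <- max(cur$end, nxt$end)
        cur$Gscore <- max(cur$Gscore, nxt$Gscore)
        cur$q <- min(cur$q, nxt$q)
        cur$freq <- max(cur$freq, nxt$freq)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

# Monotone step mapping p -> q frozen from the initial genome-wide BH
# adjustment; re-scored probes during peel-off are mapped through it so the
# multiplicity correction stays that of the original scan.
.qMap <- function(p0) {
  q0 <- qValues(p0)
  ord <- order(p0)
  ps <- p0[ord]; qs <- q0[ord]
  keep <- !duplicated(ps)
  ps <- ps[keep]; qs <- qs[keep]
  function(p) {
    idx <- findInterval(p, ps)  # largest ps <= p
    out <- qs[pmax(idx, 1)]
    out[idx == 0] <- qs[1]
    pmin(out, 1)
  }
}

# Iterative peak extraction with peel-off for one kind.
.peelOffKind <- function(contrib, nullG, probes, kind, nperm, qThreshold,
                         plateau, mergeGap, maxRegions = 500L) {
  chrom <- as.character(GenomicRanges::seqnames(probes))
  pstart <- GenomicRanges::start(probes)
  pend <- GenomicRanges::end(probes)
  G <- rowSums(contrib)
  p <- (1 + rowSums(nullG >= G - 1e-12)) / (nperm + 1)
  qmap <- .qMap(p)
  q <- qmap(p)
  regions <- list()
  while (length(regions) < maxRegions) {
    sig <- which(q < qThreshold & G > 0)
    if (!length(sig)) break
    m <- sig[which.max(G[sig])]
    ch <- chrom[m]
    onchr <- which(chrom == ch)
    # peak: contiguous run through m with G within plateau of the maximum
    inPeak <- onchr[G[onchr] >= plateau * G[m]]
    runs <- cumsum(c(1, diff(inPeak) != 1))
    peak <- inPeak[runs == runs[match(m, inPeak)]]
    # wide region: contiguous run of q < threshold through m
    inWide <- onchr[q[onchr] < qThreshold]
    wruns <- cumsum(c(1, diff(inWide) != 1))
    wide <- inWide[wruns == wruns[match(m, inWide)]]
    drivers <- which(contrib[m, ] > 0)
    regions[[length(regions) + 1L]] <- data.frame(
      kind = kind, chrom = ch,
      start = pstart[wide[1]], end = pend[wide[length(wide)]],
      peak_start = pstart[peak[1]], peak_end = pend[peak[length(peak)]],
      probe_first = wide[1], probe_last = wide[length(wide)],
      peak_probe_first = peak[1], peak_probe_last = peak[length(peak)],
      Gscore = G[m], q = q[m],
      freq = length(drivers) / ncol(contrib),
      stringsAsFactors = FALSE)
    # peel off: remove the driving samples' aberrations on this chromosome
    contrib[onchr, drivers] <- 0
    G[onchr] <- rowSums(contrib[onchr, , drop = FALSE])
    p[onchr] <- (1 + rowSums(nullG[onchr, , drop = FALSE] >=
                               G[onchr] - 1e-12)) / (nperm + 1)
    q[onchr] <- qmap(p[onchr])
  }
  if (!length(regions)) return(NULL)
  .mergeRegions(do.call(rbind, regions), mergeGap)
}

#' Score recurrent copy-number aberrations (GISTIC-style)
#'
#' Computes per-probe gain and loss G-scores, permutation p-values from the
#' cyclic-shift null, BH q-values, and extracts independent peaks by
#' iterative peel-off: the maximal-G probe defines a peak (contiguous run
#' within \code{plateau} of the local maximum) and a wide region
#' (surrounding run with q below threshold); the driving samples'
#' aberrations on that chromosome are removed, scores and significance
#' recomputed, until nothing exceeds the threshold. Peaks of the same kind
#' closer than \code{mergeGap} probes are merged.
#'
#' @param x a segmented and called \linkS4class{CopyNumberExperiment}.
#' @param nperm permutations (default 1000).
#' @param qThreshold q-value retention threshold (default 0.25).
#' @param cap amplitude ceiling (default 2.0).
#' @param plateau peak plateau fraction of local maximum (default 0.95).
#' @param mergeGap merge peaks closer than this many probes (default 5).
#' @param seed integer seed for the permutation null (default 1).
#' @return a \linkS4class{GisticResults}.
#' @export
runGistic <- function(x, nperm = 1000, qThreshold = 0.25, cap = 2.0,
                      plateau = 0.95, mergeGap = 5, seed = 1) {
  seg <- segMeans(x)
  calls <- cnCalls(x)
  probes <- probeMap(x)
  tabs <- list()
  stats <- S4Vectors::DataFrame(row.names = rownames(seg))
  for (kind in c("gain", "loss")) {
    # identical shift stream for both kinds: gain/loss analyses are exact
    # mirrors under negation of the input
    set.seed(as.integer(seed))
    contrib <- .gisticContrib(seg, calls, kind, cap)
    nullG <- .gistic_null_G(contrib, as.integer(nperm))
    G <- rowSums(contrib)
    p <- (1 + rowSums(nullG >= G - 1e-12)) / (nperm + 1)
    stats[[paste0("G_", kind)]] <- G
    stats[[paste0("p_", kind)]] <- p
    stats[[paste0("q_", kind)]] <- qValues(p)
    tabs[[kind]] <- .peelOffKind(contrib, nullG, probes, kind, nperm,
                                 qThreshold, plateau, mergeGap)
  }
  reg <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  if (is.null(reg)) {
    gr <- GenomicRanges::GRanges()
  } else {
    ord <- order(match(reg$chrom, .validChroms()), reg$start,
                 reg$kind)
    reg <- reg[ord, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = factor(reg$chrom, levels = .validChroms()),
      ranges = IRanges::IRanges(start = reg$start, end = reg$end))
    S4Vectors::mcols(gr) <- reg[, c("kind", "peak_start", "peak_end",
                                    "probe_first", "probe_last",
                                    "peak_probe_first", "peak_probe_last",
                                    "Gscore", "q", "freq")]
    names(gr) <- sprintf("%s_%s_%.1fMb", reg$kind, reg$chrom,
                         reg$peak_start / 1e6)
  }
  new("GisticResults", regions = gr, probeStats = stats,
      params = list(nperm = nperm, qThreshold = qThreshold, cap = cap,
                    plateau = plateau, mergeGap = mergeGap, seed = seed))
}

#' Export a GISTIC region table as TSV
#'
#' @param gistic a \linkS4class{GisticResults}.
#' @param path output path.
#' @export
writeGisticRegions <- function(gistic, path) {
  gr <- gisticRegions(gistic)
  df <- data.frame(region = if (length(gr)) names(gr) else character(0),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   as.data.frame(S4Vectors::mcols(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
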