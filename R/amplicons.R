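#' @include AllClasses.R
NULL

# Per-sample maximal runs of probes with segment mean >= ampCut, as probe
# index intervals.
.ampliconRuns <- function(seg, ampCut) {
  runs <- list()
  for (s in seq_len(ncol(seg))) {
    hit <- which(!is.na(seg[, s]) & seg[, s] >= ampCut)
    if (!length(hit)) next
    grp <- cumsum(c(1, diff(hit) != 1))
    for (g in unique(grp)) {
      r <- hit[grp == g]
      runs[[length(runs) + 1L]] <- data.frame(
        sample = colnames(seg)[s], first = r[1], last = r[length(r)])
    }
  }
  if (length(runs)) do.call(rbind, runs) else NULL
}

#' Catalog recurrent high-level amplicons
#'
#' Per sample, maximal probe runs with CBS segment mean >= \code{ampCut}
#' become amplified intervals; intervals are clustered across samples by
#' single-linkage probe overlap into loci (runs on different chromosomes
#' never overlap). Loci observed in more than \code{recurrence} of samples
#' are retained and annotated with the significant gain region (if any)
#' containing the locus's most frequently amplified probe.
#'
#' @param x a segmented \linkS4class{CopyNumberExperiment}.
#' @param ampCut amplification cut in log2 (default 1.0).
#' @param recurrence minimum cohort frequency, exclusive (default 0.01).
#' @param gistic optional \linkS4class{GisticResults} for gain-region
#'   annotation.
#' @return data.frame: locus id, chrom, start, end (bp), probe_first,
#'   probe_last, n_carriers, frequency, carriers (comma-joined sample ids),
#'   gistic_region (or NA).
#' @export
detectAmplicons <- function(x, ampCut = 1.0, recurrence = 0.01,
                            gistic = NULL) {
  seg <- segMeans(x)
  probes <- probeMap(x)
  runs <- .ampliconRuns(seg, ampCut)
  empty <- data.frame(locus = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      probe_first = integer(0), probe_last = integer(0),
                      n_carriers = integer(0), frequency = numeric(0),
                      carriers = character(0), gistic_region = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(runs)) return(empty)
  # single-linkage clustering by >=1 probe overlap (union-find)
  n <- nrow(runs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ord <- order(runs$first)
  ro <- runs[ord, , drop = FALSE]
  maxLast <- ro$last[1]; head <- ord[1]
  for (t in seq_len(n)[-1]) {
    if (ro$first[t] <= maxLast) {
      parent[find(ord[t])] <- find(head)
    } else {
      head <- ord[t]
    }
    maxLast <- max(maxLast, ro$last[t])
  }
  grp <- vapply(seq_len(n), find, integer(1))
  nSamples <- ncol(seg)
  chrom <- as.character(GenomicRanges::seqnames(probes))
  loci <- lapply(unique(grp), function(g) {
    sub <- runs[grp == g, , drop = FALSE]
    carriers <- unique(sub$sample)
    pf <- min(sub$first); pl <- max(sub$last)
    cov <- integer(pl - pf + 1)
    for (r in seq_len(nrow(sub)))
      cov[(sub$first[r]:sub$last[r]) - pf + 1] <-
        cov[(sub$first[r]:sub$last[r]) - pf + 1] + 1L
    mode <- pf + which.max(cov) - 1L
    data.frame(chrom = chrom[pf],
               start = GenomicRanges::start(probes)[pf],
               end = GenomicRanges::end(probes)[pl],
               probe_first = pf, probe_last = pl, mode_probe = mode,
               n_carriers = length(carriers),
               frequency = length(carriers) / nSamples,
               carriers = paste(sort(carriers), collapse = ","),
               stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, loci)
  cat <- cat[cat$frequency > recurrence, , drop = FALSE]
  if (!nrow(cat)) return(empty)
  cat <- cat[order(match(cat$chrom, .validChroms()), cat$start), ,
             drop = FALSE]
  cat$locus <- sprintf("amp_%s_%.1fMb", cat$chrom, cat$start / 1e6)
  cat$gistic_region <- NA_character_
  if (!is.null(gistic)) {
    gr <- gisticRegions(gistic)
    gains <- gr[gr$kind == "gain"]
    if (length(gains)) {
      for (r in seq_len(nrow(cat))) {
        hit <- which(gains$probe_first <= cat$mode_probe[r] &
                       gains$probe_last >= cat$mode_probe[r])
        if (length(hit)) cat$gistic_region[r] <- names(gains)[hit[1]]
      }
    }
  }
  rownames(cat) <- NULL
  cat[, c("locus", "chrom", "start", "end", "probe_first", "probe_last",
          "mode_probe", "n_carriers", "frequency", "carriers",
          "gistic_region")]
}

#' Directed coamplification fractions between amplicon loci
#'
#' Entry (A, B) is the fraction of A's carriers that also carry B. Loci
#' with fewer than \code{minCarriers} carriers are excluded. The raw
#' matrix is returned together with a display-masked copy in which
#' fractions below \code{displayCut} are NA.
#'
#' @param catalog amplicon catalog from \code{\link{detectAmplicons}}.
#' @param minCarriers minimum carriers per locus (default 3).
#' @param displayCut display mask threshold (default 0.2).
#' @return list: \code{fraction} (square matrix), \code{masked},
#'   \code{carriers} (list of carrier sets).
#' @export
coamplification <- function(catalog, minCarriers = 3, displayCut = 0.2) {
  if (!nrow(catalog)) stop("empty amplicon catalog")
  keep <- catalog[catalog$n_carriers >= minCarriers, , drop = FALSE]
  sets <- lapply(strsplit(keep$carriers, ","), unique)
  names(sets) <- keep$locus
  k <- length(sets)
  m <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
  masked <- m
  masked[masked < displayCut] <- NA_real_
  list(fraction = m, masked = masked, carriers = sets)
}
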