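#' @include AllClasses.R
NULL

# Desk-scale human autosome scaffold: lengths and centromere positions in Mb,
# roughly proportional to the reference genome. Focal amplicon regions below
# are widened to ~5 Mb so that at the default 5,000-probe resolution each
# spans >= 4 probes (the minimum segment size used downstream); on a real
# ~32k-probe tiling array the same loci span dozens of clones.
.chromLengthsMb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
                     134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
.centromeresMb <- c(125, 93, 91, 50, 48, 61, 60, 45, 49, 40, 53, 36, 18, 17,
                    19, 37, 24, 17, 26, 28, 12, 15)

# Named recurrent regions used by the archetype catalog (Mb coordinates).
.regionCatalog <- function() {
  r <- rbind(
    data.frame(region = "1q",      chrom = "chr1",  lo = 126, hi = 249),
    data.frame(region = "3p",      chrom = "chr3",  lo = 1,   hi = 90),
    data.frame(region = "chr4",    chrom = "chr4",  lo = 1,   hi = 191),
    data.frame(region = "5q",      chrom = "chr5",  lo = 49,  hi = 180),
    data.frame(region = "8p",      chrom = "chr8",  lo = 1,   hi = 34),
    data.frame(region = "8p12",    chrom = "chr8",  lo = 35,  hi = 40),
    data.frame(region = "8q",      chrom = "chr8",  lo = 46,  hi = 146),
    data.frame(region = "8q24",    chrom = "chr8",  lo = 126, hi = 131),
    data.frame(region = "9p",      chrom = "chr9",  lo = 1,   hi = 47),
    data.frame(region = "10p",     chrom = "chr10", lo = 1,   hi = 39),
    data.frame(region = "11q13.3", chrom = "chr11", lo = 68,  hi = 73),
    data.frame(region = "11q13.5", chrom = "chr11", lo = 75,  hi = 80),
    data.frame(region = "11q25",   chrom = "chr11", lo = 128, hi = 135),
    data.frame(region = "13q",     chrom = "chr13", lo = 19,  hi = 115),
    data.frame(region = "16p",     chrom = "chr16", lo = 1,   hi = 36),
    data.frame(region = "16q",     chrom = "chr16", lo = 38,  hi = 90),
    data.frame(region = "17p",     chrom = "chr17", lo = 1,   hi = 23),
    data.frame(region = "17q12",   chrom = "chr17", lo = 34,  hi = 39),
    data.frame(region = "17q",     chrom = "chr17", lo = 40,  hi = 81),
    data.frame(region = "19p",     chrom = "chr19", lo = 1,   hi = 25),
    data.frame(region = "19q",     chrom = "chr19", lo = 33,  hi = 59))
  r$lo <- r$lo * 1e6
  r$hi <- r$hi * 1e6
  r
}

.ev <- function(region, kind, prob, mean, sd = 0.1,
                given = NA_character_, prob_given = NA_real_) {
  data.frame(region = region, kind = kind, prob = prob, mean = mean,
             sd = sd, given = given, prob_given = prob_given,
             stringsAsFactors = FALSE)
}

#' Default genomic-subtype archetypes
#'
#' Six archetypes of breast-tumor copy-number architecture: luminal-simple
#' (+1q, +16p, -16q; quiet background), luminal-complex (+1q, +8q, 11q13.3
#' amplification, -3p, -8p, -9p, -11q25, -13q), basal-complex (many
#' low-level changes, -5q, -chr4, +10p, high background), 17q12 (17q12
#' high-level amplification with neighboring 17q gain), amplifier (8p12
#' amplification with conditional 11q13.3 coamplification, probability 0.7
#' given 8p12), and mixed (losses on 8p, 13q, 17p with 1q gain). Event
#' frequencies, cohort proportions, hormone-receptor/grade/node composition
#' and hazard ordering follow the published subtype characterizations;
#' amplitudes are in log2 units (high-level amplification mean >= 1).
#'
#' @return a named list of archetypes; each has fields \code{name},
#'   \code{proportion}, \code{events} (region, kind in gain/loss/high_amp,
#'   prob, mean, sd, and optional conditional fields given/prob_given),
#'   \code{background_rate} (per chromosome arm), \code{target_fga}
#'   (expected desk-scale FGA band), \code{hazard_os}, \code{hazard_dmfs}
#'   (per-year exponential hazards), and \code{clinical} (sampling
#'   distributions for covariates).
#' @export
defaultArchetypes <- function() {
  arch <- list(
    `luminal-simple` = list(
      proportion = 46 / 359,
      events = rbind(.ev("1q", "gain", 0.90, 0.40),
                     .ev("16p", "gain", 0.80, 0.40),
                     .ev("16q", "loss", 0.90, -0.40)),
      background_rate = 0.02,
      target_fga = c(0.03, 0.12),
      hazard_os = 0.030, hazard_dmfs = 0.042,
      clinical = list(er_pos = 0.96, pgr_pos = 0.85, ln_pos = 0.27,
                      size_mean = 21, size_sd = 10,
                      grade_probs = c(0.26, 0.62, 0.12),
                      intrinsic_probs = c(`basal-like` = 0, `HER2-enriched` = 0,
                                          `luminal B` = 0.02, `luminal A` = 0.79,
                                          `normal-like` = 0.19),
                      brca_probs = c(BRCA1 = 0, BRCA2 = 0,
                                     familial = 0.5, sporadic = 0.5))),
    `luminal-complex` = list(
      proportion = 105 / 359,
      events = rbind(.ev("1q", "gain", 0.85, 0.40),
                     .ev("8q", "gain", 0.85, 0.40),
                     .ev("11q13.3", "high_amp", 0.35, 1.40, 0.25),
                     .ev("3p", "loss", 0.85, -0.40),
                     .ev("8p", "loss", 0.70, -0.40),
                     .ev("9p", "loss", 0.80, -0.40),
                     .ev("11q25", "loss", 0.75, -0.40),
                     .ev("13q", "loss", 0.85, -0.40)),
      background_rate = 0.05,
      target_fga = c(0.07, 0.22),
      hazard_os = 0.050, hazard_dmfs = 0.070,
      clinical = list(er_pos = 0.89, pgr_pos = 0.75, ln_pos = 0.46,
                      size_mean = 26, size_sd = 17,
                      grade_probs = c(0.08, 0.50, 0.42),
                      intrinsic_probs = c(`basal-like` = 0.05,
                                          `HER2-enriched` = 0.03,
                                          `luminal B` = 0.54,
                                          `luminal A` = 0.35,
                                          `normal-like` = 0.03),
                      brca_probs = c(BRCA1 = 0.01, BRCA2 = 0.24,
                                     familial = 0.36, sporadic = 0.39))),
    `basal-complex` = list(
      proportion = 67 / 359,
      events = rbind(.ev("5q", "loss", 0.90, -0.35),
                     .ev("chr4", "loss", 0.80, -0.35),
                     .ev("10p", "gain", 0.70, 0.35),
                     .ev("8q", "gain", 0.60, 0.35)),
      background_rate = 0.22,
      target_fga = c(0.15, 0.40),
      hazard_os = 0.100, hazard_dmfs = 0.140,
      clinical = list(er_pos = 0.11, pgr_pos = 0.10, ln_pos = 0.31,
                      size_mean = 27, size_sd = 12,
                      grade_probs = c(0.02, 0.10, 0.88),
                      intrinsic_probs = c(`basal-like` = 0.92,
                                          `HER2-enriched` = 0,
                                          `luminal B` = 0.02,
                                          `luminal A` = 0.02,
                                          `normal-like` = 0.04),
                      brca_probs = c(BRCA1 = 0.25, BRCA2 = 0.07,
                                     familial = 0.22, sporadic = 0.46))),
    `17q12` = list(
      proportion = 51 / 359,
      events = rbind(.ev("17q12", "high_amp", 0.90, 1.50, 0.25),
                     .ev("17q", "gain", 0.80, 0.40)),
      background_rate = 0.06,
      target_fga = c(0.03, 0.15),
      hazard_os = 0.150, hazard_dmfs = 0.200,
      clinical = list(er_pos = 0.40, pgr_pos = 0.30, ln_pos = 0.57,
                      size_mean = 31, size_sd = 21,
                      grade_probs = c(0.03, 0.41, 0.56),
                      intrinsic_probs = c(`basal-like` = 0.10,
                                          `HER2-enriched` = 0.61,
                                          `luminal B` = 0.06,
                                          `luminal A` = 0.12,
                                          `normal-like` = 0.11),
                      brca_probs = c(BRCA1 = 0, BRCA2 = 0.02,
                                     familial = 0.37, sporadic = 0.61))),
    amplifier = list(
      proportion = 52 / 359,
      events = rbind(.ev("8p12", "high_amp", 0.90, 1.40, 0.25),
                     .ev("11q13.3", "high_amp", 0.10, 1.40, 0.25,
                         given = "8p12", prob_given = 0.70),
                     .ev("1q", "gain", 0.75, 0.40),
                     .ev("16p", "gain", 0.70, 0.40),
                     .ev("19p", "gain", 0.70, 0.40),
                     .ev("19q", "gain", 0.70, 0.40),
                     .ev("8p", "loss", 0.75, -0.40),
                     .ev("16q", "loss", 0.70, -0.40),
                     .ev("17p", "loss", 0.70, -0.40),
                     .ev("11q25", "loss", 0.70, -0.40)),
      background_rate = 0.05,
      target_fga = c(0.04, 0.18),
      hazard_os = 0.070, hazard_dmfs = 0.098,
      clinical = list(er_pos = 0.80, pgr_pos = 0.65, ln_pos = 0.42,
                      size_mean = 25, size_sd = 13,
                      grade_probs = c(0.22, 0.53, 0.25),
                      intrinsic_probs = c(`basal-like` = 0.19,
                                          `HER2-enriched` = 0,
                                          `luminal B` = 0.29,
                                          `luminal A` = 0.29,
                                          `normal-like` = 0.23),
                      brca_probs = c(BRCA1 = 0.04, BRCA2 = 0,
                                     familial = 0.56, sporadic = 0.40))),
    mixed = list(
      proportion = 38 / 359,
      events = rbind(.ev("8p", "loss", 0.80, -0.40),
                     .ev("13q", "loss", 0.85, -0.40),
                     .ev("17p", "loss", 0.85, -0.40),
                     .ev("1q", "gain", 0.60, 0.40)),
      background_rate = 0.10,
      target_fga = c(0.05, 0.18),
      hazard_os = 0.090, hazard_dmfs = 0.120,
      clinical = list(er_pos = 0.70, pgr_pos = 0.55, ln_pos = 0.51,
                      size_mean = 25, size_sd = 11,
                      grade_probs = c(0.11, 0.56, 0.33),
                      intrinsic_probs = c(`basal-like` = 0.20,
                                          `HER2-enriched` = 0.04,
                                          `luminal B` = 0.16,
                                          `luminal A` = 0.40,
                                          `normal-like` = 0.20),
                      brca_probs = c(BRCA1 = 0.05, BRCA2 = 0.03,
                                     familial = 0.21, sporadic = 0.71))))
  for (nm in names(arch)) arch[[nm]]$name <- nm
  arch
}

#' Build the desk-scale simulated probe map
#'
#' Tiles \code{probeCount} probes across 22 autosomes proportionally to
#' chromosome length, evenly spaced, 100-kb probe footprints.
#'
#' @param probeCount total number of probes (default 5000).
#' @return named GRanges probe map.
#' @export
simulatedProbeMap <- function(probeCount = 5000) {
  stopifnot(probeCount >= 220)
  lens <- .chromLengthsMb * 1e6
  counts <- pmax(4L, as.integer(round(probeCount * lens / sum(lens))))
  chroms <- integer(0); starts <- integer(0)
  for (c in seq_along(lens)) {
    spacing <- lens[c] / counts[c]
    mids <- (seq_len(counts[c]) - 0.5) * spacing
    st <- pmax(1, round(mids - 5e4))
    chroms <- c(chroms, rep(c, counts[c]))
    starts <- c(starts, st)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(paste0("chr", chroms), levels = .validChroms()),
    ranges = IRanges::IRanges(start = starts, width = 1e5))
  names(gr) <- sprintf("P%05d", seq_along(gr))
  gr
}

.probeMid <- function(probes)
  (GenomicRanges::start(probes) + GenomicRanges::end(probes)) / 2

# probe indices whose midpoint falls inside [lo, hi] on chrom
.probesInInterval <- function(probes, chrom, lo, hi) {
  mid <- .probeMid(probes)
  which(as.character(GenomicRanges::seqnames(probes)) == chrom &
          mid >= lo & mid <= hi)
}

.drawAmplitude <- function(kind, mean, sd) {
  a <- stats::rnorm(1, mean, sd)
  if (kind == "high_amp") max(a, 1.1)
  else if (kind == "gain") max(a, 0.2)
  else min(a, -0.2)
}

#' Generate a synthetic aCGH cohort with expression and survival
#'
#' Emulates a BAC-array-like tumor cohort: each sample draws a subtype
#' archetype, plants its catalog events (segmental log2 shifts; high-level
#' amplicons with log2 >= 1; conditional coamplification), adds random
#' per-arm background aberrations, and i.i.d. Gaussian probe noise. For
#' every catalog region, cis-dosage genes are simulated as
#' \code{a * local_log2 + noise}; additional trans genes are pure noise.
#' Survival times are exponential with per-subtype hazards, censored
#' administratively at \code{horizon} years plus uniform dropout.
#'
#' @param nSamples cohort size.
#' @param seed integer seed; the full output is reproducible given the seed.
#' @param archetypes archetype list, see \code{\link{defaultArchetypes}}.
#' @param proportions optional named mixing proportions (must sum to 1);
#'   default taken from the archetypes.
#' @param probeCount probes in the simulated genome (default 5000).
#' @param noiseSd per-probe Gaussian noise sd in log2 units (default 0.15).
#' @param exprSlope cis dosage-response slope a (default 1).
#' @param exprNoiseSd expression noise sd (default 0.2).
#' @param cisGenesPerRegion cis genes per catalog region (default 10).
#' @param transGenes number of unlinked noise genes (default 200).
#' @param horizon administrative censoring horizon in years (default 10).
#' @return list with elements \code{cn} (a
#'   \linkS4class{CopyNumberExperiment} with clinical covariates in
#'   \code{colData}), \code{expr} (RangedSummarizedExperiment), and
#'   \code{truth} (list: \code{subtype}, \code{events} data.frame,
#'   \code{segTruth} matrix of planted values, \code{fga} planted altered
#'   fraction per sample, \code{cisGenes}, \code{hazards}).
#' @export
generateCohort <- function(nSamples = 200, seed = 1,
                           archetypes = defaultArchetypes(),
                           proportions = NULL, probeCount = 5000,
                           noiseSd = 0.15, exprSlope = 1, exprNoiseSd = 0.2,
                           cisGenesPerRegion = 10, transGenes = 200,
                           horizon = 10) {
  if (length(archetypes) == 0) stop("empty archetype catalog")
  for (a in archetypes) {
    if (nrow(a$events) == 0) stop("archetype '", a$name, "' has no events")
    if (any(a$events$prob < 0 | a$events$prob > 1))
      stop("event probabilities must be in [0,1]")
    amp <- a$events[a$events$kind == "high_amp", , drop = FALSE]
    if (nrow(amp) && any(amp$mean < 1))
      stop("high_amp amplitude mean must be >= 1.0")
  }
  if (is.null(proportions))
    proportions <- vapply(archetypes, `[[`, numeric(1), "proportion")
  proportions <- proportions / 1  # keep names
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("archetype proportions must sum to 1 (got ", sum(proportions), ")")
  if (!all(names(proportions) %in% names(archetypes)))
    stop("proportions name unknown archetype(s)")

  set.seed(as.integer(seed))
  probes <- simulatedProbeMap(probeCount)
  M <- length(probes)
  cat2 <- .regionCatalog()
  regionProbes <- lapply(seq_len(nrow(cat2)), function(i)
    .probesInInterval(probes, cat2$chrom[i], cat2$lo[i], cat2$hi[i]))
  names(regionProbes) <- cat2$region
  usedRegions <- unique(unlist(lapply(archetypes,
                                      function(a) a$events$region)))
  for (r in usedRegions) {
    if (!r %in% cat2$region) stop("unknown region in catalog: ", r)
    if (length(regionProbes[[r]]) == 0)
      stop("region ", r, " maps to no probe at this resolution")
  }

  # chromosome arms for background events
  armTab <- do.call(rbind, lapply(1:22, function(c) {
    cen <- .centromeresMb[c] * 1e6
    len <- .chromLengthsMb[c] * 1e6
    data.frame(chrom = paste0("chr", c),
               lo = c(1, cen + 1), hi = c(cen, len))
  }))

  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  subtype <- sample(names(proportions), nSamples, replace = TRUE,
                    prob = proportions)
  segTruth <- matrix(0, nrow = M, ncol = nSamples,
                     dimnames = list(names(probes), sampleIds))
  eventRows <- list()
  mid <- .probeMid(probes)
  chromOf <- as.character(GenomicRanges::seqnames(probes))

  for (s in seq_len(nSamples)) {
    a <- archetypes[[subtype[s]]]
    ev <- a$events
    drawn <- logical(nrow(ev))
    # unconditional events first so conditional draws can reference them
    for (i in order(!is.na(ev$given))) {
      p <- ev$prob[i]
      if (!is.na(ev$given[i])) {
        gi <- which(ev$region == ev$given[i])[1]
        if (!is.na(gi) && drawn[gi]) p <- ev$prob_given[i]
      }
      drawn[i] <- stats::runif(1) < p
      if (drawn[i]) {
        amp <- .drawAmplitude(ev$kind[i], ev$mean[i], ev$sd[i])
        idx <- regionProbes[[ev$region[i]]]
        segTruth[idx, s] <- segTruth[idx, s] + amp
        ri <- match(ev$region[i], cat2$region)
        eventRows[[length(eventRows) + 1L]] <-
          data.frame(sample_id = sampleIds[s], region = ev$region[i],
                     chrom = cat2$chrom[ri], start = cat2$lo[ri],
                     end = cat2$hi[ri], kind = ev$kind[i], amplitude = amp,
                     stringsAsFactors = FALSE)
      }
    }
    # background segmental noise per arm
    for (r in seq_len(nrow(armTab))) {
      if (stats::runif(1) >= a$background_rate) next
      armLo <- armTab$lo[r]; armHi <- armTab$hi[r]
      lo <- stats::runif(1, armLo, armHi - 0.2 * (armHi - armLo))
      hi <- lo + stats::runif(1, 0.2, 1) * (armHi - lo)
      kind <- if (stats::runif(1) < 0.5) "gain" else "loss"
      amp <- .drawAmplitude(kind, if (kind == "gain") 0.35 else -0.35, 0.1)
      idx <- .probesInInterval(probes, armTab$chrom[r], lo, hi)
      if (!length(idx)) next
      segTruth[idx, s] <- segTruth[idx, s] + amp
      eventRows[[length(eventRows) + 1L]] <-
        data.frame(sample_id = sampleIds[s], region = "background",
                   chrom = armTab$chrom[r], start = lo, end = hi,
                   kind = kind, amplitude = amp, stringsAsFactors = FALSE)
    }
  }
  lr <- segTruth + matrix(stats::rnorm(M * nSamples, 0, noiseSd), M)
  dimnames(lr) <- dimnames(segTruth)

  # expression: cis genes inside catalog regions used by the archetypes
  geneRows <- list(); exprRows <- list(); cisGenes <- character(0)
  for (r in usedRegions) {
    ri <- match(r, cat2$region)
    pos <- seq(cat2$lo[ri], cat2$hi[ri],
               length.out = cisGenesPerRegion + 2)[-c(1, cisGenesPerRegion + 2)]
    for (g in seq_along(pos)) {
      gid <- paste0("cis_", gsub("[^0-9A-Za-z]", "_", r), "_", g)
      cisGenes <- c(cisGenes, gid)
      near <- which(chromOf == cat2$chrom[ri])
      near <- near[which.min(abs(mid[near] - pos[g]))]
      vals <- exprSlope * segTruth[near, ] +
        stats::rnorm(nSamples, 0, exprNoiseSd)
      geneRows[[gid]] <- data.frame(gene_id = gid, chrom = cat2$chrom[ri],
                                    start = round(pos[g]),
                                    end = round(pos[g]) + 999)
      exprRows[[gid]] <- vals
    }
  }
  if (transGenes > 0) {
    tchrom <- sample(1:22, transGenes, replace = TRUE)
    tpos <- round(stats::runif(transGenes, 1e6,
                               .chromLengthsMb[tchrom] * 1e6 - 1e6))
    for (g in seq_len(transGenes)) {
      gid <- sprintf("trans_%03d", g)
      geneRows[[gid]] <- data.frame(gene_id = gid,
                                    chrom = paste0("chr", tchrom[g]),
                                    start = tpos[g], end = tpos[g] + 999)
      exprRows[[gid]] <- stats::rnorm(nSamples, 0, 1)
    }
  }
  geneDf <- do.call(rbind, geneRows)
  exprMat <- do.call(rbind, exprRows)
  colnames(exprMat) <- sampleIds
  genes <- GenomicRanges::GRanges(
    seqnames = factor(geneDf$chrom, levels = .validChroms()),
    ranges = IRanges::IRanges(start = geneDf$start, end = geneDf$end))
  names(genes) <- geneDf$gene_id
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprMat), rowRanges = genes)

  # clinical covariates and survival
  clin <- do.call(rbind, lapply(seq_len(nSamples), function(s) {
    cl <- archetypes[[subtype[s]]]$clinical
    h <- archetypes[[subtype[s]]]
    er <- if (stats::runif(1) < cl$er_pos) "pos" else "neg"
    pgr <- if (stats::runif(1) < (if (er == "pos") cl$pgr_pos else 0.1))
      "pos" else "neg"
    ln <- if (stats::runif(1) < cl$ln_pos) "pos" else "neg"
    size <- max(5, round(stats::rnorm(1, cl$size_mean, cl$size_sd)))
    grade <- sample(1:3, 1, prob = cl$grade_probs)
    intr <- sample(names(cl$intrinsic_probs), 1, prob = cl$intrinsic_probs)
    brca <- sample(names(cl$brca_probs), 1, prob = cl$brca_probs)
    tos <- stats::rexp(1, h$hazard_os)
    cos <- min(horizon, stats::runif(1, 0, 2.5 * horizon))
    tdm <- stats::rexp(1, h$hazard_dmfs)
    cdm <- min(horizon, stats::runif(1, 0, 2.5 * horizon))
    data.frame(er_status = er, pgr_status = pgr, ln_status = ln,
               size_mm = size, grade = grade, intrinsic_subtype = intr,
               brca_status = brca,
               os_time = round(min(tos, cos), 4),
               os_event = as.integer(tos <= cos),
               dmfs_time = round(min(tdm, cdm), 4),
               dmfs_event = as.integer(tdm <= cdm),
               stringsAsFactors = FALSE)
  }))
  rownames(clin) <- sampleIds
  cn <- CopyNumberExperiment(lr, probes,
                             colData = S4Vectors::DataFrame(clin))
  truth <- list(
    subtype = stats::setNames(factor(subtype), sampleIds),
    events = if (length(eventRows)) do.call(rbind, eventRows) else
      data.frame(),
    segTruth = segTruth,
    fga = colMeans(segTruth != 0),
    cisGenes = cisGenes,
    hazards = vapply(archetypes, `[[`, numeric(1), "hazard_os"))
  list(cn = cn, expr = expr, truth = truth)
}
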