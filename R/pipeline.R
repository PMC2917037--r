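#' @include AllClasses.R
NULL

.defaultConfig <- function() {
  list(
    n_samples = 200, probe_count = 5000, noise_sd = 0.15,
    cbs = list(alpha = 0.01, nperm = 1000),
    calling = list(window_bp = NULL, k = 2.5, tau_min = 0.1,
                   amp_cut = 1.0, min_probes = 4),
    gistic = list(nperm = 1000, q_threshold = 0.25, cap = 2.0,
                  plateau = 0.95, merge_gap = 5),
    amplicons = list(amp_cut = 1.0, recurrence = 0.01, min_carriers = 3,
                     display_cut = 0.2),
    integrate = list(nperm = 100, alpha = 0.05),
    subtype = list(k = 6, freq_cut = 0.2),
    survive = list(endpoint = "os"))
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' A config must carry an explicit integer \code{seed} and an
#' \code{out_dir}; stage blocks default from the package settings.
#'
#' @param config list or path to a YAML file.
#' @return the completed config list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$seed))
    stop("config validation: 'seed' is required (every stochastic stage ",
         "must be explicitly seeded)")
  if (is.null(config$out_dir))
    stop("config validation: 'out_dir' is required")
  if (!is.numeric(config$seed) || config$seed != as.integer(config$seed))
    stop("config validation: 'seed' must be an integer")
  .mergeConfig(.defaultConfig(), config)
}

.stageFiles <- function(outDir, files, stage) {
  data.frame(stage = stage, file = basename(files),
             md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
}

#' Run the full copy-number subtyping pipeline
#'
#' Executes simulate -> segment -> gistic -> amplicons -> integrate ->
#' subtype -> survive on a synthetic cohort (or user-supplied inputs via
#' \code{config$input}), writing each stage's outputs as flat files
#' (BED/TSV/SEG/Newick) into \code{config$out_dir} together with the
#' verbatim config and a checksum manifest. Re-running with an identical
#' config reproduces identical checksums.
#'
#' @param config list or YAML path; see \code{\link{validateConfig}}. The
#'   only required fields are \code{seed} and \code{out_dir}.
#' @return invisibly, the manifest data.frame (stage, file, md5).
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  manifest <- list()
  log <- function(...) message("[pipeline] ", ...)

  # -- simulate (or load) ----------------------------------------------
  log("stage simulate")
  if (!is.null(cfg$input)) {
    probes <- readProbeMap(cfg$input$probe_map)
    clin <- if (!is.null(cfg$input$clinical))
      readClinicalTable(cfg$input$clinical) else NULL
    cohort <- list(
      cn = readCopyNumberMatrix(cfg$input$matrix, probes, colData = clin),
      expr = if (!is.null(cfg$input$expression))
        readExpressionMatrix(cfg$input$expression) else NULL,
      truth = NULL)
  } else {
    cohort <- generateCohort(nSamples = cfg$n_samples, seed = cfg$seed,
                             probeCount = cfg$probe_count,
                             noiseSd = cfg$noise_sd)
  }
  cn <- cohort$cn
  f <- file.path(cfg$out_dir, c("probes.bed", "cn_matrix.tsv",
                                "clinical.tsv"))
  writeProbeMap(probeMap(cn), f[1])
  writeMatrixTSV(log2Ratios(cn), f[2])
  writeClinicalTable(SummarizedExperiment::colData(cn), f[3])
  if (!is.null(cohort$expr)) {
    fe <- file.path(cfg$out_dir, "expression.tsv")
    writeExpressionMatrix(cohort$expr, fe)
    f <- c(f, fe)
  }
  if (!is.null(cohort$truth)) {
    ft <- file.path(cfg$out_dir, "truth_subtypes.tsv")
    utils::write.table(
      data.frame(sample_id = names(cohort$truth$subtype),
                 subtype = as.character(cohort$truth$subtype),
                 true_fga = cohort$truth$fga),
      ft, sep = "\t", quote = FALSE, row.names = FALSE)
    f <- c(f, ft)
  }
  manifest$simulate <- .stageFiles(cfg$out_dir, f, "simulate")

  # -- segment ---------------------------------------------------------
  log("stage segment")
  cn <- segmentCohort(cn, alpha = cfg$cbs$alpha, nperm = cfg$cbs$nperm,
                      seed = cfg$seed)
  cn <- callCohort(cn, windowBp = cfg$calling$window_bp, k = cfg$calling$k,
                   tauMin = cfg$calling$tau_min,
                   ampCut = cfg$calling$amp_cut,
                   minProbes = cfg$calling$min_probes)
  f <- file.path(cfg$out_dir, c("segments.seg", "calls.tsv", "fga.tsv"))
  writeSeg(segmentTable(cn), f[1])
  writeMatrixTSV(cnCalls(cn), f[2])
  fgaTab <- fga(cn)
  utils::write.table(cbind(sample_id = rownames(fgaTab), fgaTab), f[3],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$segment <- .stageFiles(cfg$out_dir, f, "segment")

  # -- gistic ----------------------------------------------------------
  log("stage gistic")
  gistic <- runGistic(cn, nperm = cfg$gistic$nperm,
                      qThreshold = cfg$gistic$q_threshold,
                      cap = cfg$gistic$cap, plateau = cfg$gistic$plateau,
                      mergeGap = cfg$gistic$merge_gap, seed = cfg$seed)
  f <- file.path(cfg$out_dir, "gistic_regions.tsv")
  writeGisticRegions(gistic, f)
  manifest$gistic <- .stageFiles(cfg$out_dir, f, "gistic")

  # -- amplicons -------------------------------------------------------
  log("stage amplicons")
  catalog <- detectAmplicons(cn, ampCut = cfg$amplicons$amp_cut,
                             recurrence = cfg$amplicons$recurrence,
                             gistic = gistic)
  f <- file.path(cfg$out_dir, c("amplicon_catalog.tsv", "coamp_matrix.tsv",
                                "coamp_masked.tsv"))
  utils::write.table(catalog, f[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(catalog) &&
      any(catalog$n_carriers >= cfg$amplicons$min_carriers)) {
    co <- coamplification(catalog,
                          minCarriers = cfg$amplicons$min_carriers,
                          displayCut = cfg$amplicons$display_cut)
    writeMatrixTSV(co$fraction, f[2], idCol = "locus")
    writeMatrixTSV(co$masked, f[3], idCol = "locus")
  } else {
    utils::write.table(data.frame(), f[2]); utils::write.table(data.frame(), f[3])
  }
  manifest$amplicons <- .stageFiles(cfg$out_dir, f, "amplicons")

  # -- integrate -------------------------------------------------------
  log("stage integrate")
  f <- file.path(cfg$out_dir, "dosage_correlation.tsv")
  if (!is.null(cohort$expr) && length(gisticRegions(gistic))) {
    rv <- regionValues(gistic, cn)
    assignment <- mapGenesToRegions(
      SummarizedExperiment::rowRanges(cohort$expr), gistic, probeMap(cn))
    set.seed(cfg$seed)
    dc <- dosageCorrelation(cohort$expr, rv, assignment,
                            nperm = cfg$integrate$nperm,
                            alpha = cfg$integrate$alpha)
    tab <- dc$table
    tab$r_star <- dc$rStar
    utils::write.table(tab, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(data.frame(), f)
  }
  manifest$integrate <- .stageFiles(cfg$out_dir, f, "integrate")

  # -- subtype ---------------------------------------------------------
  log("stage subtype")
  rm6 <- buildRegionMatrix(gistic, cn)
  assign6 <- clusterSubtypes(rm6, k = cfg$subtype$k)
  naming <- matchArchetypeNames(assign6, gistic, cn)
  labels <- attr(naming, "labels")
  f <- file.path(cfg$out_dir, c("subtype_assignments.tsv",
                                "region_matrix.tsv", "dendrogram.nwk",
                                "centroids.tsv"))
  utils::write.table(
    data.frame(sample_id = names(labels), cluster =
                 as.character(subtypeLabels(assign6)),
               subtype = as.character(labels)),
    f[1], sep = "\t", quote = FALSE, row.names = FALSE)
  writeMatrixTSV(rm6, f[2], idCol = "region")
  ape::write.tree(ape::as.phylo(assign6@tree), f[3])
  if (!is.null(cohort$expr)) {
    cents <- buildCentroids(cohort$expr, labels,
                            rownames(cohort$expr))
    writeMatrixTSV(cents, f[4], idCol = "gene_id")
  } else utils::write.table(data.frame(), f[4])
  manifest$subtype <- .stageFiles(cfg$out_dir, f, "subtype")

  # -- survive ---------------------------------------------------------
  log("stage survive")
  clin <- SummarizedExperiment::colData(cn)
  surv <- compareSurvival(clin, labels, endpoint = cfg$survive$endpoint)
  f <- file.path(cfg$out_dir, c("km_curves.tsv", "logrank.tsv"))
  utils::write.table(surv$km, f[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(endpoint = cfg$survive$endpoint,
               chisq = surv$logrank$chisq, df = surv$logrank$df,
               p = surv$logrank$p),
    f[2], sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$survive <- .stageFiles(cfg$out_dir, f, "survive")

  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  utils::write.table(out, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
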