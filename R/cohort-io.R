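#' @include AllClasses.R
NULL

# Internal coordinate convention: 1-based, inclusive (matches SEG).
# BED files are 0-based half-open and are converted on read/write.

#' Read a probe map from a BED-style file
#'
#' Expects a tab-separated file with columns chrom, start, end, probe_id
#' (BED coordinates: 0-based half-open). Rows are converted to the internal
#' 1-based inclusive convention and sorted into natural genome order
#' (chr1..chr22, chrX) if not already sorted, with a message.
#'
#' @param path path to the BED/TSV file.
#' @return A named \code{GRanges} probe map.
#' @export
readProbeMap <- function(path) {
  if (!file.exists(path)) stop("probe map file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "probe_id"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("probe map row ", bad[1], " (", df$probe_id[bad[1]],
         "): start >= end in BED coordinates")
  if (anyDuplicated(df$probe_id)) {
    d <- df$probe_id[duplicated(df$probe_id)][1]
    stop("duplicate probe id: ", d)
  }
  badchr <- setdiff(unique(df$chrom), .validChroms())
  if (length(badchr))
    stop("unsupported chromosome(s): ", paste(badchr, collapse = ", "))
  ord <- order(match(df$chrom, .validChroms()), df$start)
  if (!identical(as.integer(ord), seq_len(nrow(df)))) {
    message("probe map not in genome order; re-sorting by (chrom, start)")
    df <- df[ord, , drop = FALSE]
  }
  # BED half-open -> 1-based inclusive
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = .validChroms()),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  names(gr) <- df$probe_id
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)
  if (length(ov))
    stop("overlapping probes in map, e.g. ",
         names(gr)[S4Vectors::queryHits(ov)[1]], " and ",
         names(gr)[S4Vectors::subjectHits(ov)[1]])
  gr
}

#' Write a probe map as BED (0-based half-open)
#'
#' @param probes named GRanges probe map.
#' @param path output path.
#' @export
writeProbeMap <- function(probes, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(probes)),
                   start = GenomicRanges::start(probes) - 1L,
                   end = GenomicRanges::end(probes),
                   probe_id = names(probes))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe x sample log2-ratio matrix
#'
#' TSV with a header of sample ids; first column probe ids. The matrix is
#' aligned to the probe map order; mapped probes absent from the file get NA
#' rows. Probes in the file but not in the map, or non-numeric cells, are
#' errors.
#'
#' @param path TSV path.
#' @param probes named GRanges probe map to align against.
#' @param colData optional per-sample DataFrame.
#' @return A \linkS4class{CopyNumberExperiment}.
#' @export
readCopyNumberMatrix <- function(path, probes, colData = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  ids <- df[[1]]
  unknown <- setdiff(ids, names(probes))
  if (length(unknown))
    stop("probe id not in probe map: ", unknown[1])
  if (anyDuplicated(ids)) stop("duplicate probe id in matrix: ",
                               ids[duplicated(ids)][1])
  samples <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  badcell <- which(is.na(num) & !(vals %in% c("NA", "", "NaN")))
  if (length(badcell)) {
    rc <- arrayInd(badcell[1], dim(vals))
    stop("non-numeric value '", vals[badcell[1]], "' for probe ",
         ids[rc[1]], ", sample ", samples[rc[2]])
  }
  m <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
              dimnames = list(names(probes), samples))
  m[ids, ] <- num
  CopyNumberExperiment(m, probes, colData = colData)
}

#' Write a numeric matrix as TSV with an id column
#'
#' @param m matrix with rownames and colnames.
#' @param path output path.
#' @param idCol name for the first (row-id) column.
#' @export
writeMatrixTSV <- function(m, path, idCol = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idCol
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.segColumns <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")

.checkSegTable <- function(segments) {
  needed <- c("sample_id", "chrom", "start", "end", "n_probes", "seg_mean")
  if (!all(needed %in% colnames(segments)))
    stop("segment table must have columns: ", paste(needed, collapse = ", "))
  if (any(segments$n_probes < 1)) stop("n_probes must be >= 1")
  for (s in unique(segments$sample_id)) {
    sub <- segments[segments$sample_id == s, , drop = FALSE]
    for (ch in unique(sub$chrom)) {
      cc <- sub[sub$chrom == ch, , drop = FALSE]
      cc <- cc[order(cc$start), , drop = FALSE]
      if (nrow(cc) > 1 && any(cc$start[-1] <= cc$end[-nrow(cc)]))
        stop("overlapping segments for sample ", s, " on ", ch)
    }
  }
  invisible(TRUE)
}

#' Write segments in SEG format
#'
#' Standard SEG columns (ID, chrom, loc.start, loc.end, num.mark, seg.mean),
#' 1-based inclusive coordinates, seg.mean rounded to 4 decimals.
#' \code{readSeg} inverts the write at that precision.
#'
#' @param segments data.frame with columns sample_id, chrom, start, end,
#'   n_probes, seg_mean.
#' @param path output path.
#' @export
writeSeg <- function(segments, path) {
  .checkSegTable(segments)
  out <- data.frame(ID = segments$sample_id, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$n_probes,
                    seg.mean = sprintf("%.4f", segments$seg_mean))
  colnames(out) <- .segColumns
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file
#'
#' @param path SEG path as written by \code{\link{writeSeg}}.
#' @return data.frame with columns sample_id, chrom, start, end, n_probes,
#'   seg_mean.
#' @export
readSeg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!identical(make.names(.segColumns), colnames(df)) &&
      !identical(.segColumns, colnames(df)))
    stop("not a SEG file (expected columns ",
         paste(.segColumns, collapse = ", "), "): ", path)
  data.frame(sample_id = as.character(df[[1]]), chrom = df[[2]],
             start = as.integer(df[[3]]), end = as.integer(df[[4]]),
             n_probes = as.integer(df[[5]]), seg_mean = as.numeric(df[[6]]),
             stringsAsFactors = FALSE)
}

.clinicalLevels <- list(
  er_status = c("pos", "neg"), pgr_status = c("pos", "neg"),
  ln_status = c("pos", "neg"), grade = c("1", "2", "3"),
  brca_status = c("BRCA1", "BRCA2", "familial", "sporadic"))

#' Read a clinical table
#'
#' TSV with header: sample_id, er_status, pgr_status, ln_status, size_mm,
#' grade, intrinsic_subtype, brca_status, os_time, os_event, dmfs_time,
#' dmfs_event. Status fields use pos/neg/NA; times in years; events 0/1.
#'
#' @param path TSV path.
#' @return A \code{DataFrame} with sample ids as row names.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("sample_id", "er_status", "pgr_status", "ln_status", "size_mm",
              "grade", "intrinsic_subtype", "brca_status", "os_time",
              "os_event", "dmfs_time", "dmfs_event")
  miss <- setdiff(needed, colnames(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in clinical table")
  for (f in names(.clinicalLevels)) {
    bad <- setdiff(stats::na.omit(unique(as.character(df[[f]]))),
                   .clinicalLevels[[f]])
    if (length(bad))
      stop("invalid value '", bad[1], "' in column ", f)
  }
  for (f in c("os_time", "dmfs_time"))
    if (any(df[[f]] < 0, na.rm = TRUE)) stop(f, " must be >= 0")
  for (f in c("os_event", "dmfs_event"))
    if (!all(stats::na.omit(df[[f]]) %in% c(0, 1)))
      stop(f, " must be 0/1")
  out <- S4Vectors::DataFrame(df[, setdiff(needed, "sample_id")],
                              row.names = df$sample_id)
  out
}

#' Write a clinical table
#'
#' @param clin DataFrame as returned by \code{\link{readClinicalTable}}.
#' @param path output path.
#' @export
writeClinicalTable <- function(clin, path) {
  df <- as.data.frame(clin)
  df <- cbind(sample_id = rownames(df), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-expression matrix with gene coordinates
#'
#' TSV with columns gene_id, chrom, start, end (1-based inclusive) followed
#' by one column per sample.
#'
#' @param path TSV path.
#' @return A \linkS4class{RangedSummarizedExperiment} with assay
#'   \code{"exprs"}.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "start", "end")
  if (!all(needed %in% colnames(df)[1:4]))
    stop("expression table must start with columns ",
         paste(needed, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene id")
  genes <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = .validChroms()),
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  names(genes) <- df$gene_id
  m <- as.matrix(df[, -(1:4), drop = FALSE])
  rownames(m) <- df$gene_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), rowRanges = genes)
}

#' Write a gene-expression matrix with gene coordinates
#'
#' @param expr RangedSummarizedExperiment with assay \code{"exprs"}.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(expr, path) {
  rr <- SummarizedExperiment::rowRanges(expr)
  df <- data.frame(gene_id = names(rr),
                   chrom = as.character(GenomicRanges::seqnames(rr)),
                   start = GenomicRanges::start(rr),
                   end = GenomicRanges::end(rr),
                   SummarizedExperiment::assay(expr, "exprs"),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
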