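#' @export
setGeneric("probeMap", function(x, ...) standardGeneric("probeMap"))

#' @export
setGeneric("log2Ratios", function(x, ...) standardGeneric("log2Ratios"))

#' @export
setGeneric("segMeans", function(x, ...) standardGeneric("segMeans"))

#' @export
setGeneric("cnCalls", function(x, ...) standardGeneric("cnCalls"))

#' @export
setGeneric("segmentTable", function(x, ...) standardGeneric("segmentTable"))

#' @export
setGeneric("callThresholds", function(x, ...) standardGeneric("callThresholds"))

#' @export
setGeneric("gisticRegions", function(x, ...) standardGeneric("gisticRegions"))

#' @export
setGeneric("probeScores", function(x, ...) standardGeneric("probeScores"))

#' @export
setGeneric("subtypeLabels", function(x, ...) standardGeneric("subtypeLabels"))
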