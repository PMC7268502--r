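#' @rdname CallerTrack-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname CallerTrack-accessors
#' @export
setGeneric("callerRole", function(x) standardGeneric("callerRole"))

#' @rdname CallerTrack-accessors
#' @export
setGeneric("valueScale", function(x) standardGeneric("valueScale"))

#' @rdname ploidyAt
#' @export
setGeneric("ploidyAt", function(model, chrom, ...) standardGeneric("ploidyAt"))

#' @rdname Thresholds-accessors
#' @export
setGeneric("thresholdValues", function(x) standardGeneric("thresholdValues"))

#' @rdname MetricsReport-accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
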