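#' @include AllClasses.R
NULL

#' @export
setGeneric("runId", function(x) standardGeneric("runId"))
#' @export
setGeneric("timeS", function(x) standardGeneric("timeS"))
#' @export
setGeneric("o2Conc", function(x) standardGeneric("o2Conc"))
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setGeneric("openIntervals", function(x) standardGeneric("openIntervals"))
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))
#' @export
setGeneric("fluxPerVolume", function(x) standardGeneric("fluxPerVolume"))
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @export
setGeneric("protocolId", function(x) standardGeneric("protocolId"))
#' @export
setGeneric("protocolSteps", function(x) standardGeneric("protocolSteps"))
#' @export
setGeneric("referenceState", function(x) standardGeneric("referenceState"))
#' @export
setGeneric("stateRates", function(x) standardGeneric("stateRates"))
#' @export
setGeneric("rateUnits", function(x) standardGeneric("rateUnits"))
#' @export
setGeneric("isRoxCorrected", function(x) standardGeneric("isRoxCorrected"))
#' @export
setGeneric("meanSlope", function(x) standardGeneric("meanSlope"))
#' @export
setGeneric("meanIntercept", function(x) standardGeneric("meanIntercept"))
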