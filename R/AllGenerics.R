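#' @import methods
NULL

#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @export
setGeneric("signalNames", function(x) standardGeneric("signalNames"))

#' @export
setGeneric("contextNames", function(x) standardGeneric("contextNames"))

#' @export
setGeneric("availabilityMask", function(x) standardGeneric("availabilityMask"))

#' @export
setGeneric("signalValues", function(x, context, signal) standardGeneric("signalValues"))

#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @export
setGeneric("normalizedContacts", function(x) standardGeneric("normalizedContacts"))

#' @export
setGeneric("validContactRows", function(x) standardGeneric("validContactRows"))

#' @export
setGeneric("meanAttention", function(x) standardGeneric("meanAttention"))

#' @export
setGeneric("lastLayerAttention", function(x) standardGeneric("lastLayerAttention"))

#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))

#' @export
setGeneric("motifScores", function(x) standardGeneric("motifScores"))

#' @export
setGeneric("tfExpression", function(x) standardGeneric("tfExpression"))
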