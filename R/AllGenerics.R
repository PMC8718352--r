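#' @include AllClasses.R
NULL

#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @export
setGeneric("traceFlavor", function(x) standardGeneric("traceFlavor"))

#' @export
setGeneric("excludedChannels", function(x) standardGeneric("excludedChannels"))

#' @export
setGeneric("nTrialsAveraged", function(x) standardGeneric("nTrialsAveraged"))

#' @export
setGeneric("positionsMM", function(x) standardGeneric("positionsMM"))

#' @export
setGeneric("csLine", function(x) standardGeneric("csLine"))

#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @export
setGeneric("corruptedChannels", function(x) standardGeneric("corruptedChannels"))

#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @export
setGeneric("accuracyPct", function(x) standardGeneric("accuracyPct"))

#' @export
setGeneric("fisherValues", function(x) standardGeneric("fisherValues"))

#' @export
setGeneric("discriminativePeaks", function(x) standardGeneric("discriminativePeaks"))
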