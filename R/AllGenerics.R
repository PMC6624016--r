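#' @rdname Recording
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' @rdname Recording
#' @export
setGeneric("neuronNames", function(x) standardGeneric("neuronNames"))

#' @rdname Recording
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Recording
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname Recording
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname Recording
#' @export
setGeneric("behaviorLabels", function(x) standardGeneric("behaviorLabels"))

#' @rdname EmbeddedSeries
#' @export
setGeneric("embeddedPoints", function(x) standardGeneric("embeddedPoints"))

#' @rdname EmbeddedSeries
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @rdname TransitionMatrix
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname FluxDecomposition
#' @export
setGeneric("statePhase", function(x) standardGeneric("statePhase"))

#' @rdname FluxDecomposition
#' @export
setGeneric("fluxLabels", function(x) standardGeneric("fluxLabels"))

#' @rdname ManifoldModel
#' @export
setGeneric("binInfo", function(x) standardGeneric("binInfo"))

#' @rdname ManifoldModel
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname ManifoldModel
#' @export
setGeneric("binTransitions", function(x) standardGeneric("binTransitions"))

#' @rdname ManifoldModel
#' @export
setGeneric("behaviorDist", function(x) standardGeneric("behaviorDist"))
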