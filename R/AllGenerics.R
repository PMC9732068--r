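#' @name synfc-accessors
#' @title Accessors for synfc classes
#' @description Slot accessors: number of neurons, edge table, spike times,
#'   duration, sparse raster matrix, per-neuron firing rates, FC value and
#'   delay-estimate matrices, and the components of a simulation bundle.
#' @param x a synfc object.
#' @param ... further arguments for methods.
#' @return the requested component.
NULL

#' @rdname synfc-accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname synfc-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname synfc-accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname synfc-accessors
#' @export
setGeneric("durationMin", function(x) standardGeneric("durationMin"))

#' @rdname synfc-accessors
#' @export
setGeneric("spikeMatrix", function(x, ...) standardGeneric("spikeMatrix"))

#' @rdname synfc-accessors
#' @export
setGeneric("firingRates", function(x, ...) standardGeneric("firingRates"))

#' @rdname synfc-accessors
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))

#' @rdname synfc-accessors
#' @export
setGeneric("delayEstimates", function(x) standardGeneric("delayEstimates"))

#' @rdname synfc-accessors
#' @export
setGeneric("fcMeasure", function(x) standardGeneric("fcMeasure"))

#' @rdname synfc-accessors
#' @export
setGeneric("raster", function(x) standardGeneric("raster"))

#' @rdname synfc-accessors
#' @export
setGeneric("weightTrajectory", function(x) standardGeneric("weightTrajectory"))

#' @rdname synfc-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname synfc-accessors
#' @export
setGeneric("isExcitatory", function(x) standardGeneric("isExcitatory"))

#' @rdname synfc-accessors
#' @export
setGeneric("windowMin", function(x) standardGeneric("windowMin"))
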