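#' Ground-truth spiking network
#'
#' Structural state of the simulated network: neuron types, the directed
#' synapse list with signed weights and integer conduction delays, and the
#' plasticity parameters. Excitatory synapses are plastic with weights in
#' \code{[0, wMax]}; inhibitory synapses are fixed-weight and target only
#' excitatory neurons.
#'
#' @slot nNeurons number of neurons.
#' @slot isExcitatory logical per neuron.
#' @slot edges data.frame with columns \code{pre}, \code{post},
#'   \code{delay} (ms) and \code{weight} (mV, signed).
#' @slot stdp list with \code{aPlus}, \code{aMinus}, \code{tauMs},
#'   \code{memoryFactor}, \code{wMax}.
#' @slot seed integer seed used for wiring (NA if none).
#' @exportClass SpikingNetwork
setClass("SpikingNetwork",
    representation(nNeurons = "integer", isExcitatory = "logical",
                   edges = "data.frame", stdp = "list", seed = "integer"))

setValidity("SpikingNetwork", function(object) {
    e <- object@edges
    n <- object@nNeurons
    msg <- character()
    if (length(object@isExcitatory) != n)
        msg <- c(msg, "isExcitatory must have one entry per neuron")
    need <- c("pre", "post", "delay", "weight")
    if (!all(need %in% names(e)))
        return(paste("edges must have columns", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$pre < 1 | e$pre > n | e$post < 1 | e$post > n))
            msg <- c(msg, "edge indices out of range")
        if (any(e$pre == e$post))
            msg <- c(msg, "self-connections are not allowed")
        if (anyDuplicated(e[, c("pre", "post")]))
            msg <- c(msg, "duplicate directed edges")
        exc <- object@isExcitatory[e$pre]
        if (any(!exc & !object@isExcitatory[e$post]))
            msg <- c(msg, "inhibitory synapses may only target excitatory neurons")
        if (any(e$delay < 1))
            msg <- c(msg, "delays must be >= 1 ms")
        if (any(!exc & e$delay != 1L))
            msg <- c(msg, "inhibitory delays must equal 1 ms")
        if (any(exc & (e$weight < 0 | e$weight > object@stdp$wMax)))
            msg <- c(msg, "excitatory weights must lie in [0, wMax]")
        if (any(!exc & e$weight >= 0))
            msg <- c(msg, "inhibitory weights must be negative")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Binary spike raster at 1-ms resolution
#'
#' Stored as per-neuron sorted spike times (ms, 1-based bins); at most one
#' spike per neuron per bin. \code{\link{spikeMatrix}} renders the sparse
#' neurons-by-ms binary matrix.
#'
#' @slot spikeTimes list of sorted integer vectors, one per neuron.
#' @slot nNeurons,durationMs dimensions of the raster.
#' @slot seed simulation seed (NA if imported).
#' @slot metadata free-form provenance list.
#' @exportClass SpikeRaster
setClass("SpikeRaster",
    representation(spikeTimes = "list", nNeurons = "integer",
                   durationMs = "integer", seed = "integer",
                   metadata = "list"))

setValidity("SpikeRaster", function(object) {
    if (length(object@spikeTimes) != object@nNeurons)
        return("spikeTimes must have one element per neuron")
    for (st in object@spikeTimes) {
        if (length(st) == 0) next
        if (is.unsorted(st, strictly = TRUE))
            return("spike times must be strictly increasing (one spike per 1-ms bin)")
        if (st[1] < 1L || st[length(st)] > object@durationMs)
            return("spike times out of range")
    }
    TRUE
})

#' Excitatory synaptic weight trajectory
#'
#' One row per plastic (excitatory) synapse, one column per elapsed second
#' of simulation; values in \code{[0, wMax]}. This is the ground-truth
#' dynamic synaptic connectivity (DSC).
#'
#' @slot values numeric matrix, synapses by seconds.
#' @slot edges data.frame (\code{pre}, \code{post}, \code{delay}) matching
#'   rows of \code{values}.
#' @exportClass WeightTrajectory
setClass("WeightTrajectory",
    representation(values = "matrix", edges = "data.frame"))

setValidity("WeightTrajectory", function(object) {
    if (nrow(object@values) != nrow(object@edges))
        return("one edge row per trajectory row required")
    TRUE
})

#' Simulation result bundle
#'
#' @slot network the \code{SpikingNetwork} with final weights.
#' @slot raster the emitted \code{SpikeRaster}.
#' @slot weights the \code{WeightTrajectory} (1-s sampling).
#' @slot seed master seed of the run.
#' @exportClass NetworkSimulation
setClass("NetworkSimulation",
    representation(network = "SpikingNetwork", raster = "SpikeRaster",
                   weights = "WeightTrajectory", seed = "integer"))

#' Static functional connectivity of all directed pairs
#'
#' For each ordered pair (i, j) the measure profile over candidate delays is
#' reduced to the value at the delay maximizing its magnitude
#' (\code{values}, signed for correlation-based measures) and that argmax
#' delay (\code{delayHat}, ties broken toward the smallest delay). Pairs
#' involving silent neurons are NA and rank last.
#'
#' @slot measure one of \code{"xcov"}, \code{"xcorr"}, \code{"te"},
#'   \code{"hote"}, or \code{"overlap"} for a rank-overlap index.
#' @slot values,delayHat square matrices (diagonal NA).
#' @slot delays candidate delays swept (ms).
#' @slot durationMin length of raster segment used.
#' @slot signed whether \code{values} carries a sign.
#' @exportClass StaticFC
setClass("StaticFC",
    representation(measure = "character", values = "matrix",
                   delayHat = "matrix", delays = "integer",
                   durationMin = "numeric", signed = "logical"))

#' Dynamic functional connectivity series
#'
#' One FC value per retained pair per non-overlapping window.
#'
#' @slot values pairs-by-windows numeric matrix.
#' @slot pairs data.frame (\code{pre}, \code{post}, \code{delayHat}).
#' @slot windowMin window width (minutes).
#' @slot measure FC measure label.
#' @slot delayConsistent TRUE if each window was evaluated at the statically
#'   inferred delay, FALSE if at the per-window argmax over the sweep.
#' @exportClass DFCSeries
setClass("DFCSeries",
    representation(values = "matrix", pairs = "data.frame",
                   windowMin = "numeric", measure = "character",
                   delayConsistent = "logical"))

#' Window-averaged ground-truth weight series
#'
#' @slot values synapses-by-windows matrix of window-mean weights.
#' @slot edges data.frame (\code{pre}, \code{post}) matching rows.
#' @slot windowMin window width (minutes).
#' @exportClass DSCSeries
setClass("DSCSeries",
    representation(values = "matrix", edges = "data.frame",
                   windowMin = "numeric"))
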