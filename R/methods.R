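# Accessor and show methods

#' @rdname synfc-accessors
setMethod("nNeurons", "SpikingNetwork", function(x) x@nNeurons)
#' @rdname synfc-accessors
setMethod("nNeurons", "SpikeRaster", function(x) x@nNeurons)
#' @rdname synfc-accessors
setMethod("nNeurons", "StaticFC", function(x) nrow(x@values))

#' @rdname synfc-accessors
setMethod("edges", "SpikingNetwork", function(x) x@edges)
#' @rdname synfc-accessors
setMethod("edges", "WeightTrajectory", function(x) x@edges)
#' @rdname synfc-accessors
setMethod("edges", "DSCSeries", function(x) x@edges)

#' @rdname synfc-accessors
setMethod("isExcitatory", "SpikingNetwork", function(x) x@isExcitatory)

#' @rdname synfc-accessors
setMethod("spikeTimes", "SpikeRaster", function(x) x@spikeTimes)

#' @rdname synfc-accessors
setMethod("durationMin", "SpikeRaster", function(x) x@durationMs / 60000)
#' @rdname synfc-accessors
setMethod("durationMin", "StaticFC", function(x) x@durationMin)

#' @rdname synfc-accessors
setMethod("fcValues", "StaticFC", function(x) x@values)
#' @rdname synfc-accessors
setMethod("fcValues", "WeightTrajectory", function(x) x@values)
#' @rdname synfc-accessors
setMethod("fcValues", "DFCSeries", function(x) x@values)
#' @rdname synfc-accessors
setMethod("fcValues", "DSCSeries", function(x) x@values)

#' @rdname synfc-accessors
setMethod("delayEstimates", "StaticFC", function(x) x@delayHat)

#' @rdname synfc-accessors
setMethod("fcMeasure", "StaticFC", function(x) x@measure)
#' @rdname synfc-accessors
setMethod("fcMeasure", "DFCSeries", function(x) x@measure)

#' @rdname synfc-accessors
setMethod("raster", "NetworkSimulation", function(x) x@raster)
#' @rdname synfc-accessors
setMethod("weightTrajectory", "NetworkSimulation", function(x) x@weights)
#' @rdname synfc-accessors
setMethod("groundTruth", "NetworkSimulation", function(x) x@network)

#' @rdname synfc-accessors
setMethod("windowMin", "DFCSeries", function(x) x@windowMin)
#' @rdname synfc-accessors
setMethod("windowMin", "DSCSeries", function(x) x@windowMin)

#' @rdname synfc-accessors
#' @param tRange optional \code{c(from, to)} ms range (1-based, inclusive).
setMethod("spikeMatrix", "SpikeRaster", function(x, tRange = NULL) {
    if (is.null(tRange)) tRange <- c(1L, x@durationMs)
    t0 <- as.integer(tRange[1]); t1 <- as.integer(tRange[2])
    stopifnot(t0 >= 1L, t1 <= x@durationMs, t0 <= t1)
    ii <- rep.int(seq_len(x@nNeurons),
                  vapply(x@spikeTimes, function(st)
                      sum(st >= t0 & st <= t1), integer(1)))
    tt <- unlist(lapply(x@spikeTimes, function(st) st[st >= t0 & st <= t1]),
                 use.names = FALSE)
    Matrix::sparseMatrix(i = ii, j = tt - t0 + 1L,
                         dims = c(x@nNeurons, t1 - t0 + 1L), x = 1)
})

#' @rdname synfc-accessors
#' @param tRangeMs optional ms range over which rates are computed.
setMethod("firingRates", "SpikeRaster", function(x, tRangeMs = NULL) {
    if (is.null(tRangeMs)) tRangeMs <- c(1L, x@durationMs)
    span <- (tRangeMs[2] - tRangeMs[1] + 1) / 1000
    vapply(x@spikeTimes, function(st)
        sum(st >= tRangeMs[1] & st <= tRangeMs[2]) / span, numeric(1))
})

setMethod("show", "SpikingNetwork", function(object) {
    e <- object@edges
    exc <- object@isExcitatory[e$pre]
    cat("SpikingNetwork:", object@nNeurons, "neurons (",
        sum(object@isExcitatory), "excitatory /",
        sum(!object@isExcitatory), "inhibitory )\n")
    cat("  synapses:", sum(exc), "excitatory,", sum(!exc), "inhibitory\n")
    cat("  excitatory delays:", min(e$delay[exc]), "-", max(e$delay[exc]),
        "ms; STDP A+ =", object@stdp$aPlus, ", A- =", object@stdp$aMinus,
        ", tau =", object@stdp$tauMs, "ms\n")
})

setMethod("show", "SpikeRaster", function(object) {
    ns <- sum(lengths(object@spikeTimes))
    cat("SpikeRaster:", object@nNeurons, "neurons x", object@durationMs,
        "ms (", round(object@durationMs / 60000, 2), "min ),", ns,
        "spikes\n")
    cat("  mean rate:", round(ns / object@nNeurons /
        (object@durationMs / 1000), 2), "Hz\n")
})

setMethod("show", "WeightTrajectory", function(object) {
    cat("WeightTrajectory:", nrow(object@values), "plastic synapses x",
        ncol(object@values), "s\n")
})

setMethod("show", "NetworkSimulation", function(object) {
    cat("NetworkSimulation (seed", object@seed, ")\n")
    show(object@network); show(object@raster); show(object@weights)
})

setMethod("show", "StaticFC", function(object) {
    cat("StaticFC:", object@measure, "over delays",
        min(object@delays), "-", max(object@delays), "ms,",
        nrow(object@values), "neurons,", object@durationMin, "min\n")
})

setMethod("show", "DFCSeries", function(object) {
    cat("DFCSeries:", object@measure, ",", nrow(object@values), "pairs x",
        ncol(object@values), "windows of", object@windowMin, "min,",
        if (object@delayConsistent) "delay-consistent" else
            "per-window argmax", "\n")
})

setMethod("show", "DSCSeries", function(object) {
    cat("DSCSeries:", nrow(object@values), "synapses x",
        ncol(object@values), "windows of", object@windowMin, "min\n")
})
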