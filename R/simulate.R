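#' Izhikevich neuron parameter presets
#'
#' Two presets are used: regular-spiking for excitatory neurons,
#' \code{(a, b, c, d) = (0.02, 0.2, -65, 8)}, and fast-spiking for
#' inhibitory neurons, \code{(0.1, 0.2, -65, 2)}.
#'
#' @param type \code{"rs"} (regular spiking) or \code{"fs"} (fast spiking).
#' @return named list with elements \code{a}, \code{b}, \code{c}, \code{d}.
#' @export
izhikevichParams <- function(type = c("rs", "fs")) {
    type <- match.arg(type)
    if (type == "rs") list(a = 0.02, b = 0.2, c = -65, d = 8)
    else              list(a = 0.1,  b = 0.2, c = -65, d = 2)
}

#' Advance an Izhikevich neuron by one 1-ms step
#'
#' Applies the threshold/reset rule (a neuron whose potential has reached
#' 30 mV emits a spike, \code{v <- c}, \code{u <- u + d}), then advances
#' \code{v' = 0.04 v^2 + 5 v + 140 - u + I} with two 0.5-ms Euler substeps
#' and \code{u' = a (b v - u)} with one 1-ms step.
#'
#' @param v,u membrane potential (mV) and recovery variable.
#' @param params preset list from \code{\link{izhikevichParams}}.
#' @param inputMv total synaptic + external input this step (mV).
#' @return list \code{(v, u, spiked)}.
#' @export
izhikevichStep <- function(v, u, params = izhikevichParams("rs"),
                           inputMv = 0) {
    if (!is.finite(v) || !is.finite(u))
        stop("non-finite neuron state")
    spiked <- v >= 30
    if (spiked) { v <- params$c; u <- u + params$d }
    v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + inputMv)
    v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + inputMv)
    u <- u + params$a * (params$b * v - u)
    list(v = v, u = u, spiked = spiked)
}

#' Integrate a single Izhikevich neuron over an input trace
#'
#' Runs the same compiled 1-ms integration scheme as the network simulator
#' on one neuron with a user-supplied input, returning the full state
#' trajectory and the spike indicator per step.
#'
#' @param params preset list from \code{\link{izhikevichParams}}.
#' @param inputMv numeric vector, one input value per 1-ms step.
#' @param v0,u0 initial state (defaults: rest at -65 mV, \code{u0 = b v0}).
#' @return list \code{(v, u, spiked)} of per-step vectors.
#' @export
izhikevichTrace <- function(params = izhikevichParams("rs"), inputMv,
                            v0 = -65, u0 = params$b * v0) {
    izh_trace_cpp(params$a, params$b, params$c, params$d,
                  as.numeric(inputMv), v0, u0)
}

#' STDP weight-change kernel
#'
#' Asymmetric Hebbian exponential rule: a presynaptic arrival \code{dtMs}
#' ms before the postsynaptic spike (\code{dtMs > 0}) potentiates by
#' \code{aPlus * exp(-|dtMs| / tauMs)}; a postsynaptic spike before the
#' arrival (\code{dtMs < 0}) depresses by
#' \code{-aMinus * exp(-|dtMs| / tauMs)}. \code{dtMs = 0} counts as
#' potentiation.
#'
#' @param dtMs signed pre-to-post timing difference(s), ms.
#' @param aPlus,aMinus,tauMs kernel parameters.
#' @return weight increment(s), mV.
#' @export
stdpKernel <- function(dtMs, aPlus = 0.1, aMinus = 0.12, tauMs = 20) {
    stopifnot(tauMs > 0)
    ifelse(dtMs >= 0, aPlus * exp(-abs(dtMs) / tauMs),
           -aMinus * exp(-abs(dtMs) / tauMs))
}

#' Apply a 1-s synaptic weight update epoch
#'
#' Adds the accumulated change (plus an optional constant drift) to each
#' plastic weight, clips to \code{[0, wMax]}, and carries the accumulator
#' over scaled by the memory factor.
#'
#' @param w,dw current weights and accumulated changes (mV).
#' @param wMax upper cut-off (mV).
#' @param memoryFactor accumulator carry-over per epoch.
#' @param drift constant added to every plastic weight per epoch (mV).
#' @return list \code{(w, dw)} after the update.
#' @export
updateWeights <- function(w, dw, wMax = 10, memoryFactor = 0.9, drift = 0) {
    list(w = pmin(wMax, pmax(0, w + dw + drift)), dw = memoryFactor * dw)
}

#' Simulate the plastic spiking network
#'
#' Integrates the network at 1-ms resolution: presynaptic spikes are
#' delivered to their targets after the synapse's conduction delay, an
#' external +\code{externalInputMv} drive hits one uniformly chosen neuron
#' per step, and excitatory weights evolve under trace-based STDP with a
#' 1-s update epoch and memory factor. The presynaptic timestamp of the
#' STDP rule is the spike \emph{arrival} time (emission + delay).
#'
#' @param network a \code{\link{SpikingNetwork}}.
#' @param durationMin simulated duration in minutes (>= 1/60).
#' @param seed integer master seed for the run's randomness.
#' @param stdp set \code{FALSE} to freeze all weights.
#' @param externalInputMv amplitude of the random external drive (mV).
#' @param weightDrift constant added to every plastic weight at each 1-s
#'   update (mV), before clipping; the reference cortical model uses 0.01.
#'   Set 0 to disable.
#' @param stdpTraces \code{"reset"} (a spike resets its trace to unit
#'   amplitude, the nearest-spike convention of the reference cortical
#'   model) or \code{"additive"} (all-pairs accumulation).
#' @return a \code{\link{NetworkSimulation}} bundling the spike raster, the
#'   1-s weight trajectory of the plastic synapses, and the network with
#'   final weights.
#' @examples
#' sim <- simulateNetwork(buildNetwork(seed = 1), durationMin = 0.05,
#'                        seed = 1)
#' mean(firingRates(raster(sim)))
#' @export
simulateNetwork <- function(network, durationMin, seed = NULL,
                            stdp = TRUE, externalInputMv = 20,
                            weightDrift = 0.01,
                            stdpTraces = c("reset", "additive")) {
    stdpTraces <- match.arg(stdpTraces)
    stopifnot(is(network, "SpikingNetwork"))
    durationMs <- as.integer(round(durationMin * 60000))
    if (durationMs < 1000L)
        stop("duration must cover at least one 1-s update epoch")
    if (!is.null(seed)) set.seed(seed)
    e <- edges(network)
    prm <- izhParamsFor(network)
    res <- sim_network_cpp(nNeurons(network), isExcitatory(network),
                           e$pre, e$post, e$delay, e$weight,
                           prm$a, prm$b, prm$c, prm$d,
                           durationMs,
                           network@stdp$aPlus, network@stdp$aMinus,
                           network@stdp$tauMs, network@stdp$memoryFactor,
                           network@stdp$wMax, weightDrift,
                           externalInputMv, stdp,
                           stdpTraces == "additive")
    seedInt <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    ras <- new("SpikeRaster",
               spikeTimes = lapply(res$spike_times, as.integer),
               nNeurons = nNeurons(network), durationMs = durationMs,
               seed = seedInt,
               metadata = list(stdp = stdp,
                               externalInputMv = externalInputMv,
                               weightDrift = weightDrift,
                               stdpTraces = stdpTraces,
                               stdpPairing = "trace-based, presynaptic timestamp at arrival"))
    pidx <- res$plastic_idx + 1L
    wt <- new("WeightTrajectory", values = res$w_traj,
              edges = e[pidx, c("pre", "post", "delay"), drop = FALSE])
    rownames(wt@edges) <- NULL
    net2 <- network
    net2@edges$weight <- res$w_final
    new("NetworkSimulation", network = net2, raster = ras, weights = wt,
        seed = seedInt)
}

# per-neuron Izhikevich coefficients from the two presets
izhParamsFor <- function(network) {
    rs <- izhikevichParams("rs"); fs <- izhikevichParams("fs")
    exc <- isExcitatory(network)
    list(a = ifelse(exc, rs$a, fs$a), b = ifelse(exc, rs$b, fs$b),
         c = ifelse(exc, rs$c, fs$c), d = ifelse(exc, rs$d, fs$d))
}

#' Autocorrelation half-life of the weight trajectory
#'
#' Computes each plastic synapse's autocorrelation function from its
#' mean-subtracted 1-s weight series, averages across synapses (constant
#' series are excluded), and returns the lag at which the mean
#' autocorrelation first drops below 0.5, linearly interpolated between
#' 1-s lags.
#'
#' @param weights a \code{\link{WeightTrajectory}}.
#' @param maxLagS largest lag examined (s).
#' @return half-life in seconds.
#' @export
weightAutocorrHalfLife <- function(weights, maxLagS = 600) {
    w <- fcValues(weights)
    keep <- apply(w, 1, function(x) sd(x) > 0)
    if (!any(keep))
        stop("all weight series are constant; autocorrelation undefined")
    maxLagS <- min(maxLagS, ncol(w) - 2L)
    ac <- vapply(which(keep), function(r)
        as.numeric(acf(w[r, ], lag.max = maxLagS, plot = FALSE,
                       demean = TRUE)$acf),
        numeric(maxLagS + 1L))
    m <- rowMeans(ac)                       # lag 0 ... maxLagS
    below <- which(m < 0.5)
    if (!length(below))
        stop("mean autocorrelation never drops below 0.5 within maxLagS")
    k <- below[1]                           # first lag index (1-based)
    hi <- m[k - 1]; lo <- m[k]
    (k - 2) + (hi - 0.5) / (hi - lo)        # lags are k-2 and k-1 seconds
}
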