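#' Select pairs for dynamic FC
#'
#' Retains the directed pairs whose static FC magnitude lies in the top
#' 5th percentile (strictly above the \code{100 - topPercent} percentile of
#' the magnitude distribution), then restricts to putatively excitatory
#' pairs, whose synaptic weight is the plastic quantity being tracked.
#' Two restriction modes are available: \code{"sign"} keeps pairs whose
#' signed FC value is positive (a companion signed result can be supplied
#' via \code{signFC} when the selecting measure is unsigned), and
#' \code{"truth"} keeps pairs that are ground-truth excitatory synapses
#' (evaluation mode).
#'
#' @param fc the selecting \code{\link{StaticFC}}.
#' @param network ground-truth \code{\link{SpikingNetwork}} (needed for
#'   \code{mode = "truth"}).
#' @param signFC optional signed \code{StaticFC} to supply the sign when
#'   \code{fc} is unsigned.
#' @param topPercent retained top share of pairs (default 5).
#' @param mode \code{"sign"} or \code{"truth"}.
#' @return data.frame (\code{pre}, \code{post}, \code{delayHat}) with the
#'   selection mode recorded in attribute \code{"mode"}.
#' @export
selectDFCPairs <- function(fc, network = NULL, signFC = NULL,
                           topPercent = 5, mode = c("sign", "truth")) {
    mode <- match.arg(mode)
    adj <- thresholdNetwork(fc, 100 - topPercent)
    if (mode == "sign") {
        sgn <- if (fc@signed) fc else signFC
        if (is.null(sgn))
            stop("mode = \"sign\" with an unsigned measure needs signFC")
        adj <- adj & !is.na(fcValues(sgn)) & fcValues(sgn) > 0
    } else {
        if (is.null(network)) stop("mode = \"truth\" needs the network")
        exc <- isExcitatory(network)
        truth <- trueAdjacency(network)
        truth[!exc, ] <- FALSE          # keep excitatory synapses only
        adj <- adj & truth
    }
    idx <- which(adj, arr.ind = TRUE)
    out <- data.frame(pre = idx[, 1], post = idx[, 2],
                      delayHat = delayEstimates(fc)[idx])
    out <- out[order(out$pre, out$post), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "mode") <- mode
    out
}

#' Sliding-window dynamic functional connectivity
#'
#' Computes one FC value per pair per non-overlapping window of width
#' \code{windowMin} minutes, windows aligned to t = 0 with any trailing
#' remainder discarded. With \code{delayConsistent = TRUE} each window is
#' evaluated only at the pair's statically inferred delay
#' (\code{pairs$delayHat}); otherwise the value at the per-window
#' magnitude-argmax over \code{delays} is used. Windows in which either
#' neuron is silent give undefined (NA) samples for the correlation-based
#' measures.
#'
#' @param raster a \code{\link{SpikeRaster}}.
#' @param pairs data.frame from \code{\link{selectDFCPairs}} (columns
#'   \code{pre}, \code{post}, and \code{delayHat} when delay-consistent).
#' @param windowMin window width in minutes; at least 2 windows must fit.
#' @param measure \code{"xcov"}, \code{"xcorr"}, \code{"te"} or
#'   \code{"hote"}.
#' @param delayConsistent evaluate at the fixed inferred delay (default)
#'   or sweep \code{delays} per window.
#' @param delays sweep used when not delay-consistent.
#' @param k,l word lengths for \code{"hote"}.
#' @return a \code{\link{DFCSeries}}.
#' @export
dfcSliding <- function(raster, pairs, windowMin,
                       measure = c("xcov", "xcorr", "te", "hote"),
                       delayConsistent = TRUE, delays = 1:50,
                       k = 5L, l = 5L) {
    measure <- match.arg(measure)
    winMs <- as.integer(round(windowMin * 60000))
    nWin <- raster@durationMs %/% winMs
    if (nWin < 2) stop("window width must fit at least twice")
    pm <- as.matrix(pairs[, c("pre", "post")])
    storage.mode(pm) <- "integer"
    vals <- matrix(NA_real_, nrow(pairs), nWin)
    st <- spikeTimes(raster)
    for (w in seq_len(nWin)) {
        t0 <- (w - 1L) * winMs + 1L; t1 <- w * winMs
        if (delayConsistent) {
            dh <- as.integer(pairs$delayHat)
            if (anyNA(dh)) stop("delay-consistent DFC needs delayHat")
            for (d in unique(dh)) {
                rows <- which(dh == d)
                prof <- fcProfiles(st, pm[rows, , drop = FALSE], d,
                                   t0, t1, measure, k, l)
                vals[rows, w] <- prof[, 1]
            }
        } else {
            sw <- fcSweep(st, pm, as.integer(delays), t0, t1, measure, k, l)
            vals[, w] <- sw$values
        }
    }
    new("DFCSeries", values = vals, pairs = as.data.frame(pairs),
        windowMin = windowMin, measure = measure,
        delayConsistent = delayConsistent)
}

#' Window-averaged ground-truth weight series
#'
#' Averages the 1-s weight samples of each plastic synapse within each
#' non-overlapping window of width \code{windowMin} minutes, so DSC and
#' DFC share one window grid.
#'
#' @param weights a \code{\link{WeightTrajectory}}.
#' @param windowMin window width in minutes.
#' @return a \code{\link{DSCSeries}}.
#' @export
dscWindowed <- function(weights, windowMin) {
    w <- fcValues(weights)
    winS <- as.integer(round(windowMin * 60))
    nWin <- ncol(w) %/% winS
    if (nWin < 1) stop("window width exceeds the trajectory")
    vals <- vapply(seq_len(nWin), function(k)
        rowMeans(w[, ((k - 1L) * winS + 1L):(k * winS), drop = FALSE]),
        numeric(nrow(w)))
    vals <- matrix(vals, nrow = nrow(w))
    new("DSCSeries", values = vals, edges = edges(weights),
        windowMin = windowMin)
}

#' Across-time correlation between DFC and ground-truth weight dynamics
#'
#' For every DFC pair that matches a ground-truth synapse, computes the
#' Pearson correlation across time between the pair's DFC series and the
#' synapse's window-averaged weight series. To remove the sample-size
#' confound when comparing window widths, both series are first subsampled
#' to the number of windows a \code{matchToMin}-minute window would give
#' (evenly spaced by default, or seeded uniform-random). Pairs without a
#' ground-truth synapse (false positives) have no weight series and are
#' excluded but counted; zero-variance series are flagged and excluded
#' from the mean.
#'
#' @param dfc a \code{\link{DFCSeries}}.
#' @param dsc a \code{\link{DSCSeries}} on the same window grid.
#' @param matchToMin window width whose sample count is matched
#'   (default 30 min).
#' @param subsample \code{"even"} or \code{"random"}.
#' @param seed seed for random subsampling.
#' @return list with \code{perPair} (data.frame \code{pre}, \code{post},
#'   \code{correlation}, \code{nSamples}), \code{meanCorrelation},
#'   \code{nFalsePositive}, \code{nExcluded}, and the subsampling scheme.
#' @export
dfcDscCorrelation <- function(dfc, dsc, matchToMin = 30,
                              subsample = c("even", "random"),
                              seed = NULL) {
    subsample <- match.arg(subsample)
    stopifnot(windowMin(dfc) == windowMin(dsc))
    nWin <- ncol(fcValues(dfc))
    stopifnot(ncol(fcValues(dsc)) == nWin)
    durMin <- nWin * windowMin(dfc)
    m <- min(as.integer(floor(durMin / matchToMin)), nWin)
    if (m < 3)
        stop("fewer than 3 samples after matching; use a longer recording ",
             "or a smaller matchToMin")
    if (subsample == "even") {
        keep <- unique(as.integer(round(seq(1, nWin, length.out = m))))
    } else {
        if (!is.null(seed)) set.seed(seed)
        keep <- sort(sample.int(nWin, m))
    }

    key <- paste(edges(dsc)$pre, edges(dsc)$post)
    rowOf <- match(paste(dfc@pairs$pre, dfc@pairs$post), key)
    nFP <- sum(is.na(rowOf))
    cors <- rep(NA_real_, nrow(dfc@pairs))
    ns <- integer(nrow(dfc@pairs))
    for (r in which(!is.na(rowOf))) {
        x <- fcValues(dfc)[r, keep]
        y <- fcValues(dsc)[rowOf[r], keep]
        ok <- is.finite(x) & is.finite(y)
        ns[r] <- sum(ok)
        if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0)
            cors[r] <- cor(x[ok], y[ok])
    }
    matched <- !is.na(rowOf)
    perPair <- data.frame(pre = dfc@pairs$pre, post = dfc@pairs$post,
                          correlation = cors, nSamples = ns)[matched, ]
    rownames(perPair) <- NULL
    list(perPair = perPair,
         meanCorrelation = mean(perPair$correlation, na.rm = TRUE),
         nFalsePositive = nFP,
         nExcluded = sum(is.na(perPair$correlation)),
         subsample = subsample, sampleIndices = keep)
}
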