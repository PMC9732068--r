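#' Static functional connectivity over all directed pairs
#'
#' Sweeps one connectivity measure over candidate delays for every ordered
#' neuron pair and reduces each profile to the value at the delay of
#' maximum magnitude (ties broken toward the smallest delay). For the
#' signed correlation measures the magnitude is used for the argmax and the
#' signed value is kept; transfer-entropy measures are non-negative.
#' Pairs involving neurons that never fire in the analyzed range are
#' undefined (NA) and rank last in all downstream thresholding.
#'
#' @param raster a \code{\link{SpikeRaster}}.
#' @param measure \code{"xcov"}, \code{"xcorr"}, \code{"te"} or
#'   \code{"hote"}.
#' @param delays candidate delays in ms (default 1--50).
#' @param k,l past word lengths for \code{"hote"} (default 5 ms each).
#' @param tRangeMs optional \code{c(from, to)} ms restriction, e.g. a
#'   prefix of the recording or one sliding window.
#' @return a \code{\link{StaticFC}}.
#' @export
staticFC <- function(raster, measure = c("xcov", "xcorr", "te", "hote"),
                     delays = 1:50, k = 5L, l = 5L, tRangeMs = NULL) {
    measure <- match.arg(measure)
    stopifnot(is(raster, "SpikeRaster"))
    if (is.null(tRangeMs)) tRangeMs <- c(1L, raster@durationMs)
    t0 <- as.integer(tRangeMs[1]); t1 <- as.integer(tRangeMs[2])
    delays <- as.integer(delays)
    N <- nNeurons(raster)
    prs <- allPairs(N)
    res <- fcSweep(spikeTimes(raster), prs, delays, t0, t1, measure, k, l)
    silent <- vapply(spikeTimes(raster), function(st)
        !any(st >= t0 & st <= t1), logical(1))
    badPair <- silent[prs[, 1]] | silent[prs[, 2]]
    res$values[badPair] <- NA_real_
    res$delayHat[badPair] <- NA_integer_

    vals <- matrix(NA_real_, N, N)
    dh <- matrix(NA_integer_, N, N)
    vals[prs] <- res$values
    dh[prs] <- res$delayHat
    new("StaticFC", measure = measure, values = vals, delayHat = dh,
        delays = delays, durationMin = (t1 - t0 + 1) / 60000,
        signed = measure %in% c("xcov", "xcorr"))
}

allPairs <- function(N) {
    g <- expand.grid(pre = seq_len(N), post = seq_len(N))
    as.matrix(g[g$pre != g$post, c("pre", "post")])
}

# profile sweep + magnitude-argmax reduction for an arbitrary pair list;
# returns per-pair signed value and argmax delay
fcSweep <- function(spikeTimes, pairs, delays, t0, t1, measure, k, l) {
    prof <- fcProfiles(spikeTimes, pairs, delays, t0, t1, measure, k, l)
    reduceProfiles(prof, delays,
                   signed = measure %in% c("xcov", "xcorr"))
}

fcProfiles <- function(spikeTimes, pairs, delays, t0, t1, measure, k, l) {
    if (measure %in% c("xcov", "xcorr")) {
        cc <- fc_count_sweep_cpp(spikeTimes, pairs, delays, t0, t1)
        n <- matrix((t1 - t0 + 1) - delays, nrow(pairs), length(delays),
                    byrow = TRUE)
        pi_ <- cc$ni / n; pj_ <- cc$nj / n
        den <- sqrt(pi_ * (1 - pi_) * pj_ * (1 - pj_))
        prof <- if (measure == "xcov") (cc$count / n - pi_ * pj_) / den
                else (cc$count / n) / den
        prof[den == 0] <- NA_real_
        prof
    } else {
        if (measure == "te") { k <- 1L; l <- 1L }
        fc_te_sweep_cpp(spikeTimes, pairs, delays, t0, t1,
                        as.integer(k), as.integer(l))
    }
}

reduceProfiles <- function(prof, delays, signed) {
    mag <- if (signed) abs(prof) else prof
    mag[is.na(mag)] <- -Inf
    idx <- max.col(mag, ties.method = "first")
    ok <- is.finite(mag[cbind(seq_len(nrow(prof)), idx)])
    vals <- prof[cbind(seq_len(nrow(prof)), idx)]
    vals[!ok] <- NA_real_
    dh <- delays[idx]
    dh[!ok] <- NA_integer_
    list(values = vals, delayHat = as.integer(dh))
}

#' Threshold static FC into an inferred adjacency
#'
#' A directed pair is retained iff the magnitude of its static FC value
#' strictly exceeds the given percentile (linear-interpolation quantile) of
#' the magnitude distribution over all defined pairs. Higher percentiles
#' give sparser, nested networks. Undefined pairs are never retained.
#'
#' @param fc a \code{\link{StaticFC}}.
#' @param percentile threshold percentile in [1, 99].
#' @return logical adjacency matrix (rows = presynaptic).
#' @export
thresholdNetwork <- function(fc, percentile) {
    stopifnot(percentile >= 1, percentile <= 99)
    sc <- fcScores(fc)
    thr <- quantile(sc[!diag(TRUE, nrow(sc))], percentile / 100,
                    na.rm = TRUE, names = FALSE, type = 7)
    adj <- !is.na(sc) & sc > thr
    diag(adj) <- FALSE
    adj
}

fcScores <- function(fc) {
    v <- fcValues(fc)
    if (fc@signed) abs(v) else v
}

#' Precision-recall curve of synapse-presence inference
#'
#' Compares thresholded networks at every percentile in
#' \code{percentiles} against the ground-truth directed adjacency.
#'
#' @param fc a \code{\link{StaticFC}} (or rank-overlap result).
#' @param network the ground-truth \code{\link{SpikingNetwork}}.
#' @param percentiles thresholds to evaluate (default 1--99).
#' @return data.frame with columns \code{percentile}, \code{tp}, \code{fp},
#'   \code{fn}, \code{precision}, \code{recall}.
#' @export
prCurve <- function(fc, network, percentiles = 1:99) {
    truth <- trueAdjacency(network)
    if (!any(truth)) stop("ground truth contains no synapses")
    stopifnot(nrow(truth) == nNeurons(fc))
    out <- lapply(percentiles, function(p) {
        adj <- thresholdNetwork(fc, p)
        tp <- sum(adj & truth); fp <- sum(adj & !truth)
        fn <- sum(!adj & truth)
        data.frame(percentile = p, tp = tp, fp = fp, fn = fn,
                   precision = tp / (tp + fp), recall = tp / (tp + fn))
    })
    do.call(rbind, out)
}

#' Ground-truth directed adjacency matrix
#' @param network a \code{\link{SpikingNetwork}}.
#' @return logical matrix (rows = presynaptic).
#' @export
trueAdjacency <- function(network) {
    N <- nNeurons(network)
    adj <- matrix(FALSE, N, N)
    e <- edges(network)
    adj[cbind(e$pre, e$post)] <- TRUE
    adj
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integration over recall. Duplicate recall values keep their
#' maximum precision, and the curve is anchored by extending its extreme
#' recall points horizontally to recall 0 and 1.
#'
#' @param pr a data.frame from \code{\link{prCurve}} (columns
#'   \code{precision}, \code{recall}).
#' @return scalar AUPR in [0, 1].
#' @export
auprScore <- function(pr) {
    ok <- is.finite(pr$precision) & is.finite(pr$recall)
    rec <- pr$recall[ok]; prec <- pr$precision[ok]
    if (!length(rec)) stop("no finite precision-recall points")
    prec <- vapply(split(prec, rec), max, numeric(1))
    rec <- as.numeric(names(prec))
    o <- order(rec); rec <- rec[o]; prec <- prec[o]
    if (rec[1] > 0)               { rec <- c(0, rec); prec <- c(prec[1], prec) }
    if (rec[length(rec)] < 1)     { rec <- c(rec, 1); prec <- c(prec, prec[length(prec)]) }
    sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
}

#' Classify synapse sign from a signed FC measure
#'
#' Labels each directed pair excitatory if its static cross-covariance (or
#' cross-correlation) value is positive and inhibitory if negative, the
#' decision boundary being zero. Information-theoretic measures are
#' positively defined and carry no sign, so they are rejected.
#'
#' @param fc a signed \code{\link{StaticFC}} (xcov or xcorr).
#' @return character matrix with entries \code{"excitatory"},
#'   \code{"inhibitory"} or NA.
#' @export
classifySynapseSign <- function(fc) {
    if (!fc@signed)
        stop("sign classification requires a signed measure (xcov/xcorr); ",
             fcMeasure(fc), " is positively defined")
    v <- fcValues(fc)
    lab <- matrix(NA_character_, nrow(v), ncol(v))
    lab[!is.na(v) & v > 0] <- "excitatory"
    lab[!is.na(v) & v < 0] <- "inhibitory"
    lab
}

#' Delay-recovery accuracy on true positives
#'
#' Restricted to the true-positive pairs at the chosen presence threshold,
#' computes the Pearson correlation and mean absolute error between the
#' inferred delays and the ground-truth conduction delays.
#'
#' @param fc a \code{\link{StaticFC}}.
#' @param network the ground-truth \code{\link{SpikingNetwork}}.
#' @param percentile presence threshold (default 90).
#' @return list \code{(correlation, maeMs, nTruePositives)}.
#' @export
delayMetrics <- function(fc, network, percentile = 90) {
    adj <- thresholdNetwork(fc, percentile)
    truth <- trueAdjacency(network)
    tp <- which(adj & truth, arr.ind = TRUE)
    if (nrow(tp) < 2)
        stop("fewer than 2 true-positive pairs at this threshold")
    dhat <- delayEstimates(fc)[tp]
    e <- edges(network)
    dtrue <- matrix(NA_integer_, nNeurons(network), nNeurons(network))
    dtrue[cbind(e$pre, e$post)] <- e$delay
    dtrue <- dtrue[tp]
    list(correlation = cor(dhat, dtrue),
         maeMs = mean(abs(dhat - dtrue)),
         nTruePositives = nrow(tp))
}

#' Synapse-subgroup composition of an adjacency
#'
#' Fractions of retained directed pairs falling in the four subgroups
#' excitatory-to-excitatory, excitatory-to-inhibitory,
#' inhibitory-to-excitatory and inhibitory-to-inhibitory.
#'
#' @param adjacency logical matrix (rows = presynaptic).
#' @param isExcitatory logical vector of neuron types.
#' @return named numeric vector \code{c(EE, EI, IE, II)} summing to 1.
#' @export
subgroupFractions <- function(adjacency, isExcitatory) {
    idx <- which(adjacency, arr.ind = TRUE)
    if (!nrow(idx)) stop("adjacency contains no retained pairs")
    preE <- isExcitatory[idx[, 1]]; postE <- isExcitatory[idx[, 2]]
    c(EE = mean(preE & postE), EI = mean(preE & !postE),
      IE = mean(!preE & postE), II = mean(!preE & !postE))
}
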