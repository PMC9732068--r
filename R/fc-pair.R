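# Pairwise functional-connectivity measures on binary 1-ms spike trains.
# All measures are directed (sender i, receiver j) and evaluated at a
# candidate delay in ms; expectations run over the valid lagged overlap
# t = delay+1 ... T only (no circular wrap-around).

asSpikeList <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
        stop("spike trains must be binary 0/1 vectors")
    list(as.integer(which(x != 0)), as.integer(which(y != 0)))
}

pairCounts <- function(x, y, delay) {
    st <- asSpikeList(x, y)
    if (length(x) < delay + 2)
        stop("trains must be longer than delay + 1")
    cc <- fc_count_sweep_cpp(st, matrix(c(1L, 2L), 1), as.integer(delay),
                             1L, length(x))
    list(count = cc$count[1, 1], ni = cc$ni[1, 1], nj = cc$nj[1, 1],
         n = length(x) - delay)
}

corrFromCounts <- function(count, ni, nj, n, subtractMean) {
    pi <- ni / n; pj <- nj / n
    den <- sqrt(pi * (1 - pi) * pj * (1 - pj))
    if (den == 0) return(NA_real_)
    if (subtractMean) (count / n - pi * pj) / den else (count / n) / den
}

#' Directed pairwise connectivity at a candidate delay
#'
#' \code{xcorrPair} is the normalized cross-correlation
#' \code{E[i_(t-delay) j_t] / (sigma_i sigma_j)}; \code{xcovPair} is the
#' normalized cross-covariance (Pearson correlation between the lagged
#' sender and the receiver, i.e. with mean rates subtracted).
#' \code{transferEntropyPair} is the plug-in transfer entropy in bits with
#' a 1-bin sender past at \code{t - delay} and a 1-bin receiver past at
#' \code{t - 1}; \code{higherOrderTEPair} generalizes to \code{k}-bin
#' sender and \code{l}-bin receiver past words (most recent bin in the
#' least-significant bit). Empty probability cells contribute zero; a
#' zero-variance train yields \code{NA} for the correlation measures.
#'
#' @param x,y binary 0/1 vectors of equal length (sender, receiver).
#' @param delay candidate delay in ms (bins), >= 1.
#' @param k,l past word lengths in bins, >= 1.
#' @return a single numeric value (correlation in [-1, 1], or bits >= 0).
#' @examples
#' x <- c(1, 0, 1, 0, 0, 1, 0, 1, 0)
#' y <- c(0, 1, 0, 1, 0, 0, 1, 0, 1)
#' xcovPair(x, y, delay = 1)
#' @export
xcorrPair <- function(x, y, delay) {
    cc <- pairCounts(x, y, delay)
    corrFromCounts(cc$count, cc$ni, cc$nj, cc$n, subtractMean = FALSE)
}

#' @rdname xcorrPair
#' @export
xcovPair <- function(x, y, delay) {
    cc <- pairCounts(x, y, delay)
    corrFromCounts(cc$count, cc$ni, cc$nj, cc$n, subtractMean = TRUE)
}

#' @rdname xcorrPair
#' @export
transferEntropyPair <- function(x, y, delay) {
    higherOrderTEPair(x, y, delay, k = 1L, l = 1L)
}

#' @rdname xcorrPair
#' @export
higherOrderTEPair <- function(x, y, delay, k = 5L, l = 5L) {
    if (k < 1 || l < 1) stop("word lengths k and l must be >= 1")
    st <- asSpikeList(x, y)
    if (length(x) < delay + max(k, l) + 1)
        stop("trains too short for this delay and word length")
    fc_te_sweep_cpp(st, matrix(c(1L, 2L), 1), as.integer(delay),
                    1L, length(x), as.integer(k), as.integer(l))[1, 1]
}

#' Rank-overlap index of two static FC results
#'
#' For every directed pair, the overlap index is the mean of the pair's
#' ascending ranks under the two measures (signed measures are ranked on
#' magnitude). A high overlap index means both measures place the pair
#' among their strongest. The index is used for synapse-presence inference
#' only; it carries no delay estimate.
#'
#' @param fc1,fc2 \code{\link{StaticFC}} objects over the same neurons.
#' @return a \code{StaticFC} with measure
#'   \code{"overlap(<m1>,<m2>)"}, unsigned values equal to the mean ranks,
#'   and no delay estimates.
#' @export
overlapIndex <- function(fc1, fc2) {
    stopifnot(is(fc1, "StaticFC"), is(fc2, "StaticFC"))
    if (nNeurons(fc1) != nNeurons(fc2))
        stop("the two FC results cover different pair sets")
    r1 <- overlapRanks(fc1); r2 <- overlapRanks(fc2)
    o <- (r1 + r2) / 2
    diag(o) <- NA_real_
    new("StaticFC", measure = paste0("overlap(", fcMeasure(fc1), ",",
                                     fcMeasure(fc2), ")"),
        values = o,
        delayHat = matrix(NA_integer_, nrow(o), ncol(o)),
        delays = fc1@delays, durationMin = fc1@durationMin, signed = FALSE)
}

# ascending ranks of the magnitude of off-diagonal FC values; undefined
# (silent-neuron) pairs rank lowest so they can never be retained
overlapRanks <- function(fc) {
    v <- fcValues(fc)
    if (fc@signed) v <- abs(v)
    off <- !diag(TRUE, nrow(v))
    r <- v
    r[off] <- rank(v[off], ties.method = "average", na.last = FALSE)
    r
}
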