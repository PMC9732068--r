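# Independent reference implementations used as oracles. These are written
# from the definitions (explicit loops and tabulation), deliberately not
# sharing code with the package's compiled paths.

# plug-in transfer entropy by exhaustive tabulation of
# (sender word, receiver bit, receiver word) triplets, in bits
bruteTE <- function(x, y, d, k = 1, l = 1) {
    T <- length(x)
    ts <- (max(d + k, l + 1)):T
    ws <- vapply(ts, function(t) sum(x[(t - d):(t - d - k + 1)] *
                                     2^(0:(k - 1))), numeric(1))
    wr <- vapply(ts, function(t) sum(y[(t - 1):(t - l)] *
                                     2^(0:(l - 1))), numeric(1))
    b <- y[ts]
    n <- length(ts)
    te <- 0
    for (vs in unique(ws)) for (vb in unique(b)) for (vr in unique(wr)) {
        c3 <- sum(ws == vs & b == vb & wr == vr)
        if (c3 == 0) next
        nsw <- sum(ws == vs & wr == vr)
        nbw <- sum(b == vb & wr == vr)
        nw <- sum(wr == vr)
        te <- te + c3 / n * log2(c3 * nw / (nsw * nbw))
    }
    te
}

# two-pass lagged Pearson correlation with population moments over the
# overlap t = d+1 ... T
bruteXCov <- function(x, y, d) {
    a <- x[1:(length(x) - d)]
    b <- y[(d + 1):length(y)]
    ma <- mean(a); mb <- mean(b)
    num <- mean((a - ma) * (b - mb))
    num / sqrt(mean((a - ma)^2) * mean((b - mb)^2))
}

bruteXCorr <- function(x, y, d) {
    a <- x[1:(length(x) - d)]
    b <- y[(d + 1):length(y)]
    mean(a * b) / sqrt(mean((a - mean(a))^2) * mean((b - mean(b))^2))
}

# scalar 1-ms reference loop for the Izhikevich integrator (two 0.5-ms
# Euler substeps for v, one 1-ms step for u, threshold check before
# integration)
bruteIzhLoop <- function(a, b, c, d, I, v0 = -65, u0 = b * v0) {
    v <- v0; u <- u0
    spikes <- integer(0)
    for (t in seq_along(I)) {
        if (v >= 30) { v <- c; u <- u + d; spikes <- c(spikes, t) }
        for (half in 1:2)
            v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + I[t])
        u <- u + a * (b * v - u)
    }
    spikes
}

# small StaticFC constructor for synthetic score matrices
fakeStaticFC <- function(values, delayHat = NULL, measure = "xcov",
                         signed = TRUE, delays = 1:50) {
    N <- nrow(values)
    diag(values) <- NA_real_
    if (is.null(delayHat)) {
        delayHat <- matrix(1L, N, N); diag(delayHat) <- NA_integer_
    }
    new("StaticFC", measure = measure, values = values,
        delayHat = delayHat, delays = as.integer(delays),
        durationMin = 1, signed = signed)
}

# binary raster object from a 0/1 matrix (neurons x ms)
rasterFromMatrix <- function(m) {
    new("SpikeRaster",
        spikeTimes = lapply(seq_len(nrow(m)), function(i)
            as.integer(which(m[i, ] != 0))),
        nNeurons = nrow(m), durationMs = ncol(m),
        seed = NA_integer_, metadata = list())
}
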