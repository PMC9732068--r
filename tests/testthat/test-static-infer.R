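test_that("every measure recovers a planted delay on lag-copy rasters", {
    set.seed(31)
    T <- 20000
    a <- rbinom(T, 1, 0.08)
    d <- 7L
    m <- rbind(a, c(integer(d), a[1:(T - d)]), rbinom(T, 1, 0.05))
    ras <- rasterFromMatrix(m)
    for (ms in c("xcov", "xcorr", "te")) {
        fc <- staticFC(ras, ms, delays = 1:20)
        expect_equal(delayEstimates(fc)[1, 2], d,
                     info = paste("measure", ms))
        expect_gt(abs(fcValues(fc)[1, 2]), abs(fcValues(fc)[1, 3]))
    }
    # a k-bin sender word resolves the lag only to within its width: any
    # word covering the copied bin is fully informative, so the argmax
    # lies in (d - k + 1) ... d and the profile there carries ~1 bit
    fc5 <- staticFC(ras, "hote", delays = 1:20, k = 5, l = 5)
    expect_true(delayEstimates(fc5)[1, 2] %in% (d - 4):d)
    # a noiseless copy transfers the full source entropy H(p)
    p <- mean(m[2, ])
    Hb <- -p * log2(p) - (1 - p) * log2(1 - p)
    expect_equal(fcValues(fc5)[1, 2], Hb, tolerance = 0.05)
    fc1 <- staticFC(ras, "hote", delays = 1:20, k = 1, l = 1)
    expect_equal(delayEstimates(fc1)[1, 2], d)
    # signed value is kept for xcov, and an anti-correlated pair is negative
    fc <- staticFC(ras, "xcov", delays = 1:20)
    expect_gt(fcValues(fc)[1, 2], 0.9)
})

test_that("delay ties break toward the smallest delay", {
    prof <- matrix(c(0.1, 0.3, 0.2, 0.3, 0.1), 1)
    red <- synfc:::reduceProfiles(prof, delays = 1:5, signed = TRUE)
    expect_equal(red$delayHat, 2L)
    # sign: magnitude argmax keeps the signed value
    prof2 <- matrix(c(0.1, -0.5, 0.2), 1)
    red2 <- synfc:::reduceProfiles(prof2, delays = 1:3, signed = TRUE)
    expect_equal(red2$values, -0.5)
    expect_equal(red2$delayHat, 2L)
})

test_that("percentile thresholding retains the expected counts, nested", {
    set.seed(32)
    v <- matrix(rnorm(100 * 100), 100)
    fc <- fakeStaticFC(v)
    a90 <- thresholdNetwork(fc, 90)
    expect_equal(sum(a90), round(0.10 * 9900))
    a95 <- thresholdNetwork(fc, 95)
    a99 <- thresholdNetwork(fc, 99)
    expect_false(any(a99 & !a95))
    expect_false(any(a95 & !a90))
})

test_that("silent neurons are undefined and can never be retained", {
    set.seed(33)
    m <- matrix(rbinom(5 * 4000, 1, 0.1), 5)
    m[4, ] <- 0
    fc <- staticFC(rasterFromMatrix(m), "xcov", delays = 1:5)
    expect_true(all(is.na(fcValues(fc)[4, ])))
    expect_true(all(is.na(fcValues(fc)[, 4])))
    adj <- thresholdNetwork(fc, 50)
    expect_false(any(adj[4, ] | adj[, 4]))
})

test_that("PR curve equals exhaustive enumeration on a small toy", {
    # 8 directed pairs, 3 true synapses, scores 0.1 ... 0.8
    truthEdges <- data.frame(pre = c(1, 2, 3), post = c(2, 3, 1),
                             delay = 1L, weight = 6)
    net <- new("SpikingNetwork", nNeurons = 3L,
               isExcitatory = rep(TRUE, 3), edges = truthEdges,
               stdp = list(aPlus = .1, aMinus = .12, tauMs = 20,
                           memoryFactor = .9, wMax = 10),
               seed = NA_integer_)
    v <- matrix(NA_real_, 3, 3)
    off <- which(!diag(TRUE, 3))
    scores <- c(0.4, 0.8, 0.3, 0.7, 0.2, 0.6)
    v[off] <- scores
    fc <- fakeStaticFC(v)
    pr <- prCurve(fc, net, percentiles = c(10, 25, 50, 75, 90))
    truth <- trueAdjacency(net)
    for (i in seq_len(nrow(pr))) {
        thr <- quantile(scores, pr$percentile[i] / 100, type = 7)
        keep <- !is.na(v) & v > thr
        expect_equal(pr$tp[i], sum(keep & truth))
        expect_equal(pr$fp[i], sum(keep & !truth))
        expect_equal(pr$fn[i], sum(!keep & truth))
        expect_equal(pr$precision[i], pr$tp[i] / (pr$tp[i] + pr$fp[i]))
        expect_equal(pr$recall[i], pr$tp[i] / 3)
    }
    # recall is non-increasing with the threshold percentile
    expect_true(all(diff(pr$recall) <= 0))
})

test_that("AUPR is 1 for a perfect ranking and prevalence for random", {
    net <- buildNetwork(seed = 34)
    truth <- trueAdjacency(net)
    v <- matrix(NA_real_, 100, 100)
    off <- !diag(TRUE, 100)
    set.seed(34)
    v[off] <- runif(sum(off))
    v[truth] <- v[truth] + 1          # perfectly separable
    expect_equal(auprScore(prCurve(fakeStaticFC(v), net)), 1,
                 tolerance = 0.01)
    v2 <- matrix(NA_real_, 100, 100)
    v2[off] <- runif(sum(off))        # uninformative scores
    expect_equal(auprScore(prCurve(fakeStaticFC(v2), net)), 0.1,
                 tolerance = 0.02)
})

test_that("sign classification follows the XCov = 0 boundary", {
    v <- matrix(NA_real_, 2, 2)
    v[1, 2] <- 0.03; v[2, 1] <- -0.02
    lab <- classifySynapseSign(fakeStaticFC(v))
    expect_equal(lab[1, 2], "excitatory")
    expect_equal(lab[2, 1], "inhibitory")
    expect_error(classifySynapseSign(fakeStaticFC(v, measure = "te",
                                                  signed = FALSE)),
                 "positively defined")
})

test_that("delay metrics are exact on identical delays and error on few TPs", {
    net <- buildNetwork(seed = 35)
    truth <- trueAdjacency(net)
    e <- edges(net)
    v <- matrix(NA_real_, 100, 100)
    v[!diag(TRUE, 100)] <- runif(9900, 0, 0.1)
    v[truth] <- 1 + runif(sum(truth))   # distinct scores above the rest
    dh <- matrix(NA_integer_, 100, 100)
    dh[cbind(e$pre, e$post)] <- e$delay
    dh[is.na(dh) & !diag(TRUE, 100)] <- 1L
    dm <- delayMetrics(fakeStaticFC(v, delayHat = dh), net, 90)
    expect_equal(dm$correlation, 1)
    expect_equal(dm$maeMs, 0)
    v0 <- matrix(NA_real_, 100, 100)   # nothing separates -> few TPs
    v0[!diag(TRUE, 100)] <- 0.5
    expect_error(delayMetrics(fakeStaticFC(v0, delayHat = dh), net, 90),
                 "true-positive")
})

test_that("subgroup fractions sum to one and ground truth has no I-I", {
    net <- buildNetwork(seed = 36)
    fr <- subgroupFractions(trueAdjacency(net), isExcitatory(net))
    expect_equal(sum(fr), 1)
    expect_equal(unname(fr["II"]), 0)
    expect_gt(fr["EE"], fr["IE"])
    expect_error(subgroupFractions(matrix(FALSE, 3, 3), rep(TRUE, 3)),
                 "no retained")
})

test_that("static FC agrees with the single-pair functions", {
    set.seed(37)
    m <- matrix(rbinom(4 * 3000, 1, 0.12), 4)
    ras <- rasterFromMatrix(m)
    for (ms in c("xcov", "xcorr")) {
        fc <- staticFC(ras, ms, delays = 1:6)
        fun <- if (ms == "xcov") xcovPair else xcorrPair
        for (i in 1:4) for (j in 1:4) {
            if (i == j) next
            prof <- vapply(1:6, function(d) fun(m[i, ], m[j, ], d),
                           numeric(1))
            best <- which.max(abs(prof))
            expect_equal(fcValues(fc)[i, j], prof[best], tolerance = 1e-12)
            expect_equal(delayEstimates(fc)[i, j], best)
        }
    }
    fc <- staticFC(ras, "hote", delays = 1:4, k = 2, l = 2)
    for (i in 1:3) {
        prof <- vapply(1:4, function(d)
            higherOrderTEPair(m[i, ], m[i + 1, ], d, 2, 2), numeric(1))
        expect_equal(fcValues(fc)[i, i + 1], max(prof), tolerance = 1e-12)
    }
})
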