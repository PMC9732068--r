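test_that("cross-correlation reproduces Bernoulli closed forms", {
    set.seed(11)
    T <- 2e5
    # independent trains: XCorr converges to pq / sqrt(p(1-p)q(1-q)),
    # positive despite independence (the rate-sensitivity defect)
    x <- rbinom(T, 1, 0.1); y <- rbinom(T, 1, 0.1)
    expect_equal(xcorrPair(x, y, 3), 0.1 * 0.1 / 0.09, tolerance = 0.05)
    expect_equal(xcovPair(x, y, 3), 0, tolerance = 0.02)
    # self train at zero lag: E[i^2]/sigma^2 = 1 / (1 - p)
    z <- rbinom(T, 1, 0.5)
    expect_equal(xcorrPair(z, z, 0), 1 / (1 - mean(z)), tolerance = 1e-9)
    # zero-variance train gives the undefined sentinel
    expect_true(is.na(xcorrPair(integer(50), rbinom(50, 1, 0.5), 2)))
    expect_true(is.na(xcovPair(rep(1, 50), rbinom(50, 1, 0.5), 2)))
})

test_that("cross-covariance equals a two-pass oracle and detects lagged copies", {
    x <- c(1, 0, 1, 0, 0, 1, 0, 1, 0)
    y <- c(0, 1, 0, 1, 0, 0, 1, 0, 1)
    expect_equal(xcovPair(x, y, 1), bruteXCov(x, y, 1), tolerance = 1e-12)
    expect_equal(xcorrPair(x, y, 1), bruteXCorr(x, y, 1), tolerance = 1e-12)
    set.seed(12)
    for (d in c(1, 4, 9)) {
        a <- rbinom(5000, 1, 0.15)
        b <- c(integer(d), a[1:(5000 - d)])
        expect_equal(xcovPair(a, b, d), 1)
    }
    # random small cases against the oracle
    for (i in 1:20) {
        a <- rbinom(60, 1, 0.3); b <- rbinom(60, 1, 0.3); d <- sample(1:5, 1)
        expect_equal(xcovPair(a, b, d), bruteXCov(a, b, d),
                     tolerance = 1e-12)
    }
})

test_that("transfer entropy equals the exhaustive-count oracle", {
    # every sender/receiver pattern of length 5 at delay 1
    pats <- expand.grid(replicate(5, 0:1, simplify = FALSE))
    for (ix in seq_len(32)) {
        x <- as.numeric(pats[ix, ])
        for (iy in c(1, 7, 13, 22, 32)) {
            y <- as.numeric(pats[iy, ])
            expect_equal(transferEntropyPair(x, y, 1), bruteTE(x, y, 1),
                         tolerance = 1e-12)
        }
    }
    # random rasters up to length 14, delays 1-4
    set.seed(13)
    for (i in 1:60) {
        T <- sample(8:14, 1); d <- sample(1:4, 1)
        x <- rbinom(T, 1, 0.4); y <- rbinom(T, 1, 0.4)
        expect_equal(transferEntropyPair(x, y, d), bruteTE(x, y, d),
                     tolerance = 1e-12)
    }
})

test_that("higher-order TE generalizes TE and matches its oracle", {
    set.seed(14)
    for (i in 1:25) {
        x <- rbinom(30, 1, 0.4); y <- rbinom(30, 1, 0.4)
        d <- sample(1:3, 1)
        expect_equal(higherOrderTEPair(x, y, d, k = 1, l = 1),
                     transferEntropyPair(x, y, d), tolerance = 1e-14)
        expect_equal(higherOrderTEPair(x, y, d, k = 2, l = 2),
                     bruteTE(x, y, d, k = 2, l = 2), tolerance = 1e-12)
    }
    expect_error(higherOrderTEPair(rbinom(30, 1, .5), rbinom(30, 1, .5),
                                   1, k = 0, l = 2), "word lengths")
})

test_that("a noiseless delayed-copy channel carries one bit", {
    set.seed(15)
    T <- 5e4
    x <- rbinom(T, 1, 0.5)
    y <- c(integer(7), x[1:(T - 7)])
    expect_equal(transferEntropyPair(x, y, 7), 1, tolerance = 0.01)
    expect_equal(higherOrderTEPair(x, y, 7, 5, 5), 1, tolerance = 0.02)
    # independent trains: plug-in TE is a small positive bias only
    z <- rbinom(T, 1, 0.5)
    expect_lt(transferEntropyPair(x, z, 7), 0.001)
})

test_that("TE and HOTE are non-negative on arbitrary inputs", {
    set.seed(16)
    for (i in 1:40) {
        T <- sample(20:60, 1)
        x <- rbinom(T, 1, runif(1, 0.1, 0.9))
        y <- rbinom(T, 1, runif(1, 0.1, 0.9))
        d <- sample(1:3, 1)
        expect_gte(transferEntropyPair(x, y, d), 0)
        expect_gte(higherOrderTEPair(x, y, d, 3, 2), 0)
    }
})

test_that("measures are directional and zero-padding leaves XCov stable", {
    set.seed(17)
    x <- rbinom(3000, 1, 0.2)
    y <- c(0L, x[1:2999])                     # y follows x
    expect_gt(xcovPair(x, y, 1), 0.9)
    expect_lt(xcovPair(y, x, 1), 0.5)         # reverse direction is weak
    pad <- integer(100)
    expect_equal(xcovPair(c(pad, x), c(pad, y), 1), xcovPair(x, y, 1),
                 tolerance = 0.05)
})

test_that("overlap index combines ranks as prescribed", {
    set.seed(18)
    v <- matrix(runif(25), 5)
    fc1 <- fakeStaticFC(v)
    # identical rankings reproduce the ranking
    o <- overlapIndex(fc1, fakeStaticFC(v))
    off <- !diag(TRUE, 5)
    expect_equal(rank(fcValues(o)[off]), rank(abs(v[off])))
    # exactly reversed rankings make every pair (n+1)/2
    n <- sum(off)
    rev <- matrix(0, 5, 5)
    rev[off] <- max(abs(v[off])) + 1 - abs(v[off])
    o2 <- overlapIndex(fc1, fakeStaticFC(rev))
    expect_true(all(fcValues(o2)[off] == (n + 1) / 2))
    # rank arithmetic: a pair ranked 3 by one and 5 by the other gets 4
    s1 <- matrix(0, 3, 3); s2 <- matrix(0, 3, 3)
    s1[!diag(TRUE, 3)] <- c(1, 2, 3, 4, 5, 6) / 10
    s2[!diag(TRUE, 3)] <- c(1, 2, 5, 4, 3, 6) / 10
    oo <- overlapIndex(fakeStaticFC(s1), fakeStaticFC(s2))
    expect_equal(fcValues(oo)[!diag(TRUE, 3)][3], 4)
    expect_error(overlapIndex(fc1, fakeStaticFC(matrix(runif(16), 4))),
                 "different pair sets")
})
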