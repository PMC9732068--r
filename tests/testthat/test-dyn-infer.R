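test_that("DFC pair selection keeps the top share and filters by type", {
    set.seed(41)
    net <- buildNetwork(seed = 41)
    v <- matrix(NA_real_, 100, 100)
    v[!diag(TRUE, 100)] <- runif(9900, -1, 1)
    fc <- fakeStaticFC(v)
    prsSign <- selectDFCPairs(fc, mode = "sign")
    expect_lte(nrow(prsSign), round(0.05 * 9900))
    expect_true(all(fcValues(fc)[cbind(prsSign$pre, prsSign$post)] > 0))
    expect_identical(attr(prsSign, "mode"), "sign")
    prsTruth <- selectDFCPairs(fc, network = net, mode = "truth")
    truth <- trueAdjacency(net)
    exc <- isExcitatory(net)
    ok <- truth[cbind(prsTruth$pre, prsTruth$post)] & exc[prsTruth$pre]
    expect_true(all(ok))
    # unsigned measures need a sign companion in sign mode
    expect_error(selectDFCPairs(fakeStaticFC(abs(v), measure = "te",
                                             signed = FALSE),
                                mode = "sign"), "signFC")
})

test_that("window grids are laid out as floor(duration / T)", {
    set.seed(42)
    m <- matrix(rbinom(2 * 3 * 60000, 1, 0.01), 2)     # 3 minutes
    ras <- rasterFromMatrix(m)
    prs <- data.frame(pre = 1L, post = 2L, delayHat = 3L)
    dfc <- dfcSliding(ras, prs, windowMin = 0.5, measure = "xcov")
    expect_equal(ncol(fcValues(dfc)), 6L)
    expect_equal(nrow(fcValues(dfc)), 1L)
    # trailing remainder is discarded
    dfc2 <- dfcSliding(ras, prs, windowMin = 1.4, measure = "xcov")
    expect_equal(ncol(fcValues(dfc2)), 2L)
})

test_that("stationary coupling gives stable windowed values", {
    set.seed(43)
    T <- 6 * 60000
    a <- rbinom(T, 1, 0.05)
    noise <- rbinom(T, 1, 0.01)
    b <- pmin(1, c(integer(4), a[1:(T - 4)]) + noise)
    ras <- rasterFromMatrix(rbind(a, b))
    prs <- data.frame(pre = 1L, post = 2L, delayHat = 4L)
    dfc <- dfcSliding(ras, prs, windowMin = 1, measure = "xcov")
    whole <- xcovPair(a, b, 4)
    expect_lt(max(abs(fcValues(dfc) - whole)), 0.05)
})

test_that("windowed DSC averages exactly", {
    ed <- data.frame(pre = 1L, post = 2L)
    const <- new("WeightTrajectory", values = matrix(4.2, 1, 10800),
                 edges = ed)
    d1 <- dscWindowed(const, 30)
    expect_equal(ncol(fcValues(d1)), 6L)
    expect_true(all(fcValues(d1) == 4.2))
    # linear ramp: window means are the ramp at window centers
    ramp <- new("WeightTrajectory",
                values = matrix(seq(0, 10, length.out = 1200), 1),
                edges = ed)
    d2 <- dscWindowed(ramp, 1)
    centers <- (seq_len(20) - 0.5) * 60 + 0.5
    expected <- (centers - 1) / 1199 * 10
    expect_equal(as.numeric(fcValues(d2)), expected, tolerance = 1e-10)
})

test_that("DFC-DSC correlation is exactly 1 under affine relations", {
    ed <- data.frame(pre = c(1L, 2L), post = c(2L, 3L))
    set.seed(44)
    base <- matrix(runif(2 * 12), 2)
    dsc <- new("DSCSeries", values = base, edges = ed, windowMin = 1)
    dfc <- new("DFCSeries", values = 0.3 * base - 2,
               pairs = data.frame(pre = c(1L, 2L), post = c(2L, 3L),
                                  delayHat = 1L),
               windowMin = 1, measure = "xcov", delayConsistent = TRUE)
    cr <- dfcDscCorrelation(dfc, dsc, matchToMin = 1)
    expect_equal(cr$perPair$correlation, c(1, 1))
    expect_equal(cr$meanCorrelation, 1)
    expect_equal(cr$nFalsePositive, 0)
})

test_that("sample counts are matched across window widths", {
    ed <- data.frame(pre = 1L, post = 2L)
    set.seed(45)
    mk <- function(nwin, Tw) list(
        dsc = new("DSCSeries", values = matrix(runif(nwin), 1), edges = ed,
                  windowMin = Tw),
        dfc = new("DFCSeries", values = matrix(runif(nwin), 1),
                  pairs = data.frame(pre = 1L, post = 2L, delayHat = 1L),
                  windowMin = Tw, measure = "xcov",
                  delayConsistent = TRUE))
    # 180 min at T = 10 -> 18 windows subsampled to 6; at T = 30 -> all 6
    a <- mk(18, 10)
    cr <- dfcDscCorrelation(a$dfc, a$dsc, matchToMin = 30)
    expect_length(cr$sampleIndices, 6L)
    b <- mk(6, 30)
    cr2 <- dfcDscCorrelation(b$dfc, b$dsc, matchToMin = 30)
    expect_identical(cr2$sampleIndices, 1:6)
    # too few matched samples is an error
    cshort <- mk(4, 10)
    expect_error(dfcDscCorrelation(cshort$dfc, cshort$dsc,
                                   matchToMin = 30), "fewer than 3")
})

test_that("false-positive pairs are excluded but counted", {
    ed <- data.frame(pre = 1L, post = 2L)
    set.seed(46)
    dsc <- new("DSCSeries", values = matrix(runif(6), 1), edges = ed,
               windowMin = 30)
    dfc <- new("DFCSeries", values = matrix(runif(12), 2),
               pairs = data.frame(pre = c(1L, 3L), post = c(2L, 4L),
                                  delayHat = 1L),
               windowMin = 30, measure = "xcov", delayConsistent = TRUE)
    cr <- dfcDscCorrelation(dfc, dsc, matchToMin = 30)
    expect_equal(cr$nFalsePositive, 1L)
    expect_equal(nrow(cr$perPair), 1L)
})

test_that("a doubling of coupling strength shows up in windowed XCov", {
    set.seed(47)
    T <- 8 * 60000
    half <- T / 2
    a <- rbinom(T, 1, 0.05)
    copyProb <- c(rep(0.3, half), rep(0.8, half))
    b <- ifelse(runif(T) < copyProb, c(integer(3), a[1:(T - 3)]),
                rbinom(T, 1, 0.02))
    ras <- rasterFromMatrix(rbind(a, b))
    prs <- data.frame(pre = 1L, post = 2L, delayHat = 3L)
    dfc <- dfcSliding(ras, prs, windowMin = 1, measure = "xcov")
    v <- as.numeric(fcValues(dfc))
    expect_gt(mean(v[5:8]), mean(v[1:4]))
})
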