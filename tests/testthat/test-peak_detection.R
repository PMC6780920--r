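test_that("EIC extraction reproduces a synthetic Gaussian and its m/z jitter", {
    rts <- seq(1, 1.4, by = 0.01)
    tr <- gaussTrace(250.1, rts, 1.2, 0.05, 2e4)
    ch <- channelFromTraces(list(tr), rts)
    eic <- extractEic(ch, 250.1)
    expect_equal(eicPoints(eic)$intensity, tr$y)
    expect_true(all(abs(eicPoints(eic)$ppm) <= 5, na.rm = TRUE))
})

test_that("an absent target yields an all-zero EIC and no peaks", {
    rts <- seq(1, 1.2, by = 0.01)
    ch <- channelFromTraces(list(gaussTrace(250.1, rts, 1.1, 0.03, 1e4)),
                            rts)
    eic <- extractEic(ch, 400.2)
    expect_true(all(eicPoints(eic)$intensity == 0))
    expect_length(detectPeaks(eic), 0L)
})

test_that("the more intense of two in-window centroids is selected", {
    rts <- c(1, 1.01, 1.02)
    peaks <- lapply(1:3, function(i)
        cbind(mz = c(200.0002, 200.0006), intensity = c(100, 300)))
    h <- data.frame(scanId = 1:3, rt = rts, msLevel = 1L, energy = "0",
                    polarity = "positive")
    ch <- new("ScanChannel", header = h, peaks = peaks, energy = "0",
              msLevel = 1L, polarity = "positive")
    eic <- extractEic(ch, 200.0004, ppmTol = 5, mzWindow = 0.005)
    expect_equal(eicPoints(eic)$intensity, rep(300, 3))
    expect_equal(eicPoints(eic)$mz, rep(200.0006, 3))
})

test_that("the absolute m/z window caps the ppm window above m/z 1000", {
    ## at m/z 1200, 5 ppm = 0.006 Da > the 0.005 Da cap
    rts <- c(1, 1.01, 1.02)
    peaks <- lapply(1:3, function(i)
        cbind(mz = 1200.0055, intensity = 100))
    h <- data.frame(scanId = 1:3, rt = rts, msLevel = 1L, energy = "0",
                    polarity = "positive")
    ch <- new("ScanChannel", header = h, peaks = peaks, energy = "0",
              msLevel = 1L, polarity = "positive")
    expect_true(all(eicPoints(extractEic(ch, 1200))$intensity == 0))
    expect_true(all(eicPoints(extractEic(ch, 1200, mzWindow = 0.01))
                    $intensity > 0))
})

test_that("one clean Gaussian gives one peak with apex at the sampled max", {
    rts <- seq(1, 1.4, by = 0.01)
    y <- 5e3 * exp(-((rts - 1.18)^2) / (2 * 0.04^2))
    pk <- peakFromProfile(y, rts = rts)
    expect_equal(rtApex(pk), rts[which.max(y)])
    expect_equal(apexIntensity(pk), max(y))
    expect_gt(peakArea(pk), 0)
})

test_that("two Gaussians with a deep valley are split into two peaks", {
    rts <- seq(1, 1.6, by = 0.01)
    y <- 1e4 * exp(-((rts - 1.15)^2) / (2 * 0.03^2)) +
         8e3 * exp(-((rts - 1.45)^2) / (2 * 0.03^2))
    ch <- channelFromTraces(list(list(mz = 300, y = y)), rts)
    pks <- detectPeaks(extractEic(ch, 300), minIntensity = 1)
    expect_length(pks, 2L)
    expect_equal(rtApex(pks[[1]]), 1.15, tolerance = 0.011)
    expect_equal(rtApex(pks[[2]]), 1.45, tolerance = 0.011)
    ## spans are disjoint and ordered
    s1 <- eicPoints(pks[[1]])$scanId; s2 <- eicPoints(pks[[2]])$scanId
    expect_lt(max(s1), min(s2))
})

test_that("a shallow valley does not split; the valley fraction governs", {
    ## interior minimum at 60% of the smaller flanking apex
    y <- c(2, 20, 100, 60, 90, 30, 4) * 100
    rts <- as.numeric(seq_along(y))
    ch <- channelFromTraces(list(list(mz = 300, y = y)), rts)
    expect_length(detectPeaks(extractEic(ch, 300), minIntensity = 1), 1L)
    expect_length(detectPeaks(extractEic(ch, 300), minIntensity = 1,
                              valleyFraction = 0.8), 2L)
})

test_that("asymmetry factor: symmetric 1, hand example 1.5, degenerate 0", {
    rts <- as.numeric(0:20)   # uniform grid where RT differences are exact
    y <- 1e3 * exp(-((rts - 10)^2) / (2 * 9))  # symmetric, apex central
    expect_identical(asymmetryFactor(peakFromProfile(y, rts = rts)), 1)
    expect_equal(asymmetryFactor(1.0, 1.2, 1.5), 1.5)
    ## apex at the first scan -> 0
    ch <- channelFromTraces(list(list(mz = 100,
                                      y = c(100, 80, 60, 40, 20))),
                            seq(1, 1.04, by = 0.01))
    pk <- detectPeaks(extractEic(ch, 100))[[1]]
    expect_identical(asymmetryFactor(pk), 0)
    ## fewer than 3 scans -> 0
    ch2 <- channelFromTraces(list(list(mz = 100, y = c(0, 10, 20, 0, 0))),
                             seq(1, 1.04, by = 0.01))
    pk2 <- detectPeaks(extractEic(ch2, 100), minScans = 2L)[[1]]
    expect_identical(asymmetryFactor(pk2), 0)
})

test_that("mirror-symmetric sampling gives f = 1 exactly on a uniform grid", {
    for (half in list(c(1, 4, 9), c(2, 7, 20, 48), c(5, 30))) {
        y <- c(half, 100, rev(half))
        pk <- peakFromProfile(y, rts = as.numeric(seq_along(y)))
        expect_identical(asymmetryFactor(pk), 1)
    }
})

test_that("detected spans only cover above-threshold points", {
    set.seed(5)
    rts <- seq(1, 2, by = 0.01)
    y <- 2e3 * exp(-((rts - 1.3)^2) / (2 * 0.03^2)) +
         1.5e3 * exp(-((rts - 1.7)^2) / (2 * 0.04^2)) +
         runif(length(rts), 0, 40)
    ch <- channelFromTraces(list(list(mz = 500, y = y)), rts)
    pks <- detectPeaks(extractEic(ch, 500), minIntensity = 100)
    for (pk in pks)
        expect_true(all(eicPoints(pk)$intensity > 100))
    starts <- vapply(pks, function(p) eicPoints(p)$scanId[1], 0)
    expect_false(is.unsorted(starts, strictly = TRUE))
})

test_that("smoothing passes small peaks through and denoises larger ones", {
    pk3 <- peakFromProfile(c(10, 50, 20))
    sm3 <- smoothPeak(pk3)
    expect_identical(sm3@smoothMethod, "none")
    expect_equal(sm3@smoothed, eicPoints(pk3)$intensity)

    rts <- seq(1, 1.5, by = 0.01)
    clean <- 1e4 * exp(-((rts - 1.22)^2) / (2 * 0.06^2))
    smc <- smoothPeak(peakFromProfile(clean, rts = rts))
    expect_lt(abs(rts[which.max(smc@smoothed)] - 1.22), 0.011)

    ## 5% multiplicative noise: smoothing must reduce RMS error vs truth
    set.seed(19)
    wins <- 0L
    for (rep in 1:20) {
        noisy <- clean * (1 + rnorm(length(clean), 0, 0.05))
        pk <- peakFromProfile(pmax(noisy, 1), rts = rts)
        sm <- smoothPeak(pk)
        span <- match(eicPoints(pk)$rt, rts)
        rmsNoisy <- sqrt(mean((eicPoints(pk)$intensity - clean[span])^2))
        rmsSmooth <- sqrt(mean((sm@smoothed - clean[span])^2))
        wins <- wins + (rmsSmooth < rmsNoisy)
    }
    expect_gte(wins, 18L)
})

test_that("cubic interpolating spline is exact at the knots", {
    rts <- seq(1, 1.3, by = 0.01)
    y <- 1e3 * exp(-((rts - 1.15)^2) / (2 * 0.05^2))
    pk <- peakFromProfile(y, rts = rts)
    sm <- smoothPeak(pk, method = "cubic-spline")
    expect_equal(sm@smoothed, eicPoints(pk)$intensity, tolerance = 1e-9)
})
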