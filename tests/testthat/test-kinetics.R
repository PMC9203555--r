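test_that("two-state unfolded fraction follows the Boltzmann closed form", {
    ## zero free-energy gap forces equal occupancy
    expect_equal(fractionUnfolded(55, 55, 0.25), 0.5)
    expect_equal(fractionUnfolded(123, 7, 0), 0.5)
    ## direct hand evaluation of the stated closed form
    expected <- 1 / (1 + exp(0.25 * (55 - 37) / (1.987e-3 * 310.15)))
    expect_equal(fractionUnfolded(55, 37, 0.25), expected,
        tolerance = 1e-14)
    ## strictly decreasing in Tm, bounded in (0, 1)
    fu <- fractionUnfolded(seq(-5, 70, by = 2.5), 37, 0.25)
    expect_true(all(diff(fu) < 0))
    expect_true(all(fu > 0 & fu < 1))
    expect_error(fractionUnfolded(NaN, 37, 0.25), "finite")
    expect_error(fractionUnfolded(55, -300, 0.25), "absolute zero")
    expect_error(fractionUnfolded(55, 37, -0.1), ">= 0")
})

test_that("fluorophore maturation is first order with exact half-time", {
    expect_equal(maturationFraction(0, 42), 0)
    expect_equal(maturationFraction(42, 42), 0.5)
    expect_equal(maturationFraction(84, 42), 0.75)
    mf <- maturationFraction(seq(0, 500, by = 5), 14)
    expect_true(all(diff(mf) > 0))
    expect_lt(1 - maturationFraction(1e5, 14), 1e-12)
    expect_error(maturationFraction(-1, 42), ">= 0")
    expect_error(maturationFraction(10, 0), "> 0")
})

test_that("cell trajectories degenerate correctly in limiting regimes", {
    tt <- c(0, 30, 60, 120, 240)
    ## no synthesis, no leak: identically zero protein pools
    p0 <- kineticParams(kSyn = 0, leakFraction = 0)
    tr <- simulateCell(55, p0, times = tt)
    expect_true(all(as.matrix(tr[, -1]) == 0))
    ## pure accumulation: no losses, total client pool is kSyn * c * t
    pAcc <- decayOnlyParams(kSyn = 1)
    g0 <- growthModel(0.5, 0, Inf)
    tr <- simulateCell(55, pAcc, times = tt, growth = g0,
        copyNumber = 3, init = c(poi_mature = 0))
    total <- tr$poi_immature + tr$poi_mature
    expect_equal(total, 3 * tt, tolerance = 1e-8)
    ## dilution conservation: all rates zero, constant mu -> exp(-mu t)
    gExp <- growthModel(0.5, 0.01, Inf)
    tr <- simulateCell(55, decayOnlyParams(), times = tt, growth = gExp,
        init = c(poi_mature = 1000, gfp_mature = 500))
    expect_equal(tr$poi_mature, 1000 * exp(-0.01 * tt),
        tolerance = 1e-8)
    expect_equal(tr$gfp_mature, 500 * exp(-0.01 * tt),
        tolerance = 1e-8)
})

test_that("maturation of a synthesis-stopped pool follows 1 - 2^(-t/t50)", {
    tt <- c(0, 10.5, 21, 42, 84, 168)
    tr <- simulateCell(55, decayOnlyParams(), times = tt,
        growth = growthModel(0.5, 0, Inf), init = c(poi_immature = 1))
    frac <- tr$poi_mature / (tr$poi_immature + tr$poi_mature)
    expect_equal(frac, 1 - 2^(-tt / 42), tolerance = 1e-9)
})

test_that("numerical ODE solution matches the matrix-exponential closed form", {
    skip_if_not_installed("Matrix")
    tt <- samplingSchedule()
    set.seed(101)
    for (i in 1:3) {
        p <- kineticParams(
            kSyn = runif(1, 0.5, 2), kDegBasal = runif(1, 0, 0.005),
            kDegUnfolded = runif(1, 0, 0.05),
            kAgg = runif(1, 0, 0.01),
            alphaTranslation = runif(1, 0.05, 0.3),
            betaUnfolded = runif(1, 0, 0.01),
            t50RedMin = runif(1, 20, 60),
            t50GreenMin = runif(1, 5, 30))
        tm <- runif(1, 5, 65)
        mu <- runif(1, 0, 0.02)
        sim <- simulateCell(tm, p, times = tt,
            growth = growthModel(0.5, mu, Inf),
            init = c(poi_mature = 0))
        oracle <- closedFormCell(p, tm, mu, tt)
        relErr <- abs(as.matrix(sim[, -1]) - oracle) /
            pmax(abs(oracle), 1e-12)
        expect_lt(max(relErr), 1e-6)
    }
})

test_that("the toxicity switch shuts synthesis off permanently", {
    tt <- samplingSchedule()
    pTox <- noiselessParams(toxicityEnabled = TRUE,
        toxicityThreshold = 30)
    pRef <- noiselessParams()
    trTox <- simulateCell(55, pTox, times = tt)
    trRef <- simulateCell(55, pRef, times = tt)
    poolTox <- trTox$poi_immature + trTox$poi_mature
    poolRef <- trRef$poi_immature + trRef$poi_mature
    expect_true(all(poolTox <= poolRef + 1e-9))
    expect_lt(poolTox[length(tt)], poolRef[length(tt)] / 2)
    ## the pool never grows far beyond the threshold after the switch
    expect_lt(max(poolTox), 30 * 1.5)
})

test_that("logistic growth helpers are consistent", {
    g <- growthModel(0.5, 0.023, 2.5)
    expect_equal(logisticOd(g, 0), 0.5)
    expect_equal(specificGrowthRate(g, 0), 0.023 * (1 - 0.5 / 2.5))
    ## mu is the log-derivative of N (finite-difference cross-check)
    h <- 1e-4
    fd <- (log(logisticOd(g, 60 + h)) - log(logisticOd(g, 60 - h))) /
        (2 * h)
    expect_equal(specificGrowthRate(g, 60), fd, tolerance = 1e-6)
    ## infinite capacity degenerates to exponential growth
    gi <- growthModel(0.2, 0.01, Inf)
    expect_equal(logisticOd(gi, 100), 0.2 * exp(1))
    expect_equal(specificGrowthRate(gi, c(0, 100)), c(0.01, 0.01))
    expect_error(growthModel(1, 0.01, 0.5), "kCap > n0")
})
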