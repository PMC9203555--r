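test_that("noiseless logistic curves are recovered within 1 percent", {
    g <- growthModel(0.05, 0.02, 1.2)
    curve <- data.frame(time_min = samplingSchedule(),
        od600 = logisticOd(g, samplingSchedule()))
    f <- fitLogistic(curve, nDraws = 30, seed = 1)
    expect_lt(abs(f@n0 / 0.05 - 1), 0.01)
    expect_lt(abs(f@r / 0.02 - 1), 0.01)
    expect_lt(abs(f@kCap / 1.2 - 1), 0.01)
    ## degenerate residuals: bootstrap uncertainty collapses
    expect_lt(f@muMaxSd, 1e-6 * f@muMax)
    ## deterministic repeat
    f2 <- fitLogistic(curve, nDraws = 30, seed = 1)
    expect_identical(f@muMax, f2@muMax)
    expect_identical(f@posterior, f2@posterior)
})

test_that("exponential-regime fits recover the log-linear slope", {
    tt <- seq(0, 120, by = 10)
    od <- 0.05 * exp(0.015 * tt)    # far below any plausible capacity
    f <- fitLogistic(data.frame(time_min = tt, od600 = od),
        nDraws = 10, seed = 1)
    logSlope <- coef(lm(log(od) ~ tt))[[2]]
    expect_lt(abs(f@r / logSlope - 1), 0.02)
})

test_that("non-growing curves are rejected with a validation error", {
    tt <- samplingSchedule()
    expect_error(fitLogistic(data.frame(time_min = tt,
        od600 = rep(0.5, length(tt)))), "not increasing")
    expect_error(fitLogistic(data.frame(time_min = tt,
        od600 = 2 * exp(-0.01 * tt))), "not increasing")
    expect_error(fitLogistic(data.frame(time_min = c(0, 10, 20, 30),
        od600 = c(1, 2, 3, 4))), ">= 5")
    expect_error(fitLogistic(data.frame(time_min = c(0, 0, 10, 20, 30),
        od600 = 1:5)), "strictly increasing")
})

test_that("maximum specific growth rate approaches r for small n0/K", {
    ## fit object built from known parameters: isolates the mu(t)
    ## maximisation from the regression
    tt <- seq(0, 1200, by = 60)
    g <- growthModel(1e-3, 0.018, 10)
    f <- new("GrowthFit", n0 = 1e-3, r = 0.018, kCap = 10,
        posterior = matrix(rep(c(1e-3, 0.018, 10), each = 3), 3, 3,
            dimnames = list(NULL, c("n0", "r", "k_cap"))),
        muMax = NA_real_, muMaxSd = NA_real_, method = "bootstrap",
        seed = 1L,
        data = data.frame(time_min = tt, od600 = logisticOd(g, tt)))
    mm <- maxGrowthRate(f)
    ## mu(t) is maximal at t = 0 where N/K = 1e-4
    expect_equal(unname(mm["mu_max"]), 0.018 * (1 - 1e-4),
        tolerance = 1e-6)
    expect_equal(unname(mm["mu_max_sd"]), 0)
    ## absolute mode maximises dN/dt = r N (1 - N/K) = rK/4 at N = K/2
    ab <- maxGrowthRate(f, mode = "absolute")
    expect_equal(unname(ab["mu_max"]), 0.018 * 10 / 4,
        tolerance = 5e-3)
    expect_error(maxGrowthRate(new("GrowthFit", n0 = 1, r = 1,
        kCap = 2, posterior = matrix(numeric(), 0, 3),
        muMax = NA_real_, muMaxSd = NA_real_, method = "bootstrap",
        seed = 1L, data = data.frame(time_min = 0:5, od600 = 1:6))),
        "empty posterior")
})

test_that("dilution bias equals the window-averaged specific growth rate", {
    ## exponential regime: bias is exactly r for any window
    ge <- growthModel(0.1, 0.01, Inf)
    expect_equal(dilutionBias(ge, c(30, 60)), 0.01)
    expect_equal(dilutionBias(ge, c(150, 180)), 0.01)
    ## stationary phase: bias near zero
    gs <- growthModel(1.1999, 0.02, 1.2)
    expect_lt(dilutionBias(gs, c(30, 60)), 1e-4)
    ## independent quadrature oracle for the logistic
    g <- growthModel(0.05, 0.02, 1.2)
    quad <- integrate(function(t) specificGrowthRate(g, t), 30, 60,
        rel.tol = 1e-12)$value / 30
    expect_equal(dilutionBias(g, c(30, 60)), quad, tolerance = 1e-8)
    expect_error(dilutionBias(g, c(60, 60)), "window")
})

test_that("dilution spread follows the sample-sd convention", {
    fits <- list(growthModel(0.1, 0.01, Inf),
        growthModel(0.1, 0.02, Inf))
    sp <- dilutionSpread(fits, c(30, 60), referenceRate = 0.05)
    expect_equal(sp$mean_bias, 0.015)
    expect_equal(sp$sd_bias, sd(c(0.01, 0.02)))   # 0.007071 (n-1)
    expect_equal(sp$sd_percent_of_reference,
        100 * sd(c(0.01, 0.02)) / 0.05)
    expect_equal(dilutionSpread(list(fits[[1]], fits[[1]]),
        c(30, 60))$sd_bias, 0)
    expect_error(dilutionSpread(fits[1], c(30, 60)), ">= 2")
})

test_that("late dilution spread exceeds early when curves diverge late", {
    ## same early growth; one culture saturates after ~60 min
    fits <- list(growthModel(0.5, 0.02, 30),
        growthModel(0.5, 0.02, 1.2))
    early <- dilutionSpread(fits, c(30, 60))$sd_bias
    late <- dilutionSpread(fits, c(150, 180))$sd_bias
    expect_gte(late, early)
})

test_that("noisy growth curves are still recovered to ~10 percent", {
    g <- growthModel(0.05, 0.02, 1.2)
    tt <- samplingSchedule()
    set.seed(31)
    od <- logisticOd(g, tt) * exp(rnorm(length(tt), 0, 0.01))
    f <- fitLogistic(data.frame(time_min = tt, od600 = od),
        nDraws = 10, seed = 3)
    expect_lt(abs(f@r / 0.02 - 1), 0.1)
    expect_lt(abs(f@kCap / 1.2 - 1), 0.1)
})

test_that("generator growth curves feed the fitter end to end", {
    pop <- simulatePopulation("wt", 55, kineticParams(), nCells = 5,
        seed = 9)
    f <- fitLogistic(pop$growthCurve, nDraws = 20, seed = 1)
    expect_lt(abs(f@kCap / pop$growth$kCap - 1), 0.1)
    ## fitted dilution bias agrees with the generating model's
    expect_equal(dilutionBias(f, c(30, 60)),
        dilutionBias(pop$growth, c(30, 60)), tolerance = 0.05)
})

test_that("fluorescence relative rate equals minus the dilution bias when only dilution acts", {
    ## dilution-only cell carrying an initial mature pool, summarised
    ## through the standard gating/summary/rate chain
    g <- growthModel(0.5, 0.023, 2.5)
    tr <- simulateCell(55, decayOnlyParams(), times = samplingSchedule(),
        growth = g, init = c(poi_mature = 1000, gfp_mature = 800))
    samples <- lapply(seq_len(nrow(tr)), function(i)
        handSample(red = rep(tr$poi_mature[i], 3),
            green = rep(tr$gfp_mature[i], 3), time = tr$time_min[i]))
    summ <- summarizeSamples(samples, gateSpec(c(0, 2), c(0, 2)))
    rel <- fitRate(summ$time_min, summ$mean_red, c(30, 60))
    expect_lt(abs(relativeRate(rel) + dilutionBias(g, c(30, 60))) /
        dilutionBias(g, c(30, 60)), 0.02)
})
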