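test_that("log-log slope matches hand OLS and detects constant ratios", {
    ## constant ratio green = 3 * red: slope 1, intercept log10(3)
    s <- handSample(red = c(1, 10, 100, 1000),
        green = 3 * c(1, 10, 100, 1000))
    f <- logLogSlope(s)
    expect_equal(f@slope, 1)
    expect_equal(f@intercept, log10(3))
    ## constant green: slope 0
    s0 <- handSample(red = c(1, 10, 100), green = c(5, 5, 5))
    expect_equal(logLogSlope(s0)@slope, 0)
    ## 4 hand events: independent lm oracle on the log10 values
    s4 <- handSample(red = c(2, 5, 20, 80), green = c(3, 4, 30, 40))
    fit <- stats::lm(log10(green) ~ log10(red), flowEvents(s4))
    f4 <- logLogSlope(s4)
    expect_equal(f4@slope, unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(f4@intercept, unname(coef(fit)[1]), tolerance = 1e-12)
    expect_equal(f4@nEvents, 4L)
    expect_error(logLogSlope(handSample(red = 1:2, green = 1:2)),
        ">= 3")
})

test_that("slope one with zero residuals is equivalent to constant ratio", {
    set.seed(8)
    red <- rlnorm(100, 5, 1)
    s <- handSample(red = red, green = 2.5 * red)
    f <- logLogSlope(s)
    expect_equal(f@slope, 1, tolerance = 1e-12)
    resid <- log10(2.5 * red) - (f@intercept + f@slope * log10(red))
    expect_lt(var(resid), 1e-24)
})

test_that("sparsity prior prunes a single Gaussian to one component", {
    set.seed(1)
    X <- matrix(rnorm(4000), ncol = 2)
    f <- fitMixture(X, seed = 1)
    expect_equal(effectiveComponents(f), 1)
    expect_gt(max(mixtureWeights(f)), 0.99)
    expect_true(all(diff(f@elboTrace) > -1e-8 * max(1, abs(f@elbo))))
})

test_that("two well-separated components are recovered with correct weights", {
    set.seed(2)
    X <- rbind(matrix(rnorm(2000), ncol = 2),
               matrix(rnorm(2000, mean = 8), ncol = 2))
    f <- fitMixture(X, seed = 2)
    expect_equal(effectiveComponents(f), 2)
    top <- order(mixtureWeights(f), decreasing = TRUE)[1:2]
    expect_true(all(abs(mixtureWeights(f)[top] - 0.5) <= 0.05))
    mns <- f@means[top, ][order(f@means[top, 1]), ]
    expect_true(all(abs(mns[1, ] - 0) <= 0.5))
    expect_true(all(abs(mns[2, ] - 8) <= 0.5))
})

test_that("mixture fits are deterministic under a fixed seed", {
    set.seed(3)
    X <- rbind(matrix(rnorm(600), ncol = 2),
               matrix(rnorm(600, mean = 5), ncol = 2))
    a <- fitMixture(X, seed = 11)
    b <- fitMixture(X, seed = 11)
    expect_identical(a@weights, b@weights)
    expect_identical(a@means, b@means)
    expect_identical(a@elboTrace, b@elboTrace)
    expect_error(fitMixture(X[1:5, ]), "n > nComponentsMax")
    expect_error(fitMixture(matrix(c(1, NA, 3, 4, 5, 6, 7, 8,
        9, 10, 11, 12, 13, 14, 15, 16), ncol = 2)), "non-finite")
})

test_that("effective components count weights above the floor", {
    expect_equal(effectiveComponents(
        mixtureFitWithWeights(c(0.991, 0.009))), 1)
    expect_equal(effectiveComponents(
        mixtureFitWithWeights(rep(1 / 7, 7))), 7)
    expect_equal(effectiveComponents(
        mixtureFitWithWeights(c(0.6, 0.3, 0.05, 0.05, 1e-9, 1e-9,
            1e-9)), weightFloor = 0.04), 4)
})

test_that("component relabelling leaves report content unchanged", {
    set.seed(4)
    X <- rbind(matrix(rnorm(1000), ncol = 2),
               matrix(rnorm(1000, mean = 8), ncol = 2))
    f <- fitMixture(X, seed = 4)
    perm <- sample(length(f@weights))
    g <- f
    g@weights <- f@weights[perm]
    g@means <- f@means[perm, , drop = FALSE]
    g@variances <- f@variances[perm, , drop = FALSE]
    g@responsibilities <- f@responsibilities[, perm, drop = FALSE]
    expect_equal(effectiveComponents(g), effectiveComponents(f))
    rf <- subpopulationReport(list(f), 0)
    rg <- subpopulationReport(list(g), 0)
    expect_equal(sort(rf$weight), sort(rg$weight))
    expect_equal(sort(rf$mean_red), sort(rg$mean_red))
    expect_equal(rf$n_effective, rg$n_effective)
})

test_that("subpopulation report flags late low-abundance components", {
    ## single population at induction: no flags
    set.seed(5)
    X <- matrix(rnorm(2000, mean = 2, sd = 0.1), ncol = 2)
    f0 <- fitMixture(X, seed = 5)
    r0 <- subpopulationReport(list(f0), 0)
    expect_true(all(!r0$low_red))
    ## toxicity switch on: a low-red subpopulation emerges late
    p <- kineticParams(toxicityEnabled = TRUE, toxicityThreshold = 1200)
    pop <- simulatePopulation("wt", 55, p, nCells = 600, seed = 3)
    sel <- pop$samples[c(1, 21)]    # t = 0 and t = 240 min
    fits <- lapply(seq_along(sel), function(i)
        fitMixture(sel[[i]], seed = i, nRestarts = 3))
    rep <- subpopulationReport(fits, vapply(sel, sampleTime,
        numeric(1)))
    expect_true(any(rep$low_red[rep$time_min == 240]))
    expect_false(any(rep$low_red[rep$time_min == 0]))
    ## deterministic repeat
    fits2 <- lapply(seq_along(sel), function(i)
        fitMixture(sel[[i]], seed = i, nRestarts = 3))
    rep2 <- subpopulationReport(fits2, vapply(sel, sampleTime,
        numeric(1)))
    expect_identical(rep, rep2)
    expect_error(subpopulationReport(list(), numeric()), "empty")
})

test_that("hard assignments follow the dominant responsibility", {
    set.seed(6)
    X <- rbind(matrix(rnorm(400), ncol = 2),
               matrix(rnorm(400, mean = 8), ncol = 2))
    f <- fitMixture(X, seed = 6)
    cl <- assignClusters(f)
    expect_length(cl, nrow(X))
    ## the two halves land in different clusters
    expect_equal(length(unique(cl[1:200])), 1)
    expect_equal(length(unique(cl[201:400])), 1)
    expect_false(cl[1] == cl[400])
})
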