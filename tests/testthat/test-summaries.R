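test_that("singlet gating retains exactly the in-gate events", {
    s <- handSample(red = 1:5, green = 1:5,
        fsc = c(1, 5, 10, 50, 100), ssc = c(2, 2, 2, 2, 2))
    ## gate spanning the whole range: identity
    all <- gateSinglets(s, gateSpec(c(0, 1000), c(0, 1000)))
    expect_equal(flowEvents(all), flowEvents(s))
    ## hand-checked membership: fsc in [4, 60] keeps events 2, 3, 4
    g <- gateSinglets(s, gateSpec(c(4, 60), c(0, 10)))
    expect_equal(nEvents(g), 3)
    expect_equal(flowEvents(g)$red, c(2, 3, 4))
    ## excluding gate: zero events, with a warning
    expect_warning(none <- gateSinglets(s, gateSpec(c(500, 600),
        c(0, 10))), "removed all events")
    expect_equal(nEvents(none), 0)
    ## the input sample is never mutated
    expect_equal(nEvents(s), 5)
})

test_that("gating is idempotent", {
    set.seed(2)
    s <- handSample(red = runif(50, 1, 10), green = runif(50, 1, 10),
        fsc = rlnorm(50, 10, 0.3), ssc = rlnorm(50, 9, 0.3))
    g <- gateSpec(quantile(flowEvents(s)$fsc, c(0.1, 0.9)),
        quantile(flowEvents(s)$ssc, c(0.1, 0.9)))
    once <- gateSinglets(s, g)
    twice <- gateSinglets(once, g)
    expect_equal(flowEvents(twice), flowEvents(once))
})

test_that("summary means are plain arithmetic means of gated events", {
    wide <- gateSpec(c(0, 10), c(0, 10))
    one <- handSample(red = 2, green = 6)
    expect_equal(summarizeSamples(list(one), wide)$mean_red, 2)
    expect_equal(summarizeSamples(list(one), wide)$mean_green, 6)
    expect_equal(summarizeSamples(list(one), wide)$mean_ratio, 3)
    ## two events (1,2), (3,6): per-event ratios both 2
    two <- handSample(red = c(1, 3), green = c(2, 6))
    sm <- summarizeSamples(list(two), wide)
    expect_equal(sm$mean_red, 2)
    expect_equal(sm$mean_green, 4)
    expect_equal(sm$mean_ratio, 2)
    expect_equal(summarizeSamples(list(two), wide,
        ratioMethod = "ratio_of_means")$mean_ratio, 2)
    ## identical events: means equal the event values
    same <- handSample(red = c(5, 5, 5), green = c(10, 10, 10))
    sm <- summarizeSamples(list(same), wide)
    expect_equal(sm$mean_red, 5)
    expect_equal(sm$mean_ratio, 2)
    ## the two ratio conventions differ when ratios are heterogeneous
    mixed <- handSample(red = c(1, 10), green = c(10, 10))
    expect_equal(summarizeSamples(list(mixed), wide)$mean_ratio, 5.5)
    expect_equal(summarizeSamples(list(mixed), wide,
        ratioMethod = "ratio_of_means")$mean_ratio, 20 / 11)
    ## empty gated sample names the offender
    far <- gateSpec(c(500, 600), c(500, 600))
    expect_error(suppressWarnings(summarizeSamples(
        list(handSample(red = 1, green = 1, variant = "X",
            replicate = 2, time = 30)), far)),
        "X rep 2 at t = 30")
})

test_that("windowed rates reproduce hand OLS on small series", {
    r <- fitRate(c(0, 10, 20, 30), c(1, 2, 3, 4), c(0, 30))
    expect_equal(r@slope, 0.1)
    expect_equal(r@meanInWindow, 2.5)
    expect_equal(relativeRate(r), 0.04)
    ## constant series: zero slope and relative rate
    r0 <- fitRate(c(0, 10, 20, 30), rep(7, 4), c(0, 30))
    expect_equal(r0@slope, 0)
    expect_equal(relativeRate(r0), 0)
    ## hand normal equations for 1, 2, 2, 5:
    ## slope = sum((t-15)(v-2.5)) / sum((t-15)^2) = 60/500
    r2 <- fitRate(c(0, 10, 20, 30), c(1, 2, 2, 5), c(0, 30))
    expect_equal(r2@slope, 0.12)
    expect_equal(r2@meanInWindow, 2.5)
    expect_equal(relativeRate(r2), 0.048)
    ## only in-window points count
    r3 <- fitRate(c(0, 10, 20, 30, 40), c(1, 2, 3, 4, 100), c(0, 30))
    expect_equal(r3@slope, 0.1)
    expect_error(fitRate(c(0, 50), c(1, 2), c(5, 45)), ">= 2")
    expect_error(fitRate(c(0, 10), c(-1, 1), c(0, 10)), "zero")
})

test_that("rates are scale equivariant and relative rates scale free", {
    tt <- samplingSchedule()
    v <- 3 + 0.05 * tt + sin(tt / 30)
    base <- fitRate(tt, v, c(30, 90))
    scaled <- fitRate(tt, 10 * v, c(30, 90))
    expect_equal(scaled@slope, 10 * base@slope)
    expect_equal(scaled@meanInWindow, 10 * base@meanInWindow)
    expect_equal(relativeRate(scaled), relativeRate(base))
})

test_that("relative rate of an exponential approaches its rate constant", {
    tt <- samplingSchedule()
    f <- exp(0.01 * tt)
    r <- fitRate(tt, f, c(30, 40))
    expect_lt(abs(relativeRate(r) - 0.01) / 0.01, 0.05)
})

test_that("rate tables enumerate all combinations and flag absent windows", {
    ds <- simulatePanel(nCells = 20, seed = 2)
    summ <- summarizeSamples(ds)
    tab <- rateTable(summ, windows = list(c(0, 30), c(30, 60)),
        channels = "green")
    expect_equal(nrow(tab), 8 * 3 * 1 * 2)
    expect_true(all(tab$ok))
    ## a window with < 2 schedule points yields an explicit absent row
    tab2 <- rateTable(summ, windows = list(c(121, 149)),
        channels = "red")
    expect_equal(nrow(tab2), 24)
    expect_true(all(!tab2$ok))
    expect_true(all(is.na(tab2$relative_rate)))
    expect_error(rateTable(summ, channels = "magenta"), "unknown")
})
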