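## Shared fixtures; everything is generated in code at test time.

## Parameters with every stochastic element switched off: trajectories
## are then the pure ODE means.
noiselessParams <- function(...) {
    kineticParams(noiseCv = 0, copyNumberLogSd = 0,
        replicateEffectSd = 0, growthReplicateSd = 0, odNoiseCv = 0,
        ...)
}

## Parameters with all synthesis and losses off (dilution-only model).
decayOnlyParams <- function(...) {
    args <- utils::modifyList(list(kSyn = 0, leakFraction = 0,
        kDegBasal = 0, kDegUnfolded = 0, kAgg = 0,
        alphaTranslation = 0, betaUnfolded = 0), list(...))
    do.call(kineticParams, args)
}

## Tiny hand-writable sample.
handSample <- function(red, green, fsc = rep(1, length(red)),
        ssc = rep(1, length(red)), variant = "wt", replicate = 1,
        time = 0) {
    timepointSample(variant, replicate, time,
        data.frame(fsc = fsc, ssc = ssc, red = red, green = green))
}

## MixtureFit with prescribed weights and placeholder moments, for
## exercising weight-floor logic without a fit.
mixtureFitWithWeights <- function(w, means = NULL) {
    k <- length(w)
    if (is.null(means)) means <- cbind(seq_len(k), seq_len(k))
    new("MixtureFit", weights = w / sum(w), means = means,
        variances = matrix(1, k, 2),
        responsibilities = matrix(numeric(), 0, k),
        elbo = 0, elboTrace = 0, converged = TRUE, seed = 1L,
        nComponentsMax = as.integer(k),
        weightConcentrationPrior = 1e-6)
}

## Independent mid-rank Spearman oracle built only on base primitives
## different from the implementation path (stats::rank + stats::cor).
bruteSpearman <- function(x, y) {
    stats::cor(rank(x, ties.method = "average"),
        rank(y, ties.method = "average"))
}

## Matrix-exponential closed form for the linear reporter system at
## constant growth rate mu (the independent kinetic-model oracle).
closedFormCell <- function(params, tmCelsius, mu, times,
        copyNumber = 1) {
    fu <- fractionUnfolded(tmCelsius, params@growthTempCelsius,
        params@stabilitySlope)
    kMatR <- log(2) / params@t50RedMin
    kMatG <- log(2) / params@t50GreenMin
    kDeg <- params@kDegBasal + params@kDegUnfolded * fu
    A <- matrix(0, 6, 6)
    A[1, 1] <- -(kMatR + kDeg + params@kAgg + mu)
    A[1, 6] <- params@kSyn * copyNumber
    A[2, 1] <- kMatR; A[2, 2] <- -(kDeg + params@kAgg + mu)
    A[3, 1] <- params@kAgg; A[3, 2] <- params@kAgg; A[3, 3] <- -mu
    A[4, 1] <- params@betaUnfolded * fu
    A[4, 2] <- params@betaUnfolded * fu
    A[4, 4] <- -(kMatG + mu)
    A[4, 6] <- params@alphaTranslation * params@kSyn * copyNumber
    A[5, 4] <- kMatG; A[5, 5] <- -mu
    t(vapply(times, function(t)
        as.numeric(Matrix::expm(A * t) %*% c(0, 0, 0, 0, 0, 1))[1:5],
        numeric(5)))
}
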