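#' Fit a logistic growth model to an OD600 curve
#'
#' Nonlinear least squares (Gaussian error, Levenberg-Marquardt) for
#' `N(t) = K / (1 + (K/N0 - 1) exp(-r t))`, followed by sampling-based
#' uncertainty: a seeded residual bootstrap (default) or random-walk
#' Metropolis MCMC with uniform priors over documented bounds
#' (`n0` in (0, 2 max OD], `r` in (0, 1] 1/min, `K` in
#' (max OD / 2, 50 max OD]). Posterior draws of `(n0, r, k_cap)`
#' populate the fit and feed [maxGrowthRate()] and [dilutionBias()].
#'
#' @param curve data.frame with columns `time_min` (strictly
#'   increasing) and `od600` (> 0); >= 5 points.
#' @param method `"bootstrap"` (default) or `"mcmc"`.
#' @param nDraws posterior draws (default 500).
#' @param seed integer seed for the draws.
#'
#' @return A [GrowthFit-class].
#' @examples
#' g <- growthModel(0.05, 0.02, 1.2)
#' curve <- data.frame(time_min = samplingSchedule(),
#'     od600 = logisticOd(g, samplingSchedule()))
#' fitLogistic(curve, nDraws = 50)
#' @export
fitLogistic <- function(curve, method = c("bootstrap", "mcmc"),
        nDraws = 500L, seed = 1L) {
    method <- match.arg(method)
    stopifnot(all(c("time_min", "od600") %in% names(curve)))
    t <- curve$time_min; y <- curve$od600
    if (length(t) < 5L)
        stop("need >= 5 growth points", call. = FALSE)
    if (any(diff(t) <= 0))
        stop("times must be strictly increasing", call. = FALSE)
    if (any(y <= 0))
        stop("OD600 values must be > 0", call. = FALSE)
    if (olsSlope(t, log(y)) <= 0)
        stop("growth curve is not increasing: logistic fit undefined",
            call. = FALSE)
    est <- logisticNls(t, y)
    resid <- y - logisticOd(growthModel(est[1], est[2], est[3]), t)
    draws <- withSeed(seed, switch(method,
        bootstrap = bootstrapDraws(t, y, est, resid, nDraws),
        mcmc = mcmcDraws(t, y, est, resid, nDraws)))
    colnames(draws) <- c("n0", "r", "k_cap")
    fit <- new("GrowthFit", n0 = est[1], r = est[2], kCap = est[3],
        posterior = draws, muMax = NA_real_, muMaxSd = NA_real_,
        method = method, seed = as.integer(seed),
        data = data.frame(time_min = t, od600 = y))
    mm <- maxGrowthRate(fit)
    fit@muMax <- mm[["mu_max"]]
    fit@muMaxSd <- mm[["mu_max_sd"]]
    fit
}

## Point estimate by Levenberg-Marquardt NLS with log-linear start.
logisticNls <- function(t, y, start = NULL) {
    if (is.null(start)) {
        k0 <- max(y) * 1.05
        r0 <- max(olsSlope(t, log(y)), 1e-4)
        start <- c(n0 = max(min(y), 1e-6), r = r0, k = k0)
    }
    fit <- minpack.lm::nlsLM(
        y ~ k / (1 + (k / n0 - 1) * exp(-r * t)),
        start = as.list(start),
        lower = c(1e-9, 1e-6, max(y) / 2),
        upper = c(2 * max(y), 1, 50 * max(y)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    if (cf[["n0"]] >= cf[["k"]])
        stop("logistic fit degenerate (n0 >= K); residual sd ",
            signif(stats::sd(stats::resid(fit)), 3), call. = FALSE)
    c(cf[["n0"]], cf[["r"]], cf[["k"]])
}

bootstrapDraws <- function(t, y, est, resid, nDraws) {
    n <- length(y)
    draws <- matrix(NA_real_, nDraws, 3L)
    fitted <- y - resid
    for (i in seq_len(nDraws)) {
        yb <- fitted + sample(resid, n, replace = TRUE)
        yb[yb <= 0] <- min(y) * 1e-3
        draws[i, ] <- tryCatch(
            logisticNls(t, yb, start = c(n0 = est[1], r = est[2],
                k = est[3])),
            error = function(e) est)
    }
    draws
}

## Random-walk Metropolis under uniform priors; Gaussian likelihood
## with sigma fixed at the NLS residual sd (profile approximation).
mcmcDraws <- function(t, y, est, resid, nDraws, thin = 4L,
        burn = 500L) {
    lo <- c(1e-9, 1e-6, max(y) / 2)
    hi <- c(2 * max(y), 1, 50 * max(y))
    sigma <- max(stats::sd(resid), 1e-9 * max(y))
    logPost <- function(p) {
        if (any(p <= lo) || any(p >= hi) || p[1] >= p[3]) return(-Inf)
        mu <- logisticOd(growthModel(p[1], p[2], p[3]), t)
        -sum((y - mu)^2) / (2 * sigma^2)
    }
    step <- pmax(abs(est), c(1e-3, 1e-4, 1e-2)) * 0.02
    cur <- est; curLp <- logPost(cur)
    total <- burn + nDraws * thin
    draws <- matrix(NA_real_, nDraws, 3L)
    j <- 0L
    for (i in seq_len(total)) {
        prop <- cur + stats::rnorm(3L) * step
        lp <- logPost(prop)
        if (log(stats::runif(1)) < lp - curLp) {
            cur <- prop; curLp <- lp
        }
        if (i > burn && (i - burn) %% thin == 0L) {
            j <- j + 1L
            draws[j, ] <- cur
        }
    }
    draws
}

#' Maximum specific growth rate with uncertainty
#'
#' For each posterior draw, evaluates the specific (per-capita) growth
#' rate `mu(t) = d ln N / dt = r (1 - N(t)/K)` numerically over the
#' observed time window and takes its maximum; reports the posterior
#' mean and standard deviation of those maxima. `mode = "absolute"`
#' instead maximises `dN/dt = r N (1 - N/K)`.
#'
#' @param fit a [GrowthFit-class] with nonempty posterior.
#' @param mode `"specific"` (default) or `"absolute"`.
#' @return named numeric: `mu_max` and `mu_max_sd` (1/min, or OD/min
#'   for `"absolute"`).
#' @export
maxGrowthRate <- function(fit, mode = c("specific", "absolute")) {
    mode <- match.arg(mode)
    stopifnot(is(fit, "GrowthFit"))
    draws <- fit@posterior
    if (nrow(draws) == 0L)
        stop("empty posterior sample", call. = FALSE)
    tt <- seq(min(fit@data$time_min), max(fit@data$time_min),
        length.out = 241L)
    maxima <- apply(draws, 1L, function(p) {
        g <- growthModel(p[1], p[2], p[3])
        mu <- specificGrowthRate(g, tt)
        if (mode == "absolute") mu <- mu * logisticOd(g, tt)
        max(mu)
    })
    c(mu_max = mean(maxima), mu_max_sd = stats::sd(maxima))
}

#' Dilution bias of a relative fluorescence rate over a window
#'
#' The time-averaged specific growth rate over a window,
#' `[ln N(t_end) - ln N(t_start)] / (t_end - t_start)` — the additive
#' depression that growth dilution alone imposes on any per-cell
#' relative fluorescence rate measured in that window.
#'
#' @param fit a [GrowthFit-class] or a [growthModel()].
#' @param window closed interval `c(start, end)` (min) inside the
#'   observed times (for a fitted curve).
#' @return bias (1/min).
#' @examples
#' dilutionBias(growthModel(0.05, 0.02, 1.2), c(30, 60))
#' @export
dilutionBias <- function(fit, window) {
    if (length(window) != 2L || window[2] <= window[1])
        stop("window must be c(start, end) with end > start",
            call. = FALSE)
    g <- if (is(fit, "GrowthFit")) {
        tr <- range(fit@data$time_min)
        if (window[1] < tr[1] || window[2] > tr[2])
            stop("window outside observed times", call. = FALSE)
        growthModel(fit@n0, fit@r, fit@kCap)
    } else if (inherits(fit, "logisticGrowth")) fit else
        stop("fit must be a GrowthFit or a growthModel", call. = FALSE)
    (log(logisticOd(g, window[2])) - log(logisticOd(g, window[1]))) /
        (window[2] - window[1])
}

#' Spread of the dilution bias across growth fits
#'
#' Mean and standard deviation (sample, n-1 convention) of
#' [dilutionBias()] across a collection of fits, optionally expressed
#' as a percentage of a reference relative rate.
#'
#' @param fits list of >= 2 [GrowthFit-class] or [growthModel()]
#'   objects.
#' @param window closed interval (min).
#' @param referenceRate optional relative rate (1/min) for the
#'   percentage columns.
#' @return one-row data.frame: `window_start`, `window_end`,
#'   `mean_bias`, `sd_bias`, `sd_convention`, and when a reference is
#'   supplied `mean_percent_of_reference`, `sd_percent_of_reference`.
#' @export
dilutionSpread <- function(fits, window, referenceRate = NULL) {
    if (length(fits) < 2L)
        stop("need >= 2 growth fits", call. = FALSE)
    biases <- vapply(fits, dilutionBias, numeric(1), window = window)
    out <- data.frame(window_start = window[1], window_end = window[2],
        mean_bias = mean(biases), sd_bias = stats::sd(biases),
        sd_convention = "sample (n-1)")
    if (!is.null(referenceRate)) {
        out$mean_percent_of_reference <-
            100 * mean(biases) / referenceRate
        out$sd_percent_of_reference <- 100 * stats::sd(biases) /
            abs(referenceRate)
    }
    out
}
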