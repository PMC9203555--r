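#' Per-event log-log slope of green on red fluorescence
#'
#' OLS regression of log10(green) on log10(red) across the events of a
#' sample. Slope one with zero residual variance is equivalent to a
#' constant green/red ratio in every cell; slopes below one mean red
#' varies more than green across the population.
#'
#' @param sample a [TimepointSample-class] with >= 3 events.
#' @return A [SlopeFit-class].
#' @examples
#' s <- timepointSample("wt", 1, 0, data.frame(
#'     fsc = 1, ssc = 1, red = c(1, 10, 100), green = 3 * c(1, 10, 100)))
#' logLogSlope(s)   # slope 1, intercept log10(3)
#' @export
logLogSlope <- function(sample) {
    stopifnot(is(sample, "TimepointSample"))
    ev <- flowEvents(sample)
    if (nrow(ev) < 3L)
        stop("log-log slope needs >= 3 events", call. = FALSE)
    if (any(ev$red <= 0) || any(ev$green <= 0))
        stop("nonpositive channel value: log transform undefined",
            call. = FALSE)
    x <- log10(ev$red); y <- log10(ev$green)
    b <- olsSlope(x, y)
    new("SlopeFit", variant = sample@variant,
        replicate = sample@replicate, timeMin = sample@timeMin,
        slope = b, intercept = mean(y) - b * mean(x),
        nEvents = nrow(ev))
}

## ---- Variational Bayesian Gaussian mixture (diagonal covariance) ----
##
## Coordinate-ascent variational inference for a finite mixture with a
## Dirichlet prior over weights (tiny concentration prunes unused
## components) and independent Normal-Gamma priors per dimension for
## each component's mean and precision. The ELBO is computed every
## sweep and must never decrease.

vbgmmInit <- function(X, K, merged = FALSE) {
    n <- nrow(X)
    r <- matrix(0, n, K)
    if (merged) {
        ## single-component basin: lets the sparsity prior keep one
        ## merged component when the data are unimodal
        r[, 1L] <- 1
        return(r)
    }
    ## k-means++ seeding: spread centers, then hard-assign.
    centers <- matrix(0, K, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    d2 <- (X[, 1] - centers[1, 1])^2 + (X[, 2] - centers[1, 2])^2
    if (K > 1L) for (k in 2:K) {
        centers[k, ] <- X[sample.int(n, 1L, prob = d2 / sum(d2)), ]
        d2 <- pmin(d2, (X[, 1] - centers[k, 1])^2 +
            (X[, 2] - centers[k, 2])^2)
    }
    dist <- vapply(seq_len(K), function(k)
        (X[, 1] - centers[k, 1])^2 + (X[, 2] - centers[k, 2])^2,
        numeric(n))
    hard <- max.col(-dist, ties.method = "first")
    r[cbind(seq_len(n), hard)] <- 1
    r
}

vbgmmMstep <- function(X, r, prior) {
    D <- ncol(X)
    Nk <- colSums(r)
    Nks <- pmax(Nk, 1e-12)
    xbar <- sweep(crossprod(r, X), 1, Nks, "/")           # K x D
    S <- sweep(crossprod(r, X^2), 1, Nks, "/") - xbar^2   # K x D
    S[S < 0] <- 0
    alpha <- prior$alpha0 + Nk
    beta <- prior$beta0 + Nk
    m <- sweep(sweep(xbar, 1, Nk, "*") +
        matrix(prior$beta0 * prior$m0, nrow(xbar), D, byrow = TRUE),
        1, beta, "/")
    a <- matrix(prior$a0 + Nk / 2, length(Nk), D)
    dev <- sweep(xbar, 2, prior$m0)^2
    b <- matrix(prior$b0, nrow(xbar), D, byrow = TRUE) +
        0.5 * (Nk * S + sweep(dev, 1, prior$beta0 * Nk / beta, "*"))
    list(Nk = Nk, alpha = alpha, beta = beta, m = m, a = a, b = b)
}

## E-step plus the exact bound: with q(Z) set to its optimum, the ELBO
## is sum_n log-sum-exp(log rho_n.) - KL(q(pi) || p) - KL(q(mu,lambda) || p).
## Components whose posterior mass has vanished contribute exactly zero
## (their variational factors equal the prior) and are skipped.
vbgmmEstepElbo <- function(X, q, prior) {
    n <- nrow(X); D <- ncol(X); K <- length(q$alpha)
    active <- which(q$Nk > 1e-9)
    if (!length(active)) active <- 1L
    elnPi <- digamma(q$alpha) - digamma(sum(q$alpha))
    elnLam <- digamma(q$a) - log(q$b)
    eLam <- q$a / q$b
    logR <- matrix(-Inf, n, K)
    for (k in active) {
        dx1 <- X[, 1] - q$m[k, 1]; dx2 <- X[, 2] - q$m[k, 2]
        logR[, k] <- elnPi[k] + 0.5 * (elnLam[k, 1] + elnLam[k, 2]) -
            D / 2 * log(2 * pi) - 0.5 * D / q$beta[k] -
            0.5 * (eLam[k, 1] * dx1 * dx1 + eLam[k, 2] * dx2 * dx2)
    }
    mx <- do.call(pmax, lapply(active, function(k) logR[, k]))
    sm <- 0
    for (k in active) sm <- sm + exp(logR[, k] - mx)
    lse <- mx + log(sm)
    r <- matrix(0, n, K)
    for (k in active) r[, k] <- exp(logR[, k] - lse)
    ## KL(Dirichlet) over all components (dead ones have alpha = alpha0)
    a0v <- rep(prior$alpha0, K)
    klDir <- lgamma(sum(q$alpha)) - sum(lgamma(q$alpha)) -
        lgamma(sum(a0v)) + sum(lgamma(a0v)) +
        sum((q$alpha - a0v) * (digamma(q$alpha) - digamma(sum(q$alpha))))
    ## KL(Normal-Gamma) per active component and dimension
    klNg <- 0
    for (k in active) for (d in seq_len(D)) {
        klN <- 0.5 * (log(q$beta[k] / prior$beta0) +
            prior$beta0 / q$beta[k] - 1 +
            prior$beta0 * eLam[k, d] * (q$m[k, d] - prior$m0[d])^2)
        klG <- (q$a[k, d] - prior$a0) * digamma(q$a[k, d]) -
            lgamma(q$a[k, d]) + lgamma(prior$a0) +
            prior$a0 * (log(q$b[k, d]) - log(prior$b0[d])) +
            q$a[k, d] * (prior$b0[d] - q$b[k, d]) / q$b[k, d]
        klNg <- klNg + klN + klG
    }
    list(r = r, elbo = sum(lse) - klDir - klNg)
}

#' Fit a sparsity-pruned variational Gaussian mixture
#'
#' Variational Bayesian inference for a diagonal-covariance Gaussian
#' mixture in (log10 red, log10 green) space. Up to
#' `nComponentsMax` components are allowed; the Dirichlet weight prior
#' with tiny concentration (default 1e-6) drives unused components'
#' weights toward zero, so the effective number of components is
#' selected by the data. Coordinate-ascent updates alternate
#' responsibilities and the Dirichlet/Normal-Gamma variational
#' posteriors; the evidence lower bound is computed every sweep (in
#' the exact log-sum-exp minus KL-divergence form) and never
#' decreases. Several restarts are run and the best ELBO kept: the
#' first starts from a single merged component, the rest from
#' k-means++ seeding.
#'
#' @param x a [TimepointSample-class] (its `red`/`green` channels are
#'   log10-transformed) or a numeric two-column matrix/data.frame
#'   already in the fitting space.
#' @param nComponentsMax component cap (default 7).
#' @param weightConcentrationPrior Dirichlet concentration (default
#'   1e-6).
#' @param nRestarts independent initialisations (default 5).
#' @param maxIter sweep cap per restart (default 500).
#' @param tol convergence threshold on the absolute ELBO gain per
#'   sweep (default 1e-5).
#' @param seed integer seed (restart streams are derived from it).
#'
#' @return A [MixtureFit-class]; non-convergence within `maxIter` is
#'   flagged via `converged = FALSE`, not an error.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(400), ncol = 2),
#'            matrix(rnorm(400, mean = 6), ncol = 2))
#' fit <- fitMixture(X, seed = 1)
#' effectiveComponents(fit)
#' @export
fitMixture <- function(x, nComponentsMax = 7L,
        weightConcentrationPrior = 1e-6, nRestarts = 5L,
        maxIter = 500L, tol = 1e-5, seed = 1L) {
    X <- if (is(x, "TimepointSample")) {
        ev <- flowEvents(x)
        cbind(log10(ev$red), log10(ev$green))
    } else as.matrix(x)
    if (ncol(X) != 2L)
        stop("mixture input must have two channels", call. = FALSE)
    if (any(!is.finite(X)))
        stop("non-finite values in mixture input", call. = FALSE)
    n <- nrow(X); K <- as.integer(nComponentsMax)
    if (n <= K)
        stop("need more events than components (n > nComponentsMax)",
            call. = FALSE)
    prior <- list(alpha0 = weightConcentrationPrior, beta0 = 1,
        m0 = colMeans(X), a0 = 1,
        b0 = pmax(apply(X, 2, stats::var), 1e-12))
    best <- NULL
    for (rs in seq_len(nRestarts)) {
        ## restart 1 starts from a single merged component (the basin
        ## the sparsity prior selects for unimodal data); the rest are
        ## k-means++ seeded
        r <- withSeed((as.integer(seed) %% 10000000L) * 100L + rs,
            vbgmmInit(X, K, merged = (rs == 1L)))
        q <- vbgmmMstep(X, r, prior)
        trace <- numeric()
        converged <- FALSE
        for (it in seq_len(maxIter)) {
            ee <- vbgmmEstepElbo(X, q, prior)
            trace <- c(trace, ee$elbo)
            r <- ee$r
            q <- vbgmmMstep(X, r, prior)
            if (it > 1L &&
                abs(trace[it] - trace[it - 1L]) < tol) {
                converged <- TRUE
                break
            }
        }
        el <- trace[length(trace)]
        if (is.null(best) || el > best$elbo)
            best <- list(r = r, q = q, elbo = el, trace = trace,
                converged = converged)
    }
    q <- best$q
    w <- q$alpha / sum(q$alpha)
    ## posterior mean variance b/(a-1); guard small a for empty comps
    vars <- pmax(q$b / pmax(q$a - 1, 0.5), 1e-12)
    new("MixtureFit", weights = as.numeric(w / sum(w)),
        means = unname(q$m), variances = unname(vars),
        responsibilities = best$r, elbo = best$elbo,
        elboTrace = best$trace, converged = best$converged,
        seed = as.integer(seed), nComponentsMax = K,
        weightConcentrationPrior = weightConcentrationPrior)
}

#' Count mixture components surviving the weight floor
#'
#' @param fit a [MixtureFit-class].
#' @param weightFloor minimum posterior weight (default 0.01).
#' @return integer count of effective components.
#' @examples
#' # weights c(0.99, 0.009, ...) -> 1 effective component
#' @export
effectiveComponents <- function(fit, weightFloor = 0.01) {
    stopifnot(is(fit, "MixtureFit"))
    sum(mixtureWeights(fit) >= weightFloor)
}

#' Hard cluster assignment from a mixture fit
#'
#' @param fit a [MixtureFit-class].
#' @return integer vector: argmax responsibility per event, suitable
#'   for appending to an event table.
#' @export
assignClusters <- function(fit) {
    stopifnot(is(fit, "MixtureFit"))
    max.col(fit@responsibilities, ties.method = "first")
}

#' Subpopulation report over a time course
#'
#' Summarises a list of mixture fits (one per timepoint, same
#' variant/replicate) into a per-time table: number of effective
#' components and, for each surviving component, its weight, mean and
#' variance per channel, plus low-red / low-green flags marking
#' components whose mean falls below a stated lower quantile of the
#' main (largest-weight) component's marginal — the signature of the
#' late low-abundance subpopulations.
#'
#' @param fits list of [MixtureFit-class] objects.
#' @param times numeric vector of timepoints matching `fits`.
#' @param weightFloor weight floor for surviving components.
#' @param lowQuantile quantile of the main component's marginal below
#'   which a component mean is flagged (default 0.05).
#'
#' @return data.frame with one row per time x surviving component:
#'   `time_min`, `n_effective`, `component`, `weight`, `mean_red`,
#'   `mean_green`, `var_red`, `var_green`, `low_red`, `low_green`.
#' @export
subpopulationReport <- function(fits, times, weightFloor = 0.01,
        lowQuantile = 0.05) {
    if (length(fits) == 0L)
        stop("empty fit list", call. = FALSE)
    if (length(fits) != length(times))
        stop("fits and times must have equal length", call. = FALSE)
    z <- stats::qnorm(lowQuantile)
    rows <- lapply(seq_along(fits), function(i) {
        f <- fits[[i]]
        keep <- which(mixtureWeights(f) >= weightFloor)
        keep <- keep[order(mixtureWeights(f)[keep], decreasing = TRUE)]
        main <- keep[1L]
        thrR <- f@means[main, 1] + z * sqrt(f@variances[main, 1])
        thrG <- f@means[main, 2] + z * sqrt(f@variances[main, 2])
        data.frame(time_min = times[i], n_effective = length(keep),
            component = keep, weight = mixtureWeights(f)[keep],
            mean_red = f@means[keep, 1], mean_green = f@means[keep, 2],
            var_red = f@variances[keep, 1],
            var_green = f@variances[keep, 2],
            low_red = f@means[keep, 1] < thrR,
            low_green = f@means[keep, 2] < thrG)
    })
    do.call(rbind, rows)
}
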