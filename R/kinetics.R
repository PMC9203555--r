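#' Equilibrium fraction of unfolded protein
#'
#' Two-state Boltzmann occupancy of the unfolded state at the growth
#' temperature. The unfolding free energy is parameterised linearly in
#' the melting temperature, `dG_unf = s * (Tm - T)` (kcal/mol), so that
#' `dG_unf = 0` (equal occupancy) exactly at `T = Tm`:
#' `f_u = 1 / (1 + exp(dG_unf / (R T_K)))` with R = 1.987e-3
#' kcal/(mol K) and `T_K` the temperature in Kelvin.
#'
#' @param tmCelsius variant melting temperature (degrees C).
#' @param tempCelsius growth temperature (degrees C), above absolute
#'   zero.
#' @param stabilitySlope s >= 0, kcal/mol per degree C.
#'
#' @return Fraction in (0, 1), strictly decreasing in `tmCelsius` for
#'   `stabilitySlope > 0`. Vectorised over `tmCelsius`.
#' @examples
#' fractionUnfolded(55, 55, 0.25)      # 0.5 at the melting point
#' fractionUnfolded(55, 37, 0.25)      # small for a stable protein
#' @export
fractionUnfolded <- function(tmCelsius, tempCelsius, stabilitySlope) {
    stopIfNotFinite(c(tmCelsius, tempCelsius, stabilitySlope),
        "fractionUnfolded inputs")
    if (tempCelsius <= -273.15)
        stop("tempCelsius must be above absolute zero", call. = FALSE)
    if (stabilitySlope < 0)
        stop("stabilitySlope must be >= 0", call. = FALSE)
    tK <- tempCelsius + 273.15
    dG <- stabilitySlope * (tmCelsius - tempCelsius)
    1 / (1 + exp(dG / (.RGAS * tK)))
}

#' Fraction of fluorophore matured after a pulse
#'
#' First-order chromophore maturation with rate `ln(2) / t50`, so the
#' matured fraction after one half-time is exactly one half:
#' `1 - exp(-ln(2) t / t50) = 1 - 2^(-t / t50)`.
#'
#' @param tMin time since synthesis (min), >= 0.
#' @param t50Min maturation half-time (min), > 0.
#'
#' @return Fraction in [0, 1), monotone nondecreasing in `tMin` with
#'   limit 1. Vectorised over `tMin`.
#' @examples
#' maturationFraction(42, 42)   # 0.5
#' maturationFraction(84, 42)   # 0.75
#' @export
maturationFraction <- function(tMin, t50Min) {
    stopIfNotFinite(c(tMin, t50Min), "maturationFraction inputs")
    if (any(tMin < 0)) stop("tMin must be >= 0", call. = FALSE)
    if (t50Min <= 0) stop("t50Min must be > 0", call. = FALSE)
    1 - 2^(-tMin / t50Min)
}

#' Logistic growth model
#'
#' Container for the logistic culture growth model
#' `N(t) = K / (1 + (K/N0 - 1) exp(-r t))`. A carrying capacity of
#' `Inf` degenerates to pure exponential growth `N0 exp(r t)` with
#' constant specific rate `r`.
#'
#' @param n0 density at t = 0 (OD600), > 0.
#' @param r intrinsic rate (1/min), >= 0.
#' @param kCap carrying capacity (OD600), > `n0`; may be `Inf`.
#'
#' @return A list of class `"logisticGrowth"`.
#' @examples
#' g <- growthModel(0.5, 0.023, 2.5)
#' logisticOd(g, c(0, 60, 240))
#' specificGrowthRate(g, c(0, 60, 240))
#' @export
growthModel <- function(n0, r, kCap) {
    stopIfNotFinite(c(n0, r), "growth model parameters")
    if (n0 <= 0 || r < 0 || kCap <= n0)
        stop("growth model requires n0 > 0, r >= 0, kCap > n0",
            call. = FALSE)
    structure(list(n0 = n0, r = r, kCap = kCap),
        class = "logisticGrowth")
}

#' @rdname growthModel
#' @param model a `"logisticGrowth"` model.
#' @param tMin times (min); negative values extend the same curve
#'   before induction.
#' @return `logisticOd`: density N(t); `specificGrowthRate`: the
#'   per-capita dilution rate `mu(t) = r (1 - N(t)/K)` (1/min).
#' @export
logisticOd <- function(model, tMin) {
    if (is.infinite(model$kCap))
        return(model$n0 * exp(model$r * tMin))
    model$kCap / (1 + (model$kCap / model$n0 - 1) * exp(-model$r * tMin))
}

#' @rdname growthModel
#' @export
specificGrowthRate <- function(model, tMin) {
    if (is.infinite(model$kCap))
        return(rep(model$r, length(tMin)))
    model$r * (1 - logisticOd(model, tMin) / model$kCap)
}

## Variant/replicate growth model from kinetic parameters.
## growthTmCoupling modulates r around the wt anchor (55 C).
makeGrowthModel <- function(params, tmCelsius, rMultiplier = 1) {
    r <- params@growthRate *
        (1 + params@growthTmCoupling * (tmCelsius - 55)) * rMultiplier
    growthModel(params@growthN0, max(r, 1e-8), params@growthK)
}

## Right-hand side of the per-cell reporter ODE.
## State x = (poi_immature, poi_mature, poi_dark, gfp_immature,
## gfp_mature), all per unit synthesis scale (copy number x replicate
## multiplier folded in via `synScale`).
cellOde <- function(t, x, p) {
    mu <- specificGrowthRate(p$growth, t)
    indFrac <- if (t < 0) p$leak else 1
    syn <- p$kSyn * p$synScale * indFrac * p$synOn
    lossR <- p$kDeg + p$kAgg + mu
    pool <- x[1] + x[2]
    list(c(
        syn - (p$kMatR + lossR) * x[1],
        p$kMatR * x[1] - lossR * x[2],
        p$kAgg * pool - mu * x[3],
        p$alpha * syn + p$beta * p$fu * pool - (p$kMatG + mu) * x[4],
        p$kMatG * x[4] - mu * x[5]))
}

.STATES <- c("poi_immature", "poi_mature", "poi_dark", "gfp_immature",
    "gfp_mature")

## Integrate the cell ODE and return the state matrix at `times`
## (rows). Internal; wraps deSolve::lsoda at tight tolerances.
integrateCell <- function(odeParams, times, init, t0) {
    tt <- sort(unique(c(t0, times)))
    sol <- deSolve::lsoda(y = init, times = tt, func = cellOde,
        parms = odeParams, rtol = 1e-9, atol = 1e-12)
    if (any(!is.finite(sol[, -1]))) {
        bad <- tt[which(apply(!is.finite(sol[, -1]), 1, any))[1]]
        stop(sprintf("cell ODE integration produced non-finite state at t = %g min",
            bad), call. = FALSE)
    }
    out <- sol[match(times, tt), -1, drop = FALSE]
    out[out < 0] <- 0    # clip integrator round-off below zero
    colnames(out) <- .STATES
    out
}

## Assemble the ODE parameter list for a variant.
cellOdeParams <- function(params, tmCelsius, growth, synScale = 1,
        synOn = 1) {
    fu <- fractionUnfolded(tmCelsius, params@growthTempCelsius,
        params@stabilitySlope)
    list(
        kSyn = params@kSyn,
        synScale = synScale,
        synOn = synOn,
        leak = params@leakFraction,
        kMatR = log(2) / params@t50RedMin,
        kMatG = log(2) / params@t50GreenMin,
        kDeg = params@kDegBasal + params@kDegUnfolded * fu,
        kAgg = params@kAgg,
        alpha = params@alphaTranslation,
        beta = params@betaUnfolded,
        fu = fu,
        growth = growth)
}

#' Simulate the deterministic trajectory of a single cell
#'
#' Integrates the linear per-cell reporter ODE: synthesis of immature
#' client-RFP fusion, first-order maturation of both fluorophores,
#' stability-dependent degradation acting on the equilibrium unfolded
#' fraction, uniform aggregation into a dark pool, DnaK-promoter GFP
#' synthesis driven by translation plus unfolded load, and continuous
#' dilution by the culture growth rate. Folding is treated as an
#' instantaneous equilibrium, so the unfolded pool is
#' `f_u * (poi_immature + poi_mature)` rather than a separate state.
#'
#' With the default all-zero initial state the integration starts at
#' `-params@preInductionMin` with synthesis at `leakFraction`
#' (pre-induction leak); induction is at t = 0. If `init` is supplied
#' the integration starts at `min(times)` from that state instead.
#'
#' If `params@toxicityEnabled`, synthesis switches off permanently once
#' the cell's soluble client pool exceeds `toxicityThreshold` (the
#' crossing time is resolved on a 1-min grid).
#'
#' @param tmCelsius variant melting temperature (degrees C).
#' @param params a [KineticParams-class].
#' @param times output times (min); the default sampling schedule.
#' @param growth a [growthModel()]; defaults to the model implied by
#'   `params` for this variant.
#' @param copyNumber plasmid copy number of the cell.
#' @param synthesisMultiplier extra synthesis scale (replicate effect).
#' @param init optional named initial state (a.u.) at `min(times)`.
#'
#' @return data.frame with column `time_min` and the five state
#'   variables `poi_immature`, `poi_mature`, `poi_dark`,
#'   `gfp_immature`, `gfp_mature` (all >= 0).
#' @examples
#' tr <- simulateCell(55, kineticParams(), times = c(0, 60, 120))
#' tr
#' @export
simulateCell <- function(tmCelsius, params, times = samplingSchedule(),
        growth = NULL, copyNumber = 1, synthesisMultiplier = 1,
        init = NULL) {
    stopifnot(is(params, "KineticParams"))
    stopIfNotFinite(times, "times")
    if (is.null(growth)) growth <- makeGrowthModel(params, tmCelsius)
    scale <- copyNumber * synthesisMultiplier
    op <- cellOdeParams(params, tmCelsius, growth, synScale = scale)
    if (is.null(init)) {
        y0 <- stats::setNames(numeric(5), .STATES)
        t0 <- -params@preInductionMin
    } else {
        y0 <- stats::setNames(numeric(5), .STATES)
        y0[names(init)] <- init
        t0 <- min(times)
    }
    if (!params@toxicityEnabled) {
        st <- integrateCell(op, times, y0, t0)
        return(data.frame(time_min = times, st))
    }
    ## Toxicity: integrate on a 1-min grid, find the first crossing of
    ## the soluble client pool, then restart with synthesis off.
    grid <- sort(unique(c(seq(t0, max(times), by = 1), times)))
    stG <- integrateCell(op, grid, y0, t0)
    pool <- stG[, "poi_immature"] + stG[, "poi_mature"]
    hit <- which(pool >= params@toxicityThreshold)[1]
    if (is.na(hit)) {
        st <- stG[match(times, grid), , drop = FALSE]
        return(data.frame(time_min = times, st))
    }
    ts <- grid[hit]
    opOff <- op; opOff$synOn <- 0
    after <- grid[grid >= ts]
    stOff <- if (length(after) > 1L)
        integrateCell(opOff, after, stG[hit, ], ts) else
        matrix(stG[hit, ], 1L, 5L, dimnames = list(NULL, .STATES))
    stG[grid >= ts, ] <- stOff
    data.frame(time_min = times, stG[match(times, grid), , drop = FALSE])
}
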