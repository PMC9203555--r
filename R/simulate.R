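#' Simulate a single-replicate flow-cytometry time series
#'
#' Draws `nCells` cells with lognormal plasmid copy numbers, one
#' replicate-level synthesis multiplier and one growth-rate jitter,
#' integrates the shared per-unit cell trajectory (the model is linear
#' in copy number, so one ODE solve serves the whole replicate unless
#' the toxicity switch is on), and emits gated-ready event tables at
#' every schedule time:
#' `red = gainRed * poi_mature + backgroundRed` and
#' `green = gainGreen * gfp_mature + backgroundGreen`, each multiplied
#' by mean-one lognormal measurement noise of CV `noiseCv`; forward
#' and side scatter are stationary lognormals carried for gating.
#' Identical `seed` and parameters give byte-identical output.
#'
#' @param variant variant name (label carried into the samples).
#' @param tmCelsius the variant's melting temperature (degrees C).
#' @param params a [KineticParams-class].
#' @param nCells events per timepoint (default 3000).
#' @param seed integer seed for this replicate.
#' @param replicate replicate index (label).
#' @param times sampling schedule (min).
#'
#' @return list with elements `samples` (list of
#'   [TimepointSample-class], one per schedule time), `growthCurve`
#'   (data.frame `time_min`, `od600`), and `growth` (the noiseless
#'   [growthModel()] used for dilution).
#' @examples
#' pop <- simulatePopulation("wt", 55, kineticParams(), nCells = 100,
#'     seed = 1)
#' pop$samples[[1]]
#' @export
simulatePopulation <- function(variant, tmCelsius, params, nCells = 3000,
        seed = params@rngSeed, replicate = 1L,
        times = samplingSchedule()) {
    stopifnot(is(params, "KineticParams"))
    if (nCells < 1) stop("nCells must be >= 1", call. = FALSE)
    times <- sort(unique(times))
    withSeed(seed, {
        rMult <- rlnormCv(1L, params@growthReplicateSd)
        synMult <- rlnormCv(1L, params@replicateEffectSd)
        copies <- stats::rlnorm(nCells, params@copyNumberLogMean,
            params@copyNumberLogSd)
        growth <- makeGrowthModel(params, tmCelsius, rMultiplier = rMult)
        od <- logisticOd(growth, times) *
            rlnormCv(length(times), params@odNoiseCv)

        traj <- referenceTrajectories(params, tmCelsius, growth, synMult,
            copies, times)

        samples <- vector("list", length(times))
        for (i in seq_along(times)) {
            fsc <- stats::rlnorm(nCells, params@fscLogMean, params@fscLogSd)
            ssc <- stats::rlnorm(nCells, params@sscLogMean, params@sscLogSd)
            red <- (params@gainRed * traj$redProtein[, i] +
                params@backgroundRed) * rlnormCv(nCells, params@noiseCv)
            green <- (params@gainGreen * traj$greenProtein[, i] +
                params@backgroundGreen) * rlnormCv(nCells, params@noiseCv)
            samples[[i]] <- timepointSample(variant, replicate, times[i],
                data.frame(fsc = fsc, ssc = ssc, red = red, green = green))
        }
        list(samples = samples,
            growthCurve = data.frame(time_min = times, od600 = od),
            growth = growth)
    })
}

## Per-cell matured-protein matrices (cells x times). Exploits
## linearity in copy number: one per-unit ODE solve, scaled per cell.
## With the toxicity switch on, cells that cross the threshold get a
## synthesis-off continuation solved once per 1-min crossing time (the
## switched system is linear and homogeneous, so it also scales).
referenceTrajectories <- function(params, tmCelsius, growth, synMult,
        copies, times) {
    op <- cellOdeParams(params, tmCelsius, growth, synScale = synMult)
    y0 <- stats::setNames(numeric(5), .STATES)
    t0 <- -params@preInductionMin
    if (!params@toxicityEnabled) {
        st <- integrateCell(op, times, y0, t0)
        return(list(
            redProtein = copies %o% st[, "poi_mature"],
            greenProtein = copies %o% st[, "gfp_mature"]))
    }
    grid <- sort(unique(c(seq(t0, max(times), by = 1), times)))
    stG <- integrateCell(op, grid, y0, t0)
    poolRef <- stG[, "poi_immature"] + stG[, "poi_mature"]
    redM <- copies %o% stG[match(times, grid), "poi_mature"]
    greenM <- copies %o% stG[match(times, grid), "gfp_mature"]
    ## first grid index at which each cell crosses the threshold
    crossIdx <- vapply(copies, function(ci)
        which(ci * poolRef >= params@toxicityThreshold)[1], integer(1))
    opOff <- op; opOff$synOn <- 0
    for (idx in sort(unique(crossIdx[!is.na(crossIdx)]))) {
        ts <- grid[idx]
        after <- grid[grid >= ts]
        stOff <- if (length(after) > 1L)
            integrateCell(opOff, after, stG[idx, ], ts) else
            matrix(stG[idx, ], 1L, 5L,
                dimnames = list(NULL, .STATES))
        sel <- which(!is.na(crossIdx) & crossIdx == idx)
        lateTimes <- which(times >= ts)
        pick <- match(times[lateTimes], after)
        redM[sel, lateTimes] <-
            copies[sel] %o% stOff[pick, "poi_mature"]
        greenM[sel, lateTimes] <-
            copies[sel] %o% stOff[pick, "gfp_mature"]
    }
    list(redProtein = redM, greenProtein = greenM)
}

#' Construct a timepoint sample
#'
#' @param variant variant name.
#' @param replicate replicate index (>= 1).
#' @param timeMin minutes since induction.
#' @param events data.frame with positive columns `fsc`, `ssc`, `red`,
#'   `green`.
#' @return A [TimepointSample-class].
#' @examples
#' timepointSample("wt", 1, 0,
#'     data.frame(fsc = 1, ssc = 1, red = 2, green = 6))
#' @export
timepointSample <- function(variant, replicate, timeMin, events) {
    new("TimepointSample", variant = as.character(variant),
        replicate = as.integer(replicate), timeMin = as.numeric(timeMin),
        events = events)
}

#' Simulate the full variant panel
#'
#' Runs [simulatePopulation()] for every variant x replicate with
#' deterministic per-replicate sub-seeds derived from the master seed,
#' and assembles a [ReporterDataset-class]. The default call emulates
#' the full study design: 8 variants x 3 replicates x 21 timepoints x
#' 3000 events.
#'
#' @param panel a [VariantPanel-class] (default [defaultVariantPanel()]).
#' @param params a [KineticParams-class] (default [kineticParams()]).
#' @param nCells events per sample.
#' @param replicates replicates per variant.
#' @param seed master integer seed.
#' @param times sampling schedule (min).
#'
#' @return A [ReporterDataset-class].
#' @examples
#' ds <- simulatePanel(nCells = 50, seed = 1)
#' ds
#' @export
simulatePanel <- function(panel = defaultVariantPanel(),
        params = kineticParams(), nCells = 3000, replicates = 3,
        seed = params@rngSeed, times = samplingSchedule()) {
    samples <- list()
    gc <- vector("list", length(panel@name) * replicates)
    k <- 0L
    for (i in seq_along(panel@name)) {
        for (j in seq_len(replicates)) {
            k <- k + 1L
            pop <- simulatePopulation(panel@name[i], panel@tmCelsius[i],
                params, nCells = nCells,
                seed = deriveSeed(seed, i, j), replicate = j,
                times = times)
            samples <- c(samples, pop$samples)
            gc[[k]] <- data.frame(variant = panel@name[i], replicate = j,
                pop$growthCurve)
        }
    }
    new("ReporterDataset", samples = samples,
        growthCurves = do.call(rbind, gc), panel = panel,
        params = params, seed = as.integer(seed))
}
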