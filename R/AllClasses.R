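#' @import methods
NULL

#' Variant panel: named protein variants with melting temperatures
#'
#' A `VariantPanel` holds the protein variants under study. Each variant
#' carries an in vitro melting temperature (Tm, degrees C), the stability
#' axis against which every correlation track is computed, and a flag
#' marking the wild-type construct.
#'
#' @slot name character vector of distinct variant names.
#' @slot tmCelsius numeric vector of melting temperatures (degrees C).
#' @slot wildType logical vector; exactly one entry is `TRUE` in the
#'   default panel.
#' @slot description character vector of free-text descriptions.
#'
#' @seealso [variantPanel()], [defaultVariantPanel()], [tmMap()]
#' @exportClass VariantPanel
setClass("VariantPanel",
    slots = c(
        name = "character",
        tmCelsius = "numeric",
        wildType = "logical",
        description = "character"
    )
)

setValidity("VariantPanel", function(object) {
    n <- length(object@name)
    if (length(object@tmCelsius) != n || length(object@wildType) != n ||
        length(object@description) != n)
        return("all slots must have equal length")
    if (anyDuplicated(object@name))
        return("variant names must be distinct")
    if (!all(is.finite(object@tmCelsius)))
        return("tmCelsius must be finite")
    TRUE
})

#' Kinetic parameters of the dual-reporter cell model
#'
#' All tunable parameters of the per-cell generative model: plasmid copy
#' number distribution, synthesis and degradation rates, the two-term
#' DnaK-promoter activity model, fluorophore maturation half-times,
#' measurement noise, growth model and toxicity switch. Time is in
#' minutes throughout; temperatures in degrees C at the interface.
#' Construct with [kineticParams()], which documents every field and its
#' default.
#'
#' @seealso [kineticParams()], [simulateCell()], [simulatePopulation()]
#' @exportClass KineticParams
setClass("KineticParams",
    slots = c(
        copyNumberLogMean = "numeric",
        copyNumberLogSd = "numeric",
        kSyn = "numeric",
        leakFraction = "numeric",
        stabilitySlope = "numeric",
        growthTempCelsius = "numeric",
        kDegBasal = "numeric",
        kDegUnfolded = "numeric",
        kAgg = "numeric",
        alphaTranslation = "numeric",
        betaUnfolded = "numeric",
        t50RedMin = "numeric",
        t50GreenMin = "numeric",
        noiseCv = "numeric",
        backgroundRed = "numeric",
        backgroundGreen = "numeric",
        gainRed = "numeric",
        gainGreen = "numeric",
        replicateEffectSd = "numeric",
        preInductionMin = "numeric",
        fscLogMean = "numeric",
        fscLogSd = "numeric",
        sscLogMean = "numeric",
        sscLogSd = "numeric",
        growthN0 = "numeric",
        growthRate = "numeric",
        growthK = "numeric",
        growthReplicateSd = "numeric",
        growthTmCoupling = "numeric",
        odNoiseCv = "numeric",
        toxicityEnabled = "logical",
        toxicityThreshold = "numeric",
        rngSeed = "integer"
    )
)

setValidity("KineticParams", function(object) {
    rates <- c(object@kSyn, object@kDegBasal, object@kDegUnfolded,
        object@kAgg, object@alphaTranslation, object@betaUnfolded,
        object@stabilitySlope, object@growthRate)
    if (any(!is.finite(rates)) || any(rates < 0))
        return("all rates must be finite and >= 0")
    if (object@leakFraction < 0 || object@leakFraction >= 1)
        return("leakFraction must lie in [0, 1)")
    if (object@t50RedMin <= 0 || object@t50GreenMin <= 0)
        return("maturation half-times must be > 0")
    if (object@noiseCv < 0 || object@odNoiseCv < 0)
        return("noise coefficients of variation must be >= 0")
    if (object@growthTempCelsius <= -273.15)
        return("growthTempCelsius must exceed absolute zero")
    if (object@backgroundRed <= 0 || object@backgroundGreen <= 0)
        return("channel backgrounds must be > 0 (positivity floor)")
    if (object@growthN0 <= 0 || object@growthK <= 0 ||
        object@growthN0 >= object@growthK)
        return("growth model requires 0 < growthN0 < growthK")
    if (object@preInductionMin < 0)
        return("preInductionMin must be >= 0")
    TRUE
})

#' Single-cell events for one variant/replicate/timepoint
#'
#' The raw observation unit: the table of single-cell events recorded
#' for one variant, replicate and sampling time. Events carry four
#' channels (`fsc`, `ssc`, `red`, `green`), all strictly positive so
#' that log transforms are always defined.
#'
#' @slot variant variant name.
#' @slot replicate replicate index (>= 1).
#' @slot timeMin minutes since induction.
#' @slot events data.frame with columns `fsc`, `ssc`, `red`, `green`.
#'
#' @seealso [timepointSample()], [gateSinglets()], [summarizeSamples()]
#' @exportClass TimepointSample
setClass("TimepointSample",
    slots = c(
        variant = "character",
        replicate = "integer",
        timeMin = "numeric",
        events = "data.frame"
    )
)

setValidity("TimepointSample", function(object) {
    if (length(object@variant) != 1L || length(object@replicate) != 1L ||
        length(object@timeMin) != 1L)
        return("variant, replicate and timeMin must be scalars")
    if (object@replicate < 1L)
        return("replicate must be >= 1")
    ev <- object@events
    need <- c("fsc", "ssc", "red", "green")
    if (!all(need %in% names(ev)))
        return("events must have columns fsc, ssc, red, green")
    if (nrow(ev) > 0L) {
        m <- as.matrix(ev[, need])
        if (any(!is.finite(m)) || any(m <= 0))
            return("all event channels must be finite and > 0")
    }
    TRUE
})

#' A complete simulated reporter experiment
#'
#' Container for one simulated experiment: the per-sample event tables
#' for every variant x replicate x timepoint, the matching OD600 growth
#' curves, and the panel/parameters/seed that generated them.
#'
#' @slot samples list of [TimepointSample-class] objects.
#' @slot growthCurves data.frame with columns `variant`, `replicate`,
#'   `time_min`, `od600`.
#' @slot panel the [VariantPanel-class] used.
#' @slot params the [KineticParams-class] used.
#' @slot seed master integer seed of the run.
#'
#' @seealso [simulatePanel()], [writeDataset()], [readDataset()]
#' @exportClass ReporterDataset
setClass("ReporterDataset",
    slots = c(
        samples = "list",
        growthCurves = "data.frame",
        panel = "VariantPanel",
        params = "KineticParams",
        seed = "integer"
    )
)

setValidity("ReporterDataset", function(object) {
    if (!all(vapply(object@samples, is, logical(1), "TimepointSample")))
        return("samples must all be TimepointSample objects")
    need <- c("variant", "replicate", "time_min", "od600")
    if (nrow(object@growthCurves) > 0L &&
        !all(need %in% names(object@growthCurves)))
        return("growthCurves must have variant, replicate, time_min, od600")
    TRUE
})

#' Rectangular scatter gate for doublet exclusion
#'
#' Closed intervals on forward and side scatter used to exclude doublet
#' events before any summary statistic is computed.
#'
#' @slot fscBounds numeric(2), closed interval on forward scatter.
#' @slot sscBounds numeric(2), closed interval on side scatter.
#'
#' @seealso [gateSpec()], [percentileGate()], [gateSinglets()]
#' @exportClass GateSpec
setClass("GateSpec",
    slots = c(fscBounds = "numeric", sscBounds = "numeric"))

setValidity("GateSpec", function(object) {
    for (b in list(object@fscBounds, object@sscBounds)) {
        if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
            return("each bound must be a finite interval c(lower, upper), lower < upper")
    }
    TRUE
})

#' Windowed rate estimate for a fluorescence summary series
#'
#' The central population statistic: an ordinary least-squares slope of
#' a fluorescence summary over a time window, the mean of the series in
#' that window, and their quotient, the relative rate (1/min).
#'
#' @slot channel one of `"red"`, `"green"`, `"ratio"`.
#' @slot windowStart,windowEnd window bounds (min, closed interval).
#' @slot slope OLS slope (a.u./min).
#' @slot meanInWindow mean of the series inside the window (a.u.).
#' @slot relativeRate `slope / meanInWindow` (1/min).
#' @slot nPoints number of schedule points inside the window.
#'
#' @seealso [fitRate()], [rateTable()]
#' @exportClass RateEstimate
setClass("RateEstimate",
    slots = c(
        channel = "character",
        windowStart = "numeric",
        windowEnd = "numeric",
        slope = "numeric",
        meanInWindow = "numeric",
        relativeRate = "numeric",
        nPoints = "integer"
    )
)

setValidity("RateEstimate", function(object) {
    if (object@nPoints < 2L) return("a rate needs >= 2 in-window points")
    if (is.finite(object@meanInWindow) && object@meanInWindow != 0 &&
        abs(object@relativeRate - object@slope / object@meanInWindow) >
            1e-8 * max(1, abs(object@relativeRate)))
        return("relativeRate must equal slope / meanInWindow")
    TRUE
})

#' Per-event log-log regression of green on red fluorescence
#'
#' OLS fit of log10(green) on log10(red) across the single-cell events
#' of one sample. A slope of one with zero residual variance means the
#' green/red ratio is identical in every cell.
#'
#' @slot variant,replicate,timeMin sample identity.
#' @slot slope dimensionless log-log slope.
#' @slot intercept intercept in log10 a.u.
#' @slot nEvents number of events used (>= 3).
#'
#' @seealso [logLogSlope()]
#' @exportClass SlopeFit
setClass("SlopeFit",
    slots = c(
        variant = "character",
        replicate = "integer",
        timeMin = "numeric",
        slope = "numeric",
        intercept = "numeric",
        nEvents = "integer"
    )
)

setValidity("SlopeFit", function(object) {
    if (object@nEvents < 3L) return("nEvents must be >= 3")
    if (!is.finite(object@slope) || !is.finite(object@intercept))
        return("slope and intercept must be finite")
    TRUE
})

#' Sparsity-pruned variational Gaussian mixture over log fluorescence
#'
#' Result of a variational Bayesian Gaussian mixture fit in
#' (log10 red, log10 green) space with diagonal covariances and a
#' Dirichlet weight prior whose tiny concentration drives unused
#' components' weights toward zero.
#'
#' @slot weights posterior-mean mixture weights (simplex).
#' @slot means K x 2 matrix of component means (log10 a.u.).
#' @slot variances K x 2 matrix of diagonal variances.
#' @slot responsibilities n x K matrix; rows sum to one.
#' @slot elbo final evidence lower bound.
#' @slot elboTrace per-iteration ELBO of the winning restart.
#' @slot converged logical convergence flag.
#' @slot seed integer seed of the fit.
#' @slot nComponentsMax component cap (default 7).
#' @slot weightConcentrationPrior Dirichlet concentration (default 1e-6).
#'
#' @seealso [fitMixture()], [effectiveComponents()]
#' @exportClass MixtureFit
setClass("MixtureFit",
    slots = c(
        weights = "numeric",
        means = "matrix",
        variances = "matrix",
        responsibilities = "matrix",
        elbo = "numeric",
        elboTrace = "numeric",
        converged = "logical",
        seed = "integer",
        nComponentsMax = "integer",
        weightConcentrationPrior = "numeric"
    )
)

setValidity("MixtureFit", function(object) {
    if (abs(sum(object@weights) - 1) > 1e-9)
        return("weights must sum to 1 within 1e-9")
    if (any(object@variances <= 0))
        return("variances must be > 0")
    if (nrow(object@responsibilities) > 0L) {
        rs <- rowSums(object@responsibilities)
        if (any(abs(rs - 1) > 1e-9))
            return("responsibility rows must sum to 1 within 1e-9")
    }
    TRUE
})

#' Logistic growth fit with sampling-based uncertainty
#'
#' Point estimates of the logistic growth model
#' N(t) = K / (1 + (K/N0 - 1) exp(-r t)), posterior draws of
#' (N0, r, K) from residual bootstrap or MCMC, and the derived maximum
#' specific growth rate with its uncertainty.
#'
#' @slot n0 initial density (OD600).
#' @slot r intrinsic rate (1/min).
#' @slot kCap carrying capacity (OD600).
#' @slot posterior matrix of draws, columns `n0`, `r`, `k_cap`.
#' @slot muMax posterior mean of the maximum specific growth rate (1/min).
#' @slot muMaxSd posterior standard deviation of the maximum (1/min).
#' @slot method `"bootstrap"` or `"mcmc"`.
#' @slot seed integer seed used for the draws.
#' @slot data the fitted curve (columns `time_min`, `od600`).
#'
#' @seealso [fitLogistic()], [maxGrowthRate()], [dilutionBias()]
#' @exportClass GrowthFit
setClass("GrowthFit",
    slots = c(
        n0 = "numeric",
        r = "numeric",
        kCap = "numeric",
        posterior = "matrix",
        muMax = "numeric",
        muMaxSd = "numeric",
        method = "character",
        seed = "integer",
        data = "data.frame"
    )
)

setValidity("GrowthFit", function(object) {
    if (object@n0 <= 0 || object@r <= 0 || object@kCap <= 0)
        return("n0, r and kCap must be > 0")
    if (object@n0 >= object@kCap)
        return("n0 must be < kCap")
    if (length(object@muMaxSd) == 1L && is.finite(object@muMaxSd) &&
        object@muMaxSd < 0)
        return("muMaxSd must be >= 0")
    TRUE
})

#' Configuration of a full pipeline run
#'
#' Everything needed to reproduce a run: variant panel with Tm map,
#' kinetic parameters, gate, rate windows, mixture and growth settings,
#' master seed and output directory. Construct with [pipelineConfig()]
#' or read from YAML with [readPipelineConfig()]; check with
#' [validateConfig()].
#'
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    slots = c(
        panel = "VariantPanel",
        params = "KineticParams",
        gate = "ANY",
        windows = "list",
        nEvents = "integer",
        replicates = "integer",
        ratioMethod = "character",
        mixture = "list",
        growth = "list",
        seed = "integer",
        outDir = "character"
    )
)

#' Report of a pipeline run
#'
#' Manifest of produced tables, headline metrics, package version and a
#' config echo, returned by [runPipeline()].
#'
#' @slot manifest data.frame of produced files (`path`, `kind`, `md5`).
#' @slot metrics named list of headline metrics.
#' @slot version package version string.
#' @slot config the [PipelineConfig-class] that produced the run.
#'
#' @exportClass RunReport
setClass("RunReport",
    slots = c(
        manifest = "data.frame",
        metrics = "list",
        version = "character",
        config = "PipelineConfig"
    )
)
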