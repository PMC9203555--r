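#' Construct a pipeline configuration
#'
#' Bundles everything a full run needs; all defaults mirror the study
#' design (8-variant panel, 3 replicates, 3000 events per sample, the
#' standard schedule and windows).
#'
#' @param panel a [VariantPanel-class].
#' @param params a [KineticParams-class].
#' @param gate a [GateSpec-class] or `NULL` for per-sample percentile
#'   gating.
#' @param windows list of closed rate windows (min).
#' @param nEvents events per sample.
#' @param replicates replicates per variant.
#' @param ratioMethod `"per_event"` or `"ratio_of_means"`.
#' @param mixture list of mixture settings: `times` (timepoints to
#'   cluster), `nComponentsMax`, `weightConcentrationPrior`,
#'   `nRestarts`, `maxIter`, `tol`, `weightFloor`.
#' @param growth list of growth settings: `method`, `nDraws`.
#' @param seed master integer seed.
#' @param outDir output directory.
#'
#' @return A [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig(nEvents = 200, outDir = tempfile())
#' validateConfig(cfg)
#' @export
pipelineConfig <- function(panel = defaultVariantPanel(),
        params = kineticParams(), gate = NULL,
        windows = defaultWindows(), nEvents = 3000L, replicates = 3L,
        ratioMethod = "per_event",
        mixture = list(), growth = list(), seed = 1L,
        outDir = "chaperflow-run") {
    mixDefaults <- list(times = c(0, 90, 240), nComponentsMax = 7L,
        weightConcentrationPrior = 1e-6, nRestarts = 2L,
        maxIter = 500L, tol = 1e-5, weightFloor = 0.01)
    growDefaults <- list(method = "bootstrap", nDraws = 200L)
    mixture <- utils::modifyList(mixDefaults, mixture)
    growth <- utils::modifyList(growDefaults, growth)
    new("PipelineConfig", panel = panel, params = params, gate = gate,
        windows = windows, nEvents = as.integer(nEvents),
        replicates = as.integer(replicates), ratioMethod = ratioMethod,
        mixture = mixture, growth = growth, seed = as.integer(seed),
        outDir = outDir)
}

#' Validate a pipeline configuration
#'
#' Returns human-readable findings; an empty character vector means the
#' configuration satisfies every invariant (every variant has a Tm, the
#' seed is set, windows lie inside the schedule span and contain at
#' least two schedule points, counts are positive, kinetic parameters
#' pass their validity checks).
#'
#' @param config a [PipelineConfig-class].
#' @return character vector of findings (empty if valid).
#' @export
validateConfig <- function(config) {
    findings <- character()
    pn <- config@panel
    bad <- !is.finite(pn@tmCelsius)
    if (any(bad))
        findings <- c(findings, paste0(
            "variant without a finite melting temperature: ",
            paste(pn@name[bad], collapse = ", ")))
    v <- validObject(config@params, test = TRUE)
    if (is.character(v))
        findings <- c(findings, paste0("kinetic parameters: ", v))
    sched <- samplingSchedule()
    for (w in config@windows) {
        if (length(w) != 2L || !all(is.finite(w)) || w[2] <= w[1]) {
            findings <- c(findings, paste0("malformed window: ",
                paste(w, collapse = ", ")))
            next
        }
        if (w[1] < min(sched) || w[2] > max(sched))
            findings <- c(findings, sprintf(
                "window [%g, %g] outside the %g-%g min schedule span",
                w[1], w[2], min(sched), max(sched)))
        else if (sum(sched >= w[1] & sched <= w[2]) < 2L)
            findings <- c(findings, sprintf(
                "window [%g, %g] contains fewer than 2 schedule points",
                w[1], w[2]))
    }
    if (config@nEvents < 1L)
        findings <- c(findings, "nEvents must be >= 1")
    if (config@replicates < 1L)
        findings <- c(findings, "replicates must be >= 1")
    if (length(config@seed) != 1L || is.na(config@seed))
        findings <- c(findings, "master seed is not set")
    if (!is.null(config@gate)) {
        gv <- validObject(config@gate, test = TRUE)
        if (is.character(gv))
            findings <- c(findings, paste0("gate: ", gv))
    }
    if (!config@ratioMethod %in% c("per_event", "ratio_of_means"))
        findings <- c(findings,
            "ratioMethod must be per_event or ratio_of_means")
    findings
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value YAML with nested sections; unknown keys are an
#' error, missing keys take their defaults. Recognised top-level keys:
#' `variants` (name: Tm map), `wild_type`, `params`, `gate`
#' (`fsc`/`ssc` bounds), `windows`, `n_events`, `replicates`,
#' `ratio_method`, `mixture`, `growth`, `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path, call. = FALSE)
    cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
        stop("cannot parse config ", path, ": ",
            conditionMessage(e), call. = FALSE))
    known <- c("variants", "wild_type", "params", "gate", "windows",
        "n_events", "replicates", "ratio_method", "mixture", "growth",
        "seed", "out_dir")
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    args <- list()
    if (!is.null(cfg$variants)) {
        tm <- unlist(cfg$variants)
        args$panel <- variantPanel(names(tm), as.numeric(tm),
            wildType = names(tm) %in% (cfg$wild_type %||% character()))
    }
    if (!is.null(cfg$params))
        args$params <- do.call(kineticParams, cfg$params)
    if (!is.null(cfg$gate))
        args$gate <- gateSpec(as.numeric(cfg$gate$fsc),
            as.numeric(cfg$gate$ssc))
    if (!is.null(cfg$windows))
        args$windows <- lapply(cfg$windows, as.numeric)
    if (!is.null(cfg$n_events)) args$nEvents <- cfg$n_events
    if (!is.null(cfg$replicates)) args$replicates <- cfg$replicates
    if (!is.null(cfg$ratio_method)) args$ratioMethod <- cfg$ratio_method
    if (!is.null(cfg$mixture)) args$mixture <- cfg$mixture
    if (!is.null(cfg$growth)) args$growth <- cfg$growth
    if (!is.null(cfg$seed)) args$seed <- cfg$seed
    if (!is.null(cfg$out_dir)) args$outDir <- cfg$out_dir
    do.call(pipelineConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes generate -> summarize -> correlate -> cluster -> growth in
#' order, writing every stage's tables under `config@outDir` and
#' logging each stage with timestamps, seeds and event counts. A rerun
#' with identical config and seed reproduces byte-identical tables.
#' A stage failure aborts with the stage name; tables already written
#' are retained and listed in `partial_manifest.csv`.
#'
#' @param config a [PipelineConfig-class]; must pass
#'   [validateConfig()].
#' @param stages subset of
#'   `c("generate", "summarize", "correlate", "cluster", "growth")`
#'   whose outputs are written (upstream stages still execute in
#'   memory as needed).
#' @param quiet suppress progress messages.
#'
#' @return A [RunReport-class] with the manifest (paths and md5
#'   checksums), headline metrics (early green-vs-red rate rho, late
#'   green-rate-vs-Tm rho, ratio-vs-Tm rho at 120 min, per-variant
#'   maximum growth rates, effective component counts over time), the
#'   package version and a config echo.
#' @export
runPipeline <- function(config,
        stages = c("generate", "summarize", "correlate", "cluster",
            "growth"),
        quiet = FALSE) {
    stages <- match.arg(stages, several.ok = TRUE)
    findings <- validateConfig(config)
    if (length(findings))
        stop("invalid config:\n  - ", paste(findings, collapse = "\n  - "),
            call. = FALSE)
    outDir <- config@outDir
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir, call. = FALSE)
    logLine <- function(stage, msg) {
        if (!quiet) message(sprintf("[%s] %s: %s",
            format(Sys.time(), "%H:%M:%S"), stage, msg))
    }
    written <- list()
    emit <- function(tab, name, kind) {
        path <- file.path(outDir, name)
        readr::write_csv(as.data.frame(tab), path, progress = FALSE)
        written[[length(written) + 1L]] <<- data.frame(path = name,
            kind = kind, md5 = unname(tools::md5sum(path)))
    }
    runStage <- function(stage, expr) {
        logLine(stage, "start")
        tryCatch(expr, error = function(e) {
            partial <- if (length(written))
                do.call(rbind, written) else data.frame()
            if (nrow(partial))
                readr::write_csv(partial,
                    file.path(outDir, "partial_manifest.csv"),
                    progress = FALSE)
            stop(sprintf("pipeline stage '%s' failed: %s", stage,
                conditionMessage(e)), call. = FALSE)
        })
    }
    metrics <- list()

    ## -- generate ----------------------------------------------------
    ds <- runStage("generate", {
        d <- simulatePanel(config@panel, config@params,
            nCells = config@nEvents, replicates = config@replicates,
            seed = config@seed)
        if ("generate" %in% stages)
            writeDataset(d, file.path(outDir, "data"))
        logLine("generate", sprintf("%d samples x %d events",
            length(flowSamples(d)), config@nEvents))
        d
    })
    dataFiles <- if ("generate" %in% stages)
        list.files(file.path(outDir, "data")) else character()

    ## -- summarize ---------------------------------------------------
    summ <- NULL; rates <- NULL
    runStage("summarize", {
        summ <- summarizeSamples(ds, gate = config@gate,
            ratioMethod = config@ratioMethod)
        rates <- rateTable(summ, windows = config@windows)
        if ("summarize" %in% stages) {
            emit(summ, "summaries.csv", "summaries")
            emit(rates, "rates.csv", "rates")
        }
        logLine("summarize", sprintf("%d summaries, %d rate rows",
            nrow(summ), nrow(rates)))
    })

    ## -- correlate ---------------------------------------------------
    runStage("correlate", {
        tm <- tmMap(config@panel)
        tracks <- rbind(
            trackVsTm(summ, tm, "mean_red"),
            trackVsTm(summ, tm, "mean_green"),
            trackVsTm(summ, tm, "mean_ratio"))
        greenRates <- trackVsTm(rates, tm, "relative_rate", "green")
        redRates <- trackVsTm(rates, tm, "relative_rate", "red")
        gr <- rateVsRate(rates, rates, channelX = "green",
            channelY = "red")
        if ("correlate" %in% stages) {
            emit(tracks, "tracks_vs_tm.csv", "correlation")
            emit(rbind(greenRates, redRates), "rate_tracks_vs_tm.csv",
                "correlation")
            emit(gr, "green_vs_red_rates.csv", "correlation")
        }
        pick <- function(d, ws) d$rho[d$window_start == ws][1]
        metrics$rho_green_red_rate_0_30 <- pick(gr, 0)
        metrics$rho_green_rate_tm_0_30 <- pick(greenRates, 0)
        metrics$rho_green_rate_tm_150_180 <- pick(greenRates, 150)
        metrics$rho_ratio_tm_120min <-
            tracks$rho[tracks$x_descriptor == "mean_ratio" &
                tracks$at == 120][1]
        metrics$rho_red_tm_120min <-
            tracks$rho[tracks$x_descriptor == "mean_red" &
                tracks$at == 120][1]
        logLine("correlate", sprintf("%d track points",
            nrow(tracks) + nrow(greenRates) + nrow(redRates)))
    })

    ## -- cluster -----------------------------------------------------
    runStage("cluster", {
        keys <- unique(summ[, c("variant", "replicate")])
        reports <- list()
        for (i in seq_len(nrow(keys))) {
            vi <- match(keys$variant[i], config@panel@name)
            sel <- Filter(function(s)
                s@variant == keys$variant[i] &&
                s@replicate == keys$replicate[i] &&
                s@timeMin %in% config@mixture$times, flowSamples(ds))
            sel <- sel[order(vapply(sel, sampleTime, numeric(1)))]
            fits <- lapply(seq_along(sel), function(j) fitMixture(
                sel[[j]],
                nComponentsMax = config@mixture$nComponentsMax,
                weightConcentrationPrior =
                    config@mixture$weightConcentrationPrior,
                nRestarts = config@mixture$nRestarts,
                maxIter = config@mixture$maxIter,
                tol = config@mixture$tol,
                seed = deriveSeed(config@seed, vi,
                    keys$replicate[i], stage = 2L) + (j - 1L)))
            popRep <- subpopulationReport(fits,
                vapply(sel, sampleTime, numeric(1)),
                weightFloor = config@mixture$weightFloor)
            slopes <- lapply(sel, logLogSlope)
            reports[[i]] <- cbind(variant = keys$variant[i],
                replicate = keys$replicate[i], popRep,
                loglog_slope = vapply(slopes, function(s) s@slope,
                    numeric(1))[match(popRep$time_min,
                        vapply(sel, sampleTime, numeric(1)))])
        }
        popTable <- do.call(rbind, reports)
        if ("cluster" %in% stages)
            emit(popTable, "subpopulations.csv", "cluster")
        eff <- stats::aggregate(n_effective ~ time_min,
            data = unique(popTable[, c("variant", "replicate",
                "time_min", "n_effective")]), FUN = mean)
        metrics$effective_components_by_time <-
            stats::setNames(eff$n_effective, eff$time_min)
        logLine("cluster", sprintf("%d fits", nrow(keys) *
            length(config@mixture$times)))
    })

    ## -- growth ------------------------------------------------------
    runStage("growth", {
        gcs <- growthCurves(ds)
        keys <- unique(gcs[, c("variant", "replicate")])
        fits <- list(); rows <- list()
        for (i in seq_len(nrow(keys))) {
            vi <- match(keys$variant[i], config@panel@name)
            sub <- gcs[gcs$variant == keys$variant[i] &
                gcs$replicate == keys$replicate[i], ]
            f <- fitLogistic(sub[, c("time_min", "od600")],
                method = config@growth$method,
                nDraws = config@growth$nDraws,
                seed = deriveSeed(config@seed, vi, keys$replicate[i],
                    stage = 1L))
            fits[[i]] <- f
            rows[[i]] <- data.frame(variant = keys$variant[i],
                replicate = keys$replicate[i], n0 = f@n0, r = f@r,
                k_cap = f@kCap, mu_max = f@muMax,
                mu_max_sd = f@muMaxSd)
        }
        growthTab <- do.call(rbind, rows)
        earlyRef <- mean(rates$relative_rate[rates$channel == "red" &
            rates$window_start == 30 & rates$ok], na.rm = TRUE)
        spread <- rbind(
            dilutionSpread(fits, c(30, 60), referenceRate = earlyRef),
            dilutionSpread(fits, c(60, 90), referenceRate = earlyRef))
        if ("growth" %in% stages) {
            emit(growthTab, "growth_fits.csv", "growth")
            emit(spread, "dilution_spread.csv", "growth")
        }
        mu <- stats::aggregate(mu_max ~ variant, data = growthTab,
            FUN = mean)
        metrics$mu_max_by_variant <- stats::setNames(mu$mu_max,
            mu$variant)
        logLine("growth", sprintf("%d fits", nrow(keys)))
    })

    manifest <- if (length(written)) do.call(rbind, written) else
        data.frame(path = character(), kind = character(),
            md5 = character())
    if (length(dataFiles))
        manifest <- rbind(data.frame(path = file.path("data", dataFiles),
            kind = "events",
            md5 = unname(tools::md5sum(file.path(outDir, "data",
                dataFiles)))), manifest)
    report <- new("RunReport", manifest = manifest, metrics = metrics,
        version = as.character(utils::packageVersion("chaperFlow")),
        config = config)
    configEcho <- list(seed = config@seed, n_events = config@nEvents,
        replicates = config@replicates,
        ratio_method = config@ratioMethod,
        windows = lapply(config@windows, as.numeric),
        variants = as.list(tmMap(config@panel)),
        mixture = config@mixture, growth = config@growth,
        parameters = paramsAsList(config@params))
    yaml::write_yaml(configEcho, file.path(outDir, "config_echo.yaml"),
        precision = 17L)
    report
}
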