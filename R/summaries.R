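#' Construct a scatter gate
#'
#' @param fscBounds,sscBounds closed intervals `c(lower, upper)` in
#'   arbitrary units, lower < upper.
#' @return A [GateSpec-class].
#' @examples
#' gateSpec(c(1e4, 2e5), c(1e3, 5e4))
#' @export
gateSpec <- function(fscBounds, sscBounds) {
    new("GateSpec", fscBounds = as.numeric(fscBounds),
        sscBounds = as.numeric(sscBounds))
}

#' Permissive percentile gate for a sample
#'
#' The default doublet gate when none is supplied: a rectangle at the
#' 1st-99th percentile of each scatter channel of the sample itself.
#'
#' @param sample a [TimepointSample-class].
#' @param probs lower/upper percentile pair.
#' @return A [GateSpec-class].
#' @export
percentileGate <- function(sample, probs = c(0.01, 0.99)) {
    ev <- flowEvents(sample)
    gateSpec(stats::quantile(ev$fsc, probs, names = FALSE, type = 7),
        stats::quantile(ev$ssc, probs, names = FALSE, type = 7))
}

#' Exclude doublets by a rectangular scatter gate
#'
#' Retains exactly the events whose forward and side scatter fall
#' inside the closed gate bounds. The input sample is never modified;
#' removing every event raises a warning (downstream means would be
#' undefined).
#'
#' @param sample a [TimepointSample-class].
#' @param gate a [GateSpec-class], or `NULL` for the per-sample
#'   [percentileGate()].
#' @return The gated [TimepointSample-class].
#' @examples
#' s <- timepointSample("wt", 1, 0, data.frame(
#'     fsc = c(1, 2, 3), ssc = c(1, 2, 3), red = 1:3, green = 1:3))
#' nEvents(gateSinglets(s, gateSpec(c(1.5, 3.5), c(0, 10))))
#' @export
gateSinglets <- function(sample, gate = NULL) {
    stopifnot(is(sample, "TimepointSample"))
    if (is.null(gate)) gate <- percentileGate(sample)
    stopifnot(is(gate, "GateSpec"))
    ev <- sample@events
    keep <- ev$fsc >= gate@fscBounds[1] & ev$fsc <= gate@fscBounds[2] &
        ev$ssc >= gate@sscBounds[1] & ev$ssc <= gate@sscBounds[2]
    if (!any(keep))
        warning(sprintf("gate removed all events (%s rep %d, t = %g min)",
            sample@variant, sample@replicate, sample@timeMin),
            call. = FALSE)
    out <- sample
    out@events <- ev[keep, , drop = FALSE]
    rownames(out@events) <- NULL
    out
}

#' Per-timepoint summary means over gated events
#'
#' Gates every sample, then computes plain arithmetic means of the
#' absolute per-event intensities: mean red, mean green, mean
#' green/red ratio, mean forward and side scatter. The ratio is by
#' default the mean of per-event `green/red` ratios, which cancels
#' plasmid copy number cell by cell; `ratioMethod = "ratio_of_means"`
#' switches to `mean(green)/mean(red)`.
#'
#' @param samples a list of [TimepointSample-class] or a
#'   [ReporterDataset-class].
#' @param gate a [GateSpec-class] applied to every sample, or `NULL`
#'   (default) for the per-sample percentile gate.
#' @param ratioMethod `"per_event"` (default) or `"ratio_of_means"`.
#'
#' @return data.frame with one row per sample: `variant`, `replicate`,
#'   `time_min`, `n_events`, `mean_red`, `mean_green`, `mean_ratio`,
#'   `mean_fsc`, `mean_ssc`.
#' @examples
#' s <- timepointSample("wt", 1, 0, data.frame(
#'     fsc = c(1, 1), ssc = c(1, 1), red = c(1, 3), green = c(2, 6)))
#' summarizeSamples(list(s), gate = gateSpec(c(0, 2), c(0, 2)))
#' @export
summarizeSamples <- function(samples, gate = NULL,
        ratioMethod = c("per_event", "ratio_of_means")) {
    ratioMethod <- match.arg(ratioMethod)
    if (is(samples, "ReporterDataset")) samples <- flowSamples(samples)
    rows <- lapply(samples, function(s) {
        g <- gateSinglets(s, gate)
        ev <- flowEvents(g)
        if (nrow(ev) == 0L)
            stop(sprintf(
                "no gated events for %s rep %d at t = %g min: means undefined",
                s@variant, s@replicate, s@timeMin), call. = FALSE)
        ratio <- if (ratioMethod == "per_event")
            mean(ev$green / ev$red) else mean(ev$green) / mean(ev$red)
        data.frame(variant = s@variant, replicate = s@replicate,
            time_min = s@timeMin, n_events = nrow(ev),
            mean_red = mean(ev$red), mean_green = mean(ev$green),
            mean_ratio = ratio, mean_fsc = mean(ev$fsc),
            mean_ssc = mean(ev$ssc))
    })
    out <- do.call(rbind, rows)
    out[order(out$variant, out$replicate, out$time_min), , drop = FALSE]
}

## Closed-form OLS slope; own normal equations (trivial, kept explicit
## so the rate statistic has no model-fitting dependency).
olsSlope <- function(x, y) {
    xc <- x - mean(x)
    sum(xc * (y - mean(y))) / sum(xc * xc)
}

#' Windowed rate and relative rate of a summary series
#'
#' Fits an ordinary least-squares trendline to the points of a summary
#' series that fall inside a closed time window; the relative rate is
#' the slope divided by the mean of the series in the same window.
#'
#' @param times schedule times (min).
#' @param values summary values at those times (a.u.).
#' @param window closed interval `c(start, end)` (min).
#' @param channel label carried into the result.
#'
#' @return A [RateEstimate-class].
#' @examples
#' fitRate(c(0, 10, 20, 30), c(1, 2, 3, 4), c(0, 30))
#' @export
fitRate <- function(times, values, window, channel = "red") {
    stopifnot(length(times) == length(values), length(window) == 2L)
    stopIfNotFinite(c(times, values), "times and values")
    inw <- times >= window[1] & times <= window[2]
    if (sum(inw) < 2L)
        stop(sprintf("window [%g, %g] contains %d point(s); >= 2 required",
            window[1], window[2], sum(inw)), call. = FALSE)
    t <- times[inw]; v <- values[inw]
    slope <- olsSlope(t, v)
    m <- mean(v)
    if (m == 0)
        stop("mean in window is zero: relative rate undefined",
            call. = FALSE)
    new("RateEstimate", channel = channel, windowStart = window[1],
        windowEnd = window[2], slope = slope, meanInWindow = m,
        relativeRate = slope / m, nPoints = as.integer(sum(inw)))
}

#' Rate table over variants, replicates, channels and windows
#'
#' Applies [fitRate()] to each variant/replicate summary series for
#' each requested channel and window. Window/series combinations with
#' fewer than two schedule points yield an explicit row with `ok =
#' FALSE` and `NA` estimates rather than being silently dropped.
#'
#' @param summaries output of [summarizeSamples()].
#' @param windows list of closed windows (default [defaultWindows()]).
#' @param channels subset of `c("red", "green", "ratio")`.
#'
#' @return data.frame with columns `variant`, `replicate`, `channel`,
#'   `window_start`, `window_end`, `slope`, `mean_in_window`,
#'   `relative_rate`, `n_points`, `ok`.
#' @export
rateTable <- function(summaries, windows = defaultWindows(),
        channels = c("red", "green", "ratio")) {
    known <- c(red = "mean_red", green = "mean_green",
        ratio = "mean_ratio")
    if (!all(channels %in% names(known)))
        stop("unknown channel(s): ",
            paste(setdiff(channels, names(known)), collapse = ", "),
            call. = FALSE)
    keys <- unique(summaries[, c("variant", "replicate")])
    rows <- list()
    for (i in seq_len(nrow(keys))) {
        sub <- summaries[summaries$variant == keys$variant[i] &
            summaries$replicate == keys$replicate[i], ]
        sub <- sub[order(sub$time_min), ]
        for (ch in channels) {
            for (w in windows) {
                est <- tryCatch(
                    fitRate(sub$time_min, sub[[known[[ch]]]], w, ch),
                    error = function(e) NULL)
                rows[[length(rows) + 1L]] <- data.frame(
                    variant = keys$variant[i],
                    replicate = keys$replicate[i], channel = ch,
                    window_start = w[1], window_end = w[2],
                    slope = if (is.null(est)) NA_real_ else est@slope,
                    mean_in_window = if (is.null(est)) NA_real_ else
                        est@meanInWindow,
                    relative_rate = if (is.null(est)) NA_real_ else
                        est@relativeRate,
                    n_points = if (is.null(est)) sum(sub$time_min >=
                        w[1] & sub$time_min <= w[2]) else est@nPoints,
                    ok = !is.null(est))
            }
        }
    }
    do.call(rbind, rows)
}
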