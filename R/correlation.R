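## Mid-ranks (average ranks for ties), computed from scratch by
## sorting. The Spearman statistic below is deliberately implemented
## from first principles; library rank correlation serves only as an
## independent cross-check in the test suite.
midRanks <- function(x) {
    n <- length(x)
    o <- order(x)
    r <- numeric(n)
    i <- 1L
    while (i <= n) {
        j <- i
        while (j < n && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
        r[o[i:j]] <- (i + j) / 2
        i <- j + 1L
    }
    r
}

#' Spearman rank correlation with mid-rank ties
#'
#' The Pearson correlation of mid-ranks (tied observations receive the
#' average of the ranks they span). Exact +/-1 under any strictly
#' monotone relation; invariant under strictly monotone transforms of
#' either input.
#'
#' @param x,y numeric vectors of equal length >= 3, finite entries.
#'
#' @return rho in [-1, 1]. Zero rank variance in either vector (all
#'   entries tied) is an error, never a silent `NaN`.
#' @examples
#' spearmanRho(1:3, c(10, 20, 30))   #  1
#' spearmanRho(1:3, c(30, 20, 10))   # -1
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length", call. = FALSE)
    if (length(x) < 3L)
        stop("need at least 3 paired observations", call. = FALSE)
    stopIfNotFinite(c(x, y), "correlation inputs")
    rx <- midRanks(x); ry <- midRanks(y)
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    vx <- sum(dx * dx); vy <- sum(dy * dy)
    if (vx == 0 || vy == 0)
        stop("undefined correlation: zero rank variance", call. = FALSE)
    sum(dx * dy) / sqrt(vx * vy)
}

#' Exact permutation p-value for Spearman rho
#'
#' Two-sided exact permutation test (all n! pairings) for small
#' samples; provided as an optional add-on, no p-values are attached to
#' correlation tracks by default.
#'
#' @param x,y numeric vectors, length n <= 10.
#' @return two-sided exact p-value.
#' @export
spearmanExactP <- function(x, y) {
    n <- length(x)
    if (n > 10L)
        stop("exact permutation p is limited to n <= 10", call. = FALSE)
    obs <- abs(spearmanRho(x, y))
    perms <- permuteAll(n)
    stat <- apply(perms, 1L, function(p) abs(spearmanRho(x, y[p])))
    mean(stat >= obs - 1e-12)
}

permuteAll <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- permuteAll(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, sub + (sub >= i))))
}

#' Correlation track of a readout against variant melting temperature
#'
#' At each timepoint (for per-timepoint summaries) or window (for rate
#' tables), computes Spearman rho across all variant x replicate
#' points, pairing each point's readout with its variant's Tm — the
#' replicate-resolved convention (default 8 x 3 = 24 points), not
#' per-variant means. Timepoints where the readout has zero rank
#' variance yield `NA` with a warning.
#'
#' @param x a summary data.frame from [summarizeSamples()] (use
#'   `readout` `"mean_red"`, `"mean_green"` or `"mean_ratio"`) or a
#'   rate table from [rateTable()] (use `readout` `"relative_rate"` or
#'   `"slope"` together with `channel`).
#' @param tmMap named numeric vector mapping every variant to its Tm.
#' @param readout column of `x` to correlate.
#' @param channel for rate tables, which channel to track.
#'
#' @return data.frame (one row per time or window): descriptors, `at`
#'   (time, or window midpoint), `window_start`/`window_end` for rate
#'   input, `rho` and `n_points`.
#' @export
trackVsTm <- function(x, tmMap, readout = "mean_red", channel = NULL) {
    if (!readout %in% names(x))
        stop("readout column not found: ", readout, call. = FALSE)
    missing <- setdiff(unique(x$variant), names(tmMap))
    if (length(missing))
        stop("no melting temperature for variant(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
    isRates <- "window_start" %in% names(x)
    if (isRates) {
        if (!is.null(channel)) x <- x[x$channel == channel, ]
        x <- x[x$ok, ]
        grp <- interaction(x$window_start, x$window_end, drop = TRUE)
    } else {
        grp <- factor(x$time_min)
    }
    rows <- lapply(levels(grp), function(g) {
        sub <- x[grp == g, ]
        rho <- tryCatch(
            spearmanRho(tmMap[sub$variant], sub[[readout]]),
            error = function(e) {
                warning(sprintf("at %s: %s", g, conditionMessage(e)),
                    call. = FALSE)
                NA_real_
            })
        base <- data.frame(
            x_descriptor = paste0(readout,
                if (!is.null(channel)) paste0("[", channel, "]") else ""),
            y_descriptor = "tm_celsius", rho = rho,
            n_points = nrow(sub))
        if (isRates)
            cbind(base, window_start = sub$window_start[1],
                window_end = sub$window_end[1],
                at = (sub$window_start[1] + sub$window_end[1]) / 2)
        else cbind(base, at = sub$time_min[1])
    })
    out <- do.call(rbind, rows)
    out[order(out$at), , drop = FALSE]
}

#' Window-wise correlation between two rate collections
#'
#' Spearman rho between two rate tables (for example the relative rate
#' of green versus red fluorescence), matched on variant, replicate
#' and window. Unmatched variant/replicate keys are an error listing
#' the offenders.
#'
#' @param ratesX,ratesY rate tables from [rateTable()], each filtered
#'   to a single channel (or pass `channelX`/`channelY`).
#' @param channelX,channelY optional channel filters.
#' @param readout column to correlate (default `"relative_rate"`).
#'
#' @return data.frame: one row per window with `rho` and `n_points`.
#' @export
rateVsRate <- function(ratesX, ratesY, channelX = NULL, channelY = NULL,
        readout = "relative_rate") {
    if (!is.null(channelX)) ratesX <- ratesX[ratesX$channel == channelX, ]
    if (!is.null(channelY)) ratesY <- ratesY[ratesY$channel == channelY, ]
    ratesX <- ratesX[ratesX$ok, ]; ratesY <- ratesY[ratesY$ok, ]
    keyOf <- function(d) paste(d$variant, d$replicate, d$window_start,
        d$window_end, sep = "|")
    kx <- keyOf(ratesX); ky <- keyOf(ratesY)
    un <- c(setdiff(kx, ky), setdiff(ky, kx))
    if (length(un))
        stop("unmatched variant/replicate/window keys: ",
            paste(unique(un), collapse = "; "), call. = FALSE)
    m <- match(kx, ky)
    wgrp <- interaction(ratesX$window_start, ratesX$window_end,
        drop = TRUE)
    rows <- lapply(levels(wgrp), function(g) {
        sel <- wgrp == g
        data.frame(
            x_descriptor = paste0(readout, "[",
                ratesX$channel[sel][1], "]"),
            y_descriptor = paste0(readout, "[",
                ratesY$channel[m[sel]][1], "]"),
            window_start = ratesX$window_start[sel][1],
            window_end = ratesX$window_end[sel][1],
            rho = spearmanRho(ratesX[[readout]][sel],
                ratesY[[readout]][m[sel]]),
            n_points = sum(sel))
    })
    do.call(rbind, rows)
}
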