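## Internal helpers shared across modules.

## Gas constant, kcal / (mol K).
.RGAS <- 1.987e-3

#' Flow-cytometry sampling schedule
#'
#' The default sampling schedule in minutes after induction: time 0
#' (just before induction), 2 min, every 5 min up to 30 min, every
#' 10 min up to 120 min, then every 30 min up to 240 min — 21
#' timepoints in total.
#'
#' @return Numeric vector of 21 times (min).
#' @examples
#' samplingSchedule()
#' @export
samplingSchedule <- function() {
    c(0, 2, seq(5, 30, by = 5), seq(40, 120, by = 10),
      seq(150, 240, by = 30))
}

#' Default rate windows
#'
#' The closed time windows (min) over which rates are estimated by
#' default: 0-30 (initial), 30-60 (early), 60-90 (late), 150-180 and
#' 180-210 (homeostasis). Boundary schedule points belong to both
#' adjacent windows.
#'
#' @return List of numeric length-2 vectors.
#' @examples
#' defaultWindows()
#' @export
defaultWindows <- function() {
    list(c(0, 30), c(30, 60), c(60, 90), c(150, 180), c(180, 210))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic per-(variant, replicate, stage) sub-seed derived from
## a master seed; offsets are fixed so replicates and pipeline stages
## get independent but reproducible streams. Kept below 2^31.
deriveSeed <- function(master, variantIdx, replicate, stage = 0L) {
    (as.integer(master) %% 100000L) * 20000L +
        (as.integer(variantIdx) %% 100L) * 1000L +
        (as.integer(replicate) %% 100L) * 10L + as.integer(stage)
}

## Lognormal with mean 1 and coefficient of variation cv.
rlnormCv <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

stopIfNotFinite <- function(x, what) {
    if (any(!is.finite(x)))
        stop(sprintf("%s must be finite", what), call. = FALSE)
    invisible(x)
}
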