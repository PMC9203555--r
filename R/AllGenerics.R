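#' @name chaperFlow-accessors
#' @title Accessors for chaperFlow classes
#' @description Small accessor generics used across the package instead
#'   of direct slot access.
#' @param x an object of the documented class.
#' @param object an object of the documented class.
#' @return The documented component.
NULL

#' @rdname chaperFlow-accessors
#' @export
setGeneric("variantNames", function(x) standardGeneric("variantNames"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("tmMap", function(x) standardGeneric("tmMap"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("flowEvents", function(x) standardGeneric("flowEvents"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("sampleTime", function(x) standardGeneric("sampleTime"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("flowSamples", function(x) standardGeneric("flowSamples"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("growthCurves", function(x) standardGeneric("growthCurves"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("variantPanelOf", function(x) standardGeneric("variantPanelOf"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("kineticParamsOf", function(x) standardGeneric("kineticParamsOf"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("mixtureMeans", function(x) standardGeneric("mixtureMeans"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("relativeRate", function(x) standardGeneric("relativeRate"))

#' @rdname chaperFlow-accessors
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

setMethod("variantNames", "VariantPanel", function(x) x@name)
setMethod("length", "VariantPanel", function(x) length(x@name))
setMethod("tmMap", "VariantPanel",
    function(x) stats::setNames(x@tmCelsius, x@name))
setMethod("variantNames", "ReporterDataset",
    function(x) variantNames(x@panel))
setMethod("tmMap", "ReporterDataset", function(x) tmMap(x@panel))

setMethod("flowEvents", "TimepointSample", function(x) x@events)
setMethod("nEvents", "TimepointSample", function(x) nrow(x@events))
setMethod("sampleTime", "TimepointSample", function(x) x@timeMin)

setMethod("flowSamples", "ReporterDataset", function(x) x@samples)
setMethod("growthCurves", "ReporterDataset", function(x) x@growthCurves)
setMethod("variantPanelOf", "ReporterDataset", function(x) x@panel)
setMethod("kineticParamsOf", "ReporterDataset", function(x) x@params)

setMethod("mixtureWeights", "MixtureFit", function(x) x@weights)
setMethod("mixtureMeans", "MixtureFit", function(x) x@means)

setMethod("relativeRate", "RateEstimate", function(x) x@relativeRate)

setMethod("posteriorDraws", "GrowthFit", function(x) x@posterior)

setMethod("show", "VariantPanel", function(object) {
    cat("VariantPanel with", length(object@name), "variants\n")
    wt <- ifelse(object@wildType, " (wt)", "")
    cat(sprintf("  %-6s Tm = %5.1f C%s\n", object@name, object@tmCelsius, wt),
        sep = "")
})

setMethod("show", "TimepointSample", function(object) {
    cat(sprintf("TimepointSample %s rep %d at t = %g min: %d events\n",
        object@variant, object@replicate, object@timeMin,
        nrow(object@events)))
})

setMethod("show", "ReporterDataset", function(object) {
    tt <- sort(unique(vapply(object@samples, sampleTime, numeric(1))))
    cat("ReporterDataset:", length(object@samples), "samples,",
        length(object@panel@name), "variants,",
        length(tt), "timepoints, seed", object@seed, "\n")
})

setMethod("show", "RateEstimate", function(object) {
    cat(sprintf(
        "RateEstimate [%s, %g-%g min]: slope %.4g, mean %.4g, relative %.4g /min (n = %d)\n",
        object@channel, object@windowStart, object@windowEnd,
        object@slope, object@meanInWindow, object@relativeRate,
        object@nPoints))
})

setMethod("show", "SlopeFit", function(object) {
    cat(sprintf(
        "SlopeFit %s rep %d t = %g min: slope %.3f, intercept %.3f (n = %d)\n",
        object@variant, object@replicate, object@timeMin, object@slope,
        object@intercept, object@nEvents))
})

setMethod("show", "MixtureFit", function(object) {
    k <- sum(object@weights >= 0.01)
    cat(sprintf(
        "MixtureFit: %d/%d effective components (floor 0.01), ELBO %.2f, %s\n",
        k, length(object@weights), object@elbo,
        if (object@converged) "converged" else "NOT converged"))
    cat("  weights:", paste(sprintf("%.3f", sort(object@weights,
        decreasing = TRUE)), collapse = " "), "\n")
})

setMethod("show", "GrowthFit", function(object) {
    cat(sprintf(
        "GrowthFit (logistic): n0 %.4g, r %.4g /min, K %.4g; mu_max %.4g +/- %.4g /min [%s, %d draws]\n",
        object@n0, object@r, object@kCap, object@muMax, object@muMaxSd,
        object@method, nrow(object@posterior)))
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig:", length(object@panel@name), "variants x",
        object@replicates, "replicates,", object@nEvents,
        "events/sample, seed", object@seed, "\n")
    cat("  windows:", paste(vapply(object@windows,
        function(w) sprintf("%g-%g", w[1], w[2]), character(1)),
        collapse = ", "), "min\n")
    cat("  output:", object@outDir, "\n")
})

setMethod("show", "RunReport", function(object) {
    cat("RunReport (chaperFlow", object@version, ")\n")
    cat("  tables:", nrow(object@manifest), "\n")
    for (nm in names(object@metrics)) {
        v <- object@metrics[[nm]]
        if (is.numeric(v) && length(v) == 1L)
            cat(sprintf("  %s: %.4g\n", nm, v))
    }
})
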