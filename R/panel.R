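#' Construct a variant panel
#'
#' @param name character vector of distinct variant names.
#' @param tmCelsius numeric vector of melting temperatures (degrees C).
#' @param wildType logical vector flagging the wild-type construct;
#'   defaults to all `FALSE`.
#' @param description optional free-text descriptions.
#'
#' @return A [VariantPanel-class].
#' @examples
#' variantPanel(c("A", "B"), c(40, 55), wildType = c(FALSE, TRUE))
#' @export
variantPanel <- function(name, tmCelsius, wildType = rep(FALSE, length(name)),
        description = rep("", length(name))) {
    new("VariantPanel", name = as.character(name),
        tmCelsius = as.numeric(tmCelsius),
        wildType = as.logical(wildType),
        description = as.character(description))
}

#' Default eight-variant lambda-repressor panel
#'
#' Eight variants of the lambda-repressor construct N102LT spanning
#' melting temperatures from below 10 to 61 degrees C, with the wild
#' type at Tm = 55 degrees C. Only the wild-type Tm is an experimental
#' literature value; the mutant Tm values are synthetic configuration
#' values consistent with the published qualitative ordering and range,
#' chosen once for the simulated panel.
#'
#' @return A [VariantPanel-class] with 8 variants.
#' @examples
#' defaultVariantPanel()
#' @export
defaultVariantPanel <- function() {
    variantPanel(
        name = c("L57G", "L57C", "L57P", "M40A", "wt", "Q33S", "Q33Y",
            "V36I"),
        tmCelsius = c(8, 25, 35, 45, 55, 55, 58, 61),
        wildType = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
            FALSE),
        description = c(
            "core L57 -> Gly, strongly destabilised",
            "core L57 -> Cys, destabilised",
            "core L57 -> Pro, destabilised",
            "core M40 -> Ala, mildly destabilised",
            "wild-type N102LT",
            "surface Q33 -> Ser, wt-like stability",
            "surface Q33 -> Tyr, stabilised",
            "core V36 -> Ile, most stable"))
}

#' @rdname chaperFlow-accessors
#' @export
#' @aliases as.data.frame,VariantPanel-method
setMethod("as.data.frame", "VariantPanel", function(x, ...) {
    data.frame(name = x@name, tm_celsius = x@tmCelsius,
        wild_type = x@wildType, description = x@description,
        stringsAsFactors = FALSE)
})
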