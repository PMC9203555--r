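#' Construct kinetic parameters for the reporter model
#'
#' Defaults describe the study conditions the generator emulates:
#' growth at 37 degrees C, strong IPTG-induced expression of a
#' plasmid-borne RFP fusion, DnaK-promoter sfGFP with fast maturation
#' (t50 = 14 min) against slow tagRFP maturation (t50 = 42 min),
#' stability-dependent degradation of the client, a uniform dark-state
#' aggregation loss, and multiplicative flow-cytometer measurement
#' noise.
#'
#' The DnaK-promoter activity is the two-term linear model
#' `A(t) = alphaTranslation * synthesis(t) + betaUnfolded * U(t)`,
#' where `U(t)` is the equilibrium unfolded pool
#' `f_u * (poi_immature + poi_mature)`; see [fractionUnfolded()].
#'
#' @param copyNumberLogMean,copyNumberLogSd lognormal plasmid copy
#'   number distribution (dimensionless); defaults give a median of
#'   about 20 copies with ~25% cell-to-cell spread.
#' @param kSyn client synthesis rate per plasmid copy (a.u./min).
#' @param leakFraction pre-induction synthesis fraction in [0, 1).
#' @param stabilitySlope kcal/mol/degC; the unfolding free energy is
#'   `stabilitySlope * (Tm - T)`.
#' @param growthTempCelsius culture temperature (degrees C).
#' @param kDegBasal basal degradation rate (1/min).
#' @param kDegUnfolded extra degradation applied in proportion to the
#'   unfolded fraction (1/min).
#' @param kAgg variant-independent first-order aggregation into the
#'   dark (non-fluorescent) pool (1/min).
#' @param alphaTranslation DnaK-promoter activity per unit client
#'   synthesis rate (dimensionless).
#' @param betaUnfolded DnaK-promoter activity per unit unfolded protein
#'   (1/min per a.u.).
#' @param t50RedMin,t50GreenMin fluorophore maturation half-times (min);
#'   first-order maturation with rate `ln(2)/t50`.
#' @param noiseCv multiplicative measurement noise CV (dimensionless).
#' @param backgroundRed,backgroundGreen autofluorescence floors (a.u.).
#' @param gainRed,gainGreen detector gains (a.u. per protein a.u.).
#' @param replicateEffectSd lognormal sd of the per-replicate synthesis
#'   multiplier (day-to-day induction variability).
#' @param preInductionMin burn-in length before induction during which
#'   synthesis runs at `leakFraction` (min).
#' @param fscLogMean,fscLogSd,sscLogMean,sscLogSd stationary lognormal
#'   scatter channels (carried for gating only).
#' @param growthN0,growthRate,growthK logistic growth model: initial
#'   OD600, intrinsic rate (1/min) and carrying capacity.
#' @param growthReplicateSd lognormal sd of the per-replicate growth
#'   rate jitter.
#' @param growthTmCoupling fractional modulation of the growth rate per
#'   degree C of variant Tm relative to 55 C (0 = variant-independent
#'   growth, the default).
#' @param odNoiseCv multiplicative OD600 measurement noise CV.
#' @param toxicityEnabled if `TRUE`, synthesis switches off permanently
#'   in any cell whose soluble client pool exceeds `toxicityThreshold`.
#' @param toxicityThreshold protein threshold for the toxicity switch
#'   (a.u.).
#' @param rngSeed default integer seed.
#'
#' @return A validated [KineticParams-class].
#' @examples
#' p <- kineticParams()
#' p <- kineticParams(noiseCv = 0, toxicityEnabled = TRUE)
#' @export
kineticParams <- function(
        copyNumberLogMean = log(20),
        copyNumberLogSd = 0.25,
        kSyn = 1,
        leakFraction = 0.02,
        stabilitySlope = 0.25,
        growthTempCelsius = 37,
        kDegBasal = 0.002,
        kDegUnfolded = 0.008,
        kAgg = 0.003,
        alphaTranslation = 0.2,
        betaUnfolded = 0.004,
        t50RedMin = 42,
        t50GreenMin = 14,
        noiseCv = 0.15,
        backgroundRed = 80,
        backgroundGreen = 40,
        gainRed = 1,
        gainGreen = 1,
        replicateEffectSd = 0.5,
        preInductionMin = 120,
        fscLogMean = log(5e4),
        fscLogSd = 0.2,
        sscLogMean = log(1e4),
        sscLogSd = 0.25,
        growthN0 = 0.5,
        growthRate = 0.023,
        growthK = 2.5,
        growthReplicateSd = 0.02,
        growthTmCoupling = 0,
        odNoiseCv = 0.01,
        toxicityEnabled = FALSE,
        toxicityThreshold = 5e4,
        rngSeed = 1L) {
    new("KineticParams",
        copyNumberLogMean = copyNumberLogMean,
        copyNumberLogSd = copyNumberLogSd,
        kSyn = kSyn,
        leakFraction = leakFraction,
        stabilitySlope = stabilitySlope,
        growthTempCelsius = growthTempCelsius,
        kDegBasal = kDegBasal,
        kDegUnfolded = kDegUnfolded,
        kAgg = kAgg,
        alphaTranslation = alphaTranslation,
        betaUnfolded = betaUnfolded,
        t50RedMin = t50RedMin,
        t50GreenMin = t50GreenMin,
        noiseCv = noiseCv,
        backgroundRed = backgroundRed,
        backgroundGreen = backgroundGreen,
        gainRed = gainRed,
        gainGreen = gainGreen,
        replicateEffectSd = replicateEffectSd,
        preInductionMin = preInductionMin,
        fscLogMean = fscLogMean,
        fscLogSd = fscLogSd,
        sscLogMean = sscLogMean,
        sscLogSd = sscLogSd,
        growthN0 = growthN0,
        growthRate = growthRate,
        growthK = growthK,
        growthReplicateSd = growthReplicateSd,
        growthTmCoupling = growthTmCoupling,
        odNoiseCv = odNoiseCv,
        toxicityEnabled = toxicityEnabled,
        toxicityThreshold = toxicityThreshold,
        rngSeed = as.integer(rngSeed))
}

## Named list view used by the dataset manifest and the config echo.
paramsAsList <- function(p) {
    nm <- slotNames("KineticParams")
    out <- lapply(nm, function(s) slot(p, s))
    names(out) <- nm
    out
}

## Rebuild a KineticParams from the manifest list view.
paramsFromList <- function(x) {
    do.call(kineticParams, x[names(x) %in% names(formals(kineticParams))])
}
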