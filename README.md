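# chaperFlow

Simulation and analysis of dual fluorescent-reporter flow cytometry
time series for protein quality control studies in *E. coli*.

## The problem

When a recombinant protein is overexpressed, the DnaK (Hsp70)
chaperone system responds — but to *what*? The rate at which the
protein is being translated, or the amount of unfolded protein its
(in)stability leaves at folding equilibrium? A dual-reporter plasmid
separates the two: a slow-maturing tagRFP fusion reports client
abundance (red channel) and DnaK-promoter sfGFP reports heat-shock
transcription (green channel), measured by flow cytometry over four
hours after induction for a panel of client variants whose melting
temperatures Tm span ~8–61 °C.

chaperFlow is for computational biologists who want to analyse such
panels — or to prototype the analysis on faithful synthetic data
before any cytometer time is spent.

## The model and statistics at its core

Each cell is a linear ODE with states (R_i, R_m, D, G_i, G_m):
immature/mature client-RFP, a dark aggregated pool, immature/mature
GFP. Synthesis is k_syn·c per cell (plasmid copy number c); both
fluorophores mature first-order with rate ln2/t50 (42 min red, 14 min
green); the client is degraded at k_deg = k_basal + k_unf·f_u, where
f_u = 1/(1 + exp(s(Tm−T)/RT)) is the two-state unfolded fraction;
everything is diluted by the logistic culture growth rate
μ(t) = r(1 − N/K). The DnaK promoter activity is the two-term model

    A(t) = α·(synthesis rate) + β·f_u·(R_i + R_m),

translation-coupled early, stability-coupled late.

On the analysis side: doublet gating, per-timepoint means, windowed
OLS rates with relative rate = slope/mean (1/min), Spearman
correlation tracks (mid-rank implementation) of any readout against
variant Tm across all variant×replicate points, a sparsity-pruned
variational Bayesian Gaussian mixture over (log10 red, log10 green)
for subpopulation detection (Dirichlet concentration 1e-6, diagonal
covariances, up to 7 components), and logistic growth fits with
bootstrap/MCMC uncertainty plus the dilution bias
⟨μ⟩ = [ln N(t2) − ln N(t1)]/(t2 − t1) that growth alone subtracts
from any relative fluorescence rate.

## Worked example

```r
library(chaperFlow)

ds    <- simulatePanel(seed = 1)   # 8 variants x 3 reps x 21 times x 3000 events
summ  <- summarizeSamples(ds)
rates <- rateTable(summ)
tm    <- tmMap(ds)

rateVsRate(rates, rates, channelX = "green", channelY = "red")
```

The 0–30 min row of that table prints `rho = 0.96` (n = 24): the
initial DnaK response tracks the translation rate almost perfectly.
The same call chain against stability shows the shift:

```r
gTm <- trackVsTm(rates, tm, "relative_rate", "green")
gTm[gTm$window_start %in% c(0, 150), c("window_start", "rho", "n_points")]
#>   window_start    rho n_points
#>              0 -0.145       24     # early: no stability signal
#>            150 -0.700       24     # late: less stable => stronger response

ratioTm <- trackVsTm(summ, tm, "mean_ratio")
ratioTm$rho[ratioTm$at == 120]
#> [1] -0.912                         # normalised response ranks variants by Tm
```

(Numbers are from `runPipeline(pipelineConfig(seed = 11))`, which
wraps the whole chain, writes every table plus a config echo, and
returns these metrics in a `RunReport`.) Growth analysis on the same
run:

```r
gc1 <- subset(growthCurves(ds), variant == "wt" & replicate == 1)
fit <- fitLogistic(gc1[, c("time_min", "od600")])
fit
#> GrowthFit (logistic): n0 0.5017, r 0.02303 /min, K 2.497;
#>   mu_max 0.01843 +/- 0.0001 /min [bootstrap, 500 draws]
dilutionBias(fit, c(30, 60))   # ~0.012/min of every relative rate is dilution
```

A thin command-line front end lives at
`inst/scripts/run-pipeline.R` (verbs: run-all, generate, summarize,
correlate, cluster, growth, validate).

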