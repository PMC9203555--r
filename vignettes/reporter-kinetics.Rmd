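---
title: "Modelling and analysing chaperone-reporter flow cytometry time series"
author: "chaperFlow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing chaperone-reporter flow cytometry time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaperFlow)
```

## The system and the questions

A dual-reporter plasmid makes two quantities visible in every *E. coli*
cell: the abundance of a recombinant client protein (a slow-maturing
tagRFP fusion under an IPTG-inducible promoter, read in the red
channel) and the activity of the DnaK heat-shock promoter (fast-maturing
sfGFP, read in the green channel). DnaK is the bacterial Hsp70; it
binds exposed hydrophobic stretches of unfolded protein and, by
releasing the sigma-32 transcription factor, converts unfolded-protein
load into heat-shock transcription. Expressing a panel of client
variants that differ only in thermodynamic stability (melting
temperature Tm) turns this into a controlled experiment: how much of
the chaperone response is driven by how *much* protein is being made,
and how much by how *unstable* it is?

chaperFlow implements both halves of the analysis: a generative
kinetic model that produces realistic single-cell fluorescence time
series and OD600 growth curves for such a panel, and the statistical
chain (gating, summaries, windowed relative rates, Spearman tracks
against Tm, mixture clustering, growth/dilution analysis) that turns
event tables into the population-level conclusions.

## The per-cell kinetic model

Each cell is an independent linear ODE in five states: immature and
mature client-RFP (`poi_immature`, `poi_mature`), a dark aggregated
pool (`poi_dark`), and immature and mature GFP. For a cell with plasmid
copy number $c$:

$$
\begin{aligned}
\dot R_i &= k_{syn} c\, I(t) - (k_{mat}^R + k_{deg}(f_u) + k_{agg} + \mu(t))\,R_i\\
\dot R_m &= k_{mat}^R R_i - (k_{deg}(f_u) + k_{agg} + \mu(t))\,R_m\\
\dot D   &= k_{agg}(R_i + R_m) - \mu(t)\,D\\
\dot G_i &= \alpha\,k_{syn} c\, I(t) + \beta\,U(t) - (k_{mat}^G + \mu(t))\,G_i\\
\dot G_m &= k_{mat}^G G_i - \mu(t)\,G_m
\end{aligned}
$$

with $k_{deg}(f_u) = k_{deg}^{basal} + k_{deg}^{unf} f_u$ and the
unfolded pool $U(t) = f_u (R_i + R_m)$.

The assumptions, and why they are defensible for this system:

* **Folding is an instantaneous two-state equilibrium.** The lambda
  repressor folds on sub-millisecond timescales, far faster than any
  rate in the model, so the unfolded fraction is the Boltzmann
  occupancy $f_u = 1/(1 + e^{\Delta G_u / RT})$ with
  $\Delta G_u = s\,(T_m - T)$ (`fractionUnfolded()`). The linear
  free-energy parameterisation pins $f_u = 1/2$ at $T = T_m$ by
  construction; the slope $s$ (kcal/mol/°C, default 0.25) sets how
  sharply stability maps onto unfolded load at 37 °C.
* **Promoter activity is the minimal two-term linear model**
  $A(t) = \alpha \cdot \text{synthesis} + \beta \cdot U(t)$. The first
  term captures co-translational DnaK engagement with nascent chains
  (proportional to translation), the second the equilibrium
  misfolded-pool engagement (proportional to unfolded protein). No
  saturation is modelled: the response is assumed to stay inside the
  cell's regulatory range at these expression levels. This is a known
  simplification — a capacity-limited cell would compress the response
  to the least stable variants.
* **Maturation is first order** with rate $\ln 2 / t_{50}$, using the
  literature half-times of 42 min (tagRFP) and 14 min (sfGFP). The
  36-min gap between the two reporters is what de-synchronises total
  intensities and makes *rates*, not levels, the comparable statistic.
* **GFP is not degraded, only diluted** — its degradation is decoupled
  from DnaK turnover, so the green level reports accumulated promoter
  output.
* **Aggregation is a uniform first-order loss** to a non-fluorescent
  pool ($k_{agg}$, variant-independent), consistent with the
  observation that the insoluble/soluble proportion does not differ
  across variants.
* **Division is not simulated**; growth enters as the continuous
  per-capita dilution rate $\mu(t) = r\,(1 - N(t)/K)$ of a logistic
  culture. All stable species are diluted equally.
* **Induction at $t = 0$** follows a 120-min burn-in during which
  synthesis runs at the leak fraction (2%), which is what puts the
  faint pre-induction diagonal into the $t = 0$ event clouds.

Because every term is linear in $c$ (the GFP equation through $U$ and
the $\alpha$ term), a whole replicate needs a single per-unit ODE
solve, scaled per cell — unless the optional toxicity switch is on, in
which case cells that push their soluble client pool over a threshold
shut synthesis off permanently (resolved on a 1-min grid) and the
synthesis-off continuation is solved once per crossing time. That
switch, off by default, is one *possible* emulation of the late
low-abundance subpopulations seen for the most stable variants; the
data do not identify the mechanism, and the package does not claim to.

## What the generator emulates, and what it does not

The default panel is eight lambda-repressor variants spanning Tm 8-61
°C with the wild type at 55 °C. Only the wild-type Tm is a literature
value; the mutant values are synthetic configuration values consistent
with the published ordering and range. Three replicates, 3000 events
per sample, and the standard sampling schedule (0, 2, every 5 min to
30, every 10 min to 120, every 30 min to 240) reproduce the study
design.

Sources of variation, in decreasing order of importance:

* a **replicate-level synthesis multiplier** (lognormal, sd 0.5 on the
  log scale) emulating day-to-day induction and culture variability;
* **plasmid copy number** per cell (lognormal, median ~20, sdlog
  0.25);
* **multiplicative measurement noise** (CV 0.15) on both fluorescence
  channels, applied to signal plus autofluorescence background (80
  a.u. red, 40 a.u. green);
* small growth-rate jitter (2%) and OD measurement noise (1%).

The replicate synthesis multiplier deserves comment because it carries
the package's central reproduction. Early after induction both
channels sit close to their backgrounds, so both *relative* rates are
steep monotone functions of the shared signal-to-background scale —
that is what produces the strong early green-rate-versus-red-rate
correlation with only weak early dependence on Tm. Late in the
time course the signals dwarf the backgrounds, the multiplier cancels
out of relative rates, and the stability-dependent terms
($k_{deg}^{unf} f_u$ on red, $\beta U$ on green) dominate. The
translation-early / stability-late shift is therefore a structural
property of the model, not a per-seed accident; the acceptance suite
verifies it across 20 independent seeds at full scale.

The same multiplier is also the model's main *limitation*: it
multiplies late protein levels, so the correlation between mean red
fluorescence at 120 min and Tm — strongly positive in noiseless means
(Spearman exactly 1) — is attenuated in noisy panels to roughly
+0.1 to +0.7 depending on the seed. Real experiments that show
stronger abundance-stability correlations presumably have tighter
day-to-day synthesis reproducibility than the conservative default
here. Passing tests therefore demonstrate the rate- and
ratio-based statistics, which are robust to synthesis scale, rather
than absolute-abundance reproducibility.

Scatter channels are stationary lognormals carried only so the
doublet-gating interface is exercised; no morphology is modelled.
Default growth is variant-independent: a Tm-coupled growth rate of
realistic size would let differential dilution reorder the red means
of the two least stable variants (whose unfolded fractions are nearly
identical), breaking the clean monotonicity that degradation alone
implies. A `growthTmCoupling` parameter exists for users who want the
coupling.

## The statistics

**Summaries and rates.** Events are gated on forward/side scatter
(default: a permissive per-sample 1st-99th percentile rectangle, since
no numeric gate is published); per-timepoint means are plain
arithmetic means of absolute intensities. The green/red ratio is by
default the mean of per-event ratios — both reporters sit on the same
plasmid, so the per-event ratio cancels copy number cell by cell —
with ratio-of-means available as a switch. Rates are unweighted OLS
slopes over closed windows (default 0-30, 30-60, 60-90, 150-180,
180-210 min; boundary points belong to both adjacent windows), and
relative rates divide the slope by the in-window mean, giving units of
1/min and removing reporter brightness from the comparison.

**Correlation tracks.** Spearman's rho is implemented from first
principles (mid-ranks for ties, then the Pearson formula on ranks) and
is cross-checked in the tests against an independent implementation to
1e-12. Tracks against Tm use all variant-by-replicate points (24 by
default), not per-variant means; signed rho is always reported. A zero-
variance readout yields an explicit NA with a warning rather than a
silent NaN. No p-values are attached by default; an exact permutation
test is available for n <= 10.

**Mixture clustering.** Single-cell structure is analysed in
(log10 red, log10 green) space — raw fluorescence is heavy-tailed and
a poor target for diagonal Gaussians — with a variational Bayesian
mixture: up to 7 components, Dirichlet weight prior with concentration
1e-6, diagonal covariances with Normal-Gamma priors per dimension
(prior mean at the data mean, prior variance at the data variance,
unit mean-precision). The tiny concentration makes empty components
cost prior mass, so the data select the effective component count; a
component is reported as "effective" above a weight floor of 0.01 (a
documented operationalisation — no quantitative definition of the
main population is published). The ELBO is computed every sweep in the
exact form (log-sum-exp of the responsibilities minus the KL
divergence of the variational posteriors from their priors) and is
asserted to be non-decreasing in every test fit. Restarts: the first
initialisation is a single merged component — the basin the sparsity
prior favours for unimodal data — and the rest are k-means++ seeded;
the best ELBO wins. Convergence is an absolute ELBO gain below 1e-5
with a 500-sweep cap; hitting the cap flags `converged = FALSE`
rather than erroring. The pipeline batches many fits and uses 2
restarts (merged + one seeded), which in practice recovers the same
solutions as the 5-restart interactive default.

**Growth and dilution.** OD600 curves are fit to the logistic model by
Levenberg-Marquardt least squares; uncertainty comes from a seeded
residual bootstrap (500 resamples by default) or, behind the same
interface, random-walk Metropolis MCMC with uniform priors over
documented bounds (n0 in (0, 2 max OD], r in (0, 1] 1/min, K in
(max OD/2, 10 max OD]). "Maximum growth rate" is the maximum of the
*specific* rate mu(t) = r (1 - N/K) over the observed window,
evaluated numerically per posterior draw (an "absolute" dN/dt mode is
provided, since the published phrase does not disambiguate). The
dilution bias of a window is the time-averaged specific rate,
[ln N(t2) - ln N(t1)]/(t2 - t1) — the additive depression that growth
alone imposes on any per-cell relative fluorescence rate. The additive
(not fractional) convention is a documented choice. Spreads across
fits use the sample (n-1) standard deviation, stated in the output.

## Numerical choices

* ODEs: `deSolve::lsoda`, rtol 1e-9 / atol 1e-12; the tests require
  agreement with an independent matrix-exponential closed form to
  1e-6 relative at all 21 schedule times. Round-off below zero is
  clipped to preserve the positivity invariant.
* Degenerate inputs are errors, not NaNs: empty gated samples name the
  sample; windows with fewer than two schedule points are explicit
  absent rows in rate tables; non-increasing OD curves refuse a
  logistic fit; all-tied vectors refuse a correlation.
* Randomness: one master seed; per-(variant, replicate, stage)
  sub-seeds derived by fixed arithmetic offsets (all below 2^31), so
  replicates are independent but reproducible and a rerun is
  byte-identical.
* Carrying capacity `Inf` is supported internally for exactly constant
  specific growth (used by the conservation tests); fitted models are
  always finite-K logistics.

## Worked example

```{r example, eval = FALSE}
library(chaperFlow)

ds <- simulatePanel(seed = 1)            # full default panel
summ <- summarizeSamples(ds)
rates <- rateTable(summ)
tm <- tmMap(ds)

## early response follows translation ...
rateVsRate(rates, rates, channelX = "green", channelY = "red")
## ... the late response follows stability
trackVsTm(rates, tm, "relative_rate", "green")
## and the normalised response ranks variants by Tm at 120 min
trackVsTm(summ, tm, "mean_ratio")

## growth and dilution
gc1 <- subset(growthCurves(ds), variant == "wt" & replicate == 1)
fit <- fitLogistic(gc1[, c("time_min", "od600")])
maxGrowthRate(fit)
dilutionBias(fit, c(30, 60))

## single-cell structure at 240 min
s <- Filter(function(x) x@variant == "wt" && x@timeMin == 240,
    flowSamples(ds))[[1]]
fitMixture(s, seed = 1)
```

Problem sizes: the test suite runs the full default design (8 x 3 x 21
x 3000 events) for the 20-seed pattern checks and the determinism
check, mixture recovery on 2000-point two-component data, and smaller
panels elsewhere; these sizes were chosen so the whole suite exercises
the study-scale conditions while remaining routine to run on a laptop.

## Known limitations

* No stochastic chemical kinetics; cells are deterministic ODEs with
  extrinsic (copy number, replicate) and measurement noise only.
* No explicit sigma-32/FtsH circuit, no promoter saturation, no
  co-translational folding intermediates.
* No spectral spillover or logicle/arcsinh display transforms; gating
  is a rectangle, not density-based doublet discrimination.
* The FCS binary format is not read; the native interchange format is
  the delimited event table written by `writeDataset()`.
* Whether the late OD drop of stable variants reflects death or
  artifact is left open; the toxicity switch is an emulation device,
  not a mechanistic claim.
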