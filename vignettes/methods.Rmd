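---
title: "Modelling the probability of peaceful interactions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the probability of peaceful interactions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the estimator

`peacetrace` models the probability that an adult individual from an
archaeological skeletal assemblage shows *no* craniofacial trauma — the
probability of peaceful interactions (PPI) — as a function of the
climatic, oceanic, demographic and socio-political conditions the
individual plausibly experienced. Three features of such data shape the
whole design:

1. **Individuals are dated only to a period window** (often several
   centuries). Any predictor tied to calendar time is therefore
   uncertain, and that uncertainty must be propagated, not averaged
   away.
2. **There is no direct census.** Relative population density is proxied
   by the temporal density of radiocarbon dates ("dates as data"),
   summarized as a bootstrap ensemble of composite kernel density
   estimates (CKDE).
3. **The response is binary and imbalanced** (roughly 4:1 no-trauma to
   trauma), with strong site-level clustering and correlated,
   interacting predictors — the natural home of a probability forest
   rather than a single parametric regression.

The estimator chain is: calibrate and bin the dates and build 1000
CKDE replicates per region → attach to every individual 1000 Monte-Carlo
draws of each exposure over their window → fit 1000 probability-forest
models per region, model *i* using draw *i* as if it were the true
predictor table → aggregate metrics, permutation importances and
partial-dependence curves across the runs.

## Radiocarbon machinery

**Calibration.** The calendar posterior of a date is the standard
intercept-free density: at each grid year, the normal density of the
(reservoir-adjusted) 14C age at the interpolated curve mean with
variance `lab error² + curve error²`, normalized to sum to one. The grid
is 1-yr steps by default, linearly interpolated between curve knots;
this makes an independent fine-grid integration oracle well-posed, and
the tests hold the implementation to that oracle (mode within one grid
step, 95.4% HPD mass within 1e-3). Marine dates are calibrated on the
marine curve with their ΔR offset.

**Quality control and binning.** Dates with 1σ errors above 100 yr are
dropped (strictly greater: an error of exactly 100 is kept). Within each
site, dates are clustered by complete-linkage agglomeration on
uncalibrated 14C ages, cut at 200 yr. The curve grid step, the linkage
criterion and the KDE bandwidth are not field-standardized numbers; the
package's choices (1 yr, complete linkage, 50 yr bandwidth) are defaults
exposed as arguments.

**CKDE.** Each of the 1000 replicates samples one date per bin, one
calendar year from that date's posterior, and fits a Gaussian KDE on the
output grid, renormalized by trapezoid rule. An optional taphonomic
variant divides each replicate by the survival curve
`n(t) = 5.726442e6 · (t + 2176.4)^-1.3925309` and renormalizes.

**What binning costs.** Binning deliberately caps the influence of
intensively dated sites, which also means the CKDE does *not* estimate
the raw date-generating intensity: within a 200-yr cluster, one date and
fifty dates contribute identically. In synthetic worlds we measure this
directly: exposures extracted straight from grids or series are
recovered from the draw means at r > 0.9 (for windows ≤ 3 centuries),
while the CKDE-mediated population exposure is attenuated to roughly
r ≈ 0.65–0.85 depending on the seed. A green population-recovery test
therefore certifies the Monte-Carlo plumbing and the qualitative shape
of the proxy, not an unbiased population estimate — which is also the
honest reading of the method on real data.

## Exposure draws

The coastal zone is `distance < 15 km AND elevation < 500 masl`, both
strict; everything else is inland. For each individual and each century
overlapping their window, the four terrestrial climate variables are
averaged over grid cells whose centers lie within a 20-km great-circle
radius. One century index is drawn per Monte-Carlo draw and all four
variables are taken from it **jointly**, preserving within-century
covariance (the alternative — independent per-variable draws — would
erase exactly the covariance the collinearity screen is supposed to
see). SST comes from the nearest core (coastal individuals only; ties
broken by core id), ENSO frequency from the single events-per-century
series, both resampled uniformly within the window. Population draws
pick one KDE replicate and one grid year per draw and record that
replicate's density. Climate, SST, ENSO and population draws are
mutually independent across sources within a draw index; nothing in the
data supports cross-source coupling. Individuals whose window leaves the
grid or series produce an error rather than a silent truncation.

## The forest ensemble

A probability forest is a bagged ensemble of regression trees on the
0/1 "no trauma" indicator: variance-reduction splits, `mtry = √p`
candidate variables per split, minimum node size 10, 500 trees,
unlimited depth. Leaf means are class probabilities and the forest
prediction is their average. These hyperparameters are conventional
defaults, stated here because no field standard fixes them; all are
configurable. The implementation is compiled (Rcpp) because the ensemble
fits 2 × 2 × 1000 forests in a full run.

Per run *i*: slice draw *i* as the predictor table; cap each site at 30
individuals (uniform without replacement; every site stays represented);
split 75/25 stratified by trauma status; fit; record held-out AUC and
MSE (Brier score); permutation importance (mean MSE increase over 5
permutations, computed on the held-out rows — on training rows even
pure-noise variables show inflated importance); partial dependence of
P(no trauma) for every retained variable on a **fixed grid** (25 points
between the 1st and 99th percentile of the pooled draw means — fixed so
curves aggregate pointwise across runs; the percentile clip avoids
extrapolating trees beyond support). A second forest on all (capped)
rows yields log-loss (probabilities clipped to `[1e-15, 1-1e-15]`) and
its transform `exp(-log_loss)`, the "accuracy as probability" metric.
Two-variable PD surfaces are computed only for a configured number of
leading runs — they are an order of magnitude more expensive and their
aggregate stabilizes quickly. PD averages are taken over a per-run
subsample of at most `pd_rows = 200` rows (standard practice, as in the
`pdp` package's sampling option); this changes PD values by Monte-Carlo
noise only.

**Collinearity screen.** Before any run, pairwise Pearson correlations
of the per-individual draw means are computed; for each pair with
|r| ≥ 0.7 the variable lower in a fixed preference order is dropped —
means are preferred over SDs, since a mean captures both productivity
and (through the built-in mean–SD coupling) instability. In worlds built
like the real system this reproducibly removes SD precipitation (tied to
mean precipitation) and, on the coast, SD temperature (inversely tied to
mean temperature). Variables constant within a region (e.g. complexity
in a span with no state presence) are dropped with a warning before
screening.

**Aggregation.** Across runs: mean, sample SD, a ±2 SD band, and a
normal-approximation 95% CI on the mean (`±1.96·SD/√n`). PD curves are
averaged pointwise; each mean curve is reduced to its **PPI range** —
the pair (value at the low predictor end, value at the high end).
Because several responses are non-monotone ("sweet spots"), the curve
minimum and maximum are also reported; both conventions are emitted and
labelled, since the narrative use of "PPI range" is ambiguous between
them.

## The synthetic world

The generator is a first-class module, not a fixture: every downstream
stage is tested against its known truth. Its defaults are the stated
study system — 116 sites, 7983 adults (44% coastal), a Holocene span at
century steps — scaled down in tests.

* **Trauma model.** Log-odds of trauma are linear in standardized true
  exposures with one centered quadratic population term (`z² − 1`) and
  one temperature×population interaction: enough nonlinearity to mirror
  the inferred "growth fosters peace until density tips into violence"
  pattern while staying analytically checkable. The default intercept
  (−1.55) puts prevalence near the observed ~21% after accounting for
  the variance the nonzero coefficients add (a logit-normal mean, not
  `plogis(intercept)`).
* **Climate.** Smooth spatial gradients plus a spatially coherent AR(1)
  century anomaly. SD fields are tied to mean fields — SD precipitation
  proportional to mean precipitation, SD temperature declining in mean
  temperature — so the collinearity screen fires the way it does on real
  reconstructions, and cell noise is kept small enough that 5/20/50-km
  buffer means are tightly correlated, as validation on the real rasters
  reports.
* **Occupation histories.** Each region has a "master" density of a few
  broad demographic booms over a uniform background; site occupation
  phases (1–3 Gaussians, SD 150–400 yr) center on years drawn from the
  master. This is the regime in which a binned dates-as-data proxy is
  informative: the regional signal is carried by many sites' phases, not
  by date counts at single sites. Site sizes are moderately heavy-tailed
  (Gamma(2)), so the 30-per-site cap binds at large sites without one
  site swamping a region.
* **ENSO.** An events-per-century series built as slow forcing plus
  Poisson event noise, then 5-century smoothed — emulating a
  sediment-core *reconstruction* rather than raw counts.
* **Dates.** Sites are dated proportionally to size; true years are kept
  so calibration can be round-trip tested. 10% of coastal dates are
  marine with a ΔR offset, generated through (and calibrated against)
  the marine curve. The calibration curves themselves are synthetic
  stand-ins in the standard `.14c` layout — strictly increasing with
  realistic wiggles — because no real curve file can be assumed present.
* **Not emulated:** real Andean geography, ocean dynamics, ENSO physics,
  spatially varying reservoir effects, inter-site exchange. A green test
  on this world certifies the inference machinery, not any substantive
  claim about the Andes.

## Numerical and degenerate-case choices

* Calibration errors ≤ 0, dates outside the curve's 14C span ± 4σ, empty
  bin lists, windows outside grids, single-class training sets and
  unknown PD variables all raise classed errors naming the offender.
* AUC on a one-class test set is `NA` with a warning; the other metrics
  are still returned.
* `round(class_n · test_fraction)` sets per-class test counts; with tiny
  strata this can make AUC undefined for a run, which then simply drops
  out of the AUC mean.
* All randomness flows from one global seed through `derive_seed(seed,
  stage_label)` (a 31-bit label hash), so every stage is independently
  reproducible and two runs from one seed are byte-identical.
* Ties in SST core distance go to the smallest core id; binning ties are
  broken by lab id sort; both are arbitrary but deterministic.

## Known limitations

* The forest cannot extrapolate; PD curves flatten toward the grid
  extremes, so PPI ranges at the 1st/99th percentile endpoints are
  mildly conservative relative to the generative model.
* The CKDE population proxy is relative and attenuated (see above);
  coefficients on population are therefore recoverable in sign and rank,
  not in magnitude.
* Exposure draws are stored dense (individuals × draws × variables);
  at the full published scale this is ~450 MB, fine on a workstation but
  the pipeline makes no attempt to chunk it.
* The per-region ensemble treats individuals as exchangeable given site
  capping; no spatial cross-validation is attempted.
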