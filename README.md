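# peacetrace

Modelling the probability of peaceful interactions (PPI) — the absence
of craniofacial trauma in adult skeletal remains — as a function of
Holocene climate, relative population density and socio-political
complexity.

## Who this is for

Bioarchaeologists and quantitative paleo-scientists who have (a) an
individual-level trauma database with site coordinates and period
windows, (b) regional radiocarbon date lists, and (c) gridded paleoclimate
reconstructions plus ocean-core series, and who want a tested,
reproducible version of the full inference chain:

```
14C dates ──calibrate/filter/bin──▶ 1000 CKDE population replicates per region
                                          │
individuals ──20-km buffer extraction──▶ 1000 Monte-Carlo exposure draws each
                                          │    (temp, precip, SDs, SST, ENSO, pop.)
                                          ▼
              1000 probability-forest models per region (draw i = model i)
                                          │
         aggregated importance, AUC/MSE/log-loss, partial dependence, PPI ranges
```

The statistical core: each individual's trauma status `y ∈ {0,1}` is
modelled by a probability forest (bagged regression trees on `1 − y`,
`mtry = √p`, leaf means = probabilities), so every model returns
`P(no trauma | x)`. Temporal uncertainty is propagated by treating each
of the 1000 per-individual exposure draws as one "true" data set:
model *i* is fitted to draw *i*, and inference reads the distribution of
the 1000 runs — importance means with ±2 SD bands and 95% CIs, and
pointwise-mean partial-dependence curves summarized as PPI ranges
(P(no trauma) at the low vs high end of each predictor).

A full synthetic-world generator (`generate_world()`) with a known
logistic trauma model makes the entire chain testable against ground
truth; see `vignettes/methods.Rmd` for the model, its assumptions, and
every numerical choice.

## Worked example

```r
library(peacetrace)

wc <- world_config(seed = 42, n_sites = 20, n_individuals = 300,
                   n_dates = 200, time_span = c(6000, 0),
                   grid_extent = list(lon = c(-76, -74.5),
                                      lat = c(-14, -12.5), cell_deg = 0.1))
w <- generate_world(wc)
w
#> <synthetic_world: 20 sites, 300 individuals (20.7% trauma), 200 dates, span 6000-0 cal BP>

cfg <- pipeline_config(output_dir = "out", seed = 42, world = wc,
                       model = model_config(n_models = 5, n_trees = 50,
                                            pd_grid_size = 10),
                       n_draws = 50, n_kde_replicates = 50)
s <- run_pipeline(cfg)
s$coast
#> <ensemble_summary: region coast, 5 runs>
#> metrics:
#>                metric  mean ci_lo ci_hi
#>                   auc 0.628 0.489 0.768
#>                   mse 0.203 0.158 0.248
#>              log_loss 0.275 0.259 0.291
#>  log_loss_probability 0.760 0.748 0.772
#> PPI ranges:
#>            variable p_low_end p_high_end p_min p_max
#>    mean_temperature     0.636      0.787 0.636 0.801
#>  mean_precipitation     0.610      0.765 0.610 0.765
#>      enso_frequency     0.714      0.705 0.693 0.715
#>          population     0.716      0.672 0.672 0.727
#>                 sst     0.643      0.731 0.625 0.813
#>          complexity     0.707      0.716 0.707 0.716
```

Reading it: the mean held-out AUC of the 5 runs is 0.63 (this demo world
has a real but modest signal at n = 300); `log_loss_probability` is
`exp(−log loss)` of the all-data refits. The PPI ranges say, e.g., that
the mean partial-dependence curve for temperature rises from
P(no trauma) = 0.64 at cold to 0.79 at warm — in this world temperature
was generated trauma-protective — while SD-precipitation does not appear
because the collinearity screen (|r| ≥ 0.7 against mean precipitation)
removed it. Artifacts land in `out/`: `summary_<region>.json`,
importance/PD/PPI/correlation CSVs, per-run metrics, CKDE replicates and
a manifest with the seed.

Real data enter through the same CSV schemas the generator writes
(`individuals.csv`, `dates.csv`, `sst_cores.csv`, `enso.csv`,
`climate.csv`, `.14c` curve files); point `pipeline_config(paths = ...)`
at them instead of passing `world`. A JSON config + CLI wrapper is
available via `inst/cli/peacetrace.R` (`--config cfg.json --seed N
--out DIR`).

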