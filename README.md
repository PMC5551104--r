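# coarsesdm

Many species occurrence records are georeferenced only to an administrative
unit — "this dragonfly was seen somewhere in this county" — rather than to a
point. Distribution modelers routinely put such records on the county
centroid, or describe them by county-average climate, and feed them to a
presence-background model alongside precise localities. **coarsesdm** is a
fully synthetic testbed for measuring what that coarse georeferencing does to
the fitted models: it simulates a climate landscape, tessellates it into
counties of controllable size, samples virtual species with *known*
suitability surfaces, degrades the samples the way county-level databases
degrade real records, fits a maximum-entropy distribution model to each
variant, and quantifies the damage.

Because every species is virtual, the usually-unanswerable question — "how
wrong is the model built from coarse records?" — has an exact answer here:
the model fitted to the true point localities of the same individuals is the
reference, and the true suitability surface is known.

## The model

The fitted model is a presence-background maximum-entropy model: the Gibbs
distribution over background cells `raw(x) ∝ exp(λ · f(x))` that maximizes
the L1-regularized presence log-likelihood

```
mean_presence(λ · f) − log Σ_bg exp(λ · f) − Σ_j β_j |λ_j|
```

with the classic auto-feature rules (linear and quadratic always, hinge from
15 presences, product from 80) and the published per-class regularization
tables. Optimization is cyclic coordinate descent with soft-thresholding
(compiled); fits are checked against the Karush–Kuhn–Tucker stationarity
conditions. Covariates are the leading principal components (≥ 98.5%
cumulative variance) of 19 bioclimatic summaries derived from simulated
monthly climate normals.

Each modeled species is fitted five times, to:

| treatment | records |
|---|---|
| `true_locality` | exact coordinates |
| `county_centroid` | every record moved to its county centroid |
| `county_average` | every record given county-mean covariates |
| `mix_centroid` | half converted to centroids (seeded selection) |
| `mix_average` | the same half converted to county averages |

and each degraded model is scored against the true-locality reference:
thresholded range-area ratios (minimum-training-presence and
sensitivity-equals-specificity thresholds), niche-overlap statistics
(Schoener's D, Hellinger-based I, relative rank agreement), and
presence-background AUC.

## Worked example

A small end-to-end experiment (a 60×60 landscape, four virtual species,
15 records each) runs in under a minute:

```r
library(coarsesdm)

cfg <- experiment_config(n_rows = 60, n_cols = 60, mean_area_small = 16,
                         mean_area_large = 150, n_bg = 800,
                         n_species = 4, n_per_species = 15, seed = 7)
report <- run_experiment(cfg)
report
#> <experiment_report> 4 species modeled (0 skipped)
#> Mean predicted-area ratio vs true localities (%):
#>        treatment mean_ratio_ses_pct mean_ratio_mtp_pct
#>  county_centroid           220.1833          191.13413
#>   county_average           133.0767           78.35161
#>     mix_centroid           208.1508          193.06461
#>      mix_average           149.7157          123.73479

subset(report$per_species, treatment == "county_centroid",
       select = c(species_id, n_records, auc, ratio_mtp, D, I, RR))
#>    species_id n_records       auc ratio_mtp         D         I        RR
#> 2      vsp001        15 0.7863333  2.541893 0.4485332 0.7478419 0.6759166
#> 7      vsp002        15 0.7925833  2.954780 0.5430009 0.8210709 0.7778619
#> 12     vsp003        15 0.8783333  1.146967 0.6706632 0.9093518 0.8006723
#> 17     vsp004        15 0.7863333  1.001724 0.5303708 0.8276567 0.7360733
```

Already at this scale the study's signature pattern appears: centroid-placed
records roughly double the predicted range area (mean 191% of the
true-locality area at the minimum-training-presence threshold), while
county-average covariates are far gentler (78%), and the 50/50 mixes fall in
between. `run_experiment(cfg, out_dir = "results")` additionally writes
deterministic CSVs (`per_species.csv`, `area_ratios.csv`, `overlap.csv`,
`wilcoxon_tests.csv`, `region_contrast.csv`, `size_effect.csv`).

Lower-level pieces are all exported — `generate_monthly_climate()`,
`derive_bioclim()`, `fit_pca()`/`select_components()`,
`generate_counties()`, `sample_occurrences()`, `filter_records()`, the
`make_*_dataset()` treatments, `build_features()`/`fit_maxent()`, and the
comparison statistics — so any stage can be run and inspected in isolation.
A command-line wrapper lives in `inst/scripts/coarsesdm.R`.

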