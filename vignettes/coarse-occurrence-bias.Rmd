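---
title: "Measuring the cost of county-resolution occurrence data in distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the cost of county-resolution occurrence data in distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## 1. The question

Occurrence databases mix precisely georeferenced records with records known
only to an administrative unit. The two standard rescues — placing a record
on its county centroid, or describing it by county-average environmental
conditions — both inject error whose size depends on how large and how
climatically heterogeneous the county is. This package builds a world in
which that error can be measured exactly: the species are simulated, so the
model fitted to their *true* point localities, and the true suitability
surface itself, are available as references that no field study can have.

Everything below is generated in code; there are no external data
dependencies. Each module is exported on its own, and
`run_experiment()` chains them.

## 2. The synthetic landscape

**Grid.** A `grid_spec(n_rows, n_cols)` raster of unit cells; matrices are
the raster type throughout, with ESRI ASCII grid text I/O
(`write_ascii_grid()`).

**Climate.** `generate_monthly_climate()` builds 12 monthly normals of
minimum/maximum temperature and precipitation as

* a deterministic north–south temperature gradient (`gradient_strength`,
  default 15 degrees across the map) and a west–east moisture gradient,
* a seasonal cosine cycle (`seasonal_amplitude`, default 10 degrees),
* spatially autocorrelated anomalies: Gaussian random fields with
  exponential covariance `exp(-h / autocorr_length)` (default length 8
  cells), simulated exactly by circulant embedding on the doubled torus
  (`gaussian_random_field()`), plus independent per-month noise.

Positivity of precipitation and `tmax - tmin >= 1` are enforced by softplus
transforms, not truncation, so fields stay smooth. With all noise and
gradients set to zero the generator emits spatially constant layers, which
the tests exploit.

**Bioclim summaries.** `derive_bioclim()` computes the 19 standard
bioclimatic variables from the monthly normals. Conventions that matter for
reproducibility: quarters are the 12 consecutive three-month windows with
December–January wraparound and earliest-window tie-breaking; the
seasonality variables (BIO4, BIO15) use population standard deviations; the
BIO15 denominator is `1 + BIO12/12`.

**Covariates.** `normalize_layers()` z-scores each layer with the
*population* SD over masked cells; `fit_pca()` eigendecomposes the
population covariance matrix (signs fixed so each component's
largest-magnitude loading is positive); `select_components()` keeps the
smallest component set reaching `cum_threshold` (default 0.985) cumulative
variance — typically 3–4 components, which become the model covariates and
carry their eigenvalue fractions as weights.

**Counties.** `generate_counties()` tessellates the grid by seeded Voronoi
growth around county seeds, with seed density set by target mean areas on
either side of a dividing line: a *large-county region* (west, default mean
300 cells) and a *small-county region* (east, default 25 cells), the
synthetic analog of a map where administrative units differ an order of
magnitude in size. County centroids are cell means, snapped into the county
when the mean falls outside it. `county_climate_offset()` (eigenvalue-
weighted |centroid climate − county mean climate|) and
`county_climate_variance()` quantify how unrepresentative each county's
centroid is; in the default landscape the large-county region's median
offset is ~1.6× the small-county region's.

**Species and records.** A `virtual_species()` has product-Gaussian
suitability over the component axes. Experiment species draw their niche
center from a (possibly region-restricted) cell and use
`niche_width_factor` (default 1) times each component's landscape SD as
widths. `sample_occurrences()` draws cells without replacement with
probability proportional to suitability.

## 3. Record filtering and the five treatments

`filter_records()` mimics a vetted database snapshot, in order: drop records
whose coordinates contradict their claimed county; deduplicate
species-by-cell; keep only the first record per species per county; drop
species with fewer than `min_records` (default 10). The one-per-county rule
makes the point dataset and its county-degraded sister datasets the same
size. The filter is idempotent.

`n_per_species` is a *post-filter* target: the runner oversamples raw draws
(`oversample`, default 4×, capped by the species' support), filters, and
keeps the first `n` survivors, so modeled sample sizes are controlled the
way curated record counts are.

The five training sets per species (`make_true_locality_dataset()`,
`make_centroid_dataset()`, `make_county_average_dataset()`,
`make_mixed_datasets()`) are described in the README; the two mixes convert
the *same* seeded `floor(n/2)` record subset, so they differ only in how the
converted half is degraded.

## 4. The distribution model

`fit_maxent()` maximizes the L1-regularized presence log-likelihood of the
Gibbs distribution over the background sample (default `n_bg` 4000 cells
drawn uniformly from the mask). Implementation choices:

* **Features** (`build_features()`): linear + quadratic always, hinge (20
  knots per covariate, both orientations) from 15 presences, pairwise
  products from 80 — the classic auto-feature thresholds. Features are
  scaled to [0, 1] by their background range and clamped outside it. The
  expansion depends only on the background and the presence *count*, so one
  expansion is shared by all five treatments of a species.
* **Regularization**: `β_j = multiplier × class_default(n) × SD_presence(f_j) / sqrt(n)`
  using the published per-class interpolation tables, with the deviation
  floored at 0.001 × feature range and at `0.5/sqrt(n)` for hinge features.
  The floor matters: without it, hinge features unseen at the presences are
  unpenalized in the direction that sends their weights to −∞, which
  hard-zeroes background regions and makes surfaces from different
  treatments artificially disjoint.
* **Solver**: cyclic coordinate descent with soft-thresholding in C++
  (active-set sweeps, periodic full re-screening). Convergence requires both
  a small relative objective change and Karush–Kuhn–Tucker stationarity on
  every coordinate (`kkt_tol`, default 1e-4). The objective is concave, so
  the fitted *distribution* is initialization-invariant; the weight vector
  itself is identifiable only to about the KKT tolerance when hinge features
  are nearly collinear.
* **Outputs**: raw (normalized to sum 1 over the background) and logistic
  `τ·e^H·raw / (1 + τ·e^H·raw)` with prevalence `τ = 0.5` and `H` the
  entropy of the raw distribution.

## 5. Scoring a degraded model

`compare_species()` scores each treatment against the true-locality
reference on the same background:

* **Thresholded range area**: minimum training presence (lowest presence
  prediction; sensitivity 1 by construction) and
  sensitivity-equals-specificity (exhaustive candidate scan, lower tie),
  both with the ≥ rule; `area_ratio()` is treatment area / reference area.
* **Niche overlap** on mask-normalized raw surfaces: Schoener's
  `D = 1 − ½Σ|p_A − p_B|`, Hellinger-based
  `I = 1 − ½Σ(√p_A − √p_B)²` (always ≥ D), and relative rank `RR`, the
  probability that a random cell pair is ordered identically (exact
  O(n log n) inversion counting, ties half-credit).
* **AUC** of presences vs background (rank formulation), and paired
  Wilcoxon signed-rank tests across species (`stats::wilcox.test`; exact
  for ≤ 25 untied pairs; all-zero differences give p = 1 by convention).

## 6. Defaults and their rationale

| parameter | default | why |
|---|---|---|
| grid | 120 × 120 | smallest size giving ~25 large + ~290 small counties |
| `mean_area_small` / `large` | 25 / 300 | order-of-magnitude county-size contrast |
| `autocorr_length` | 8 | counties both smaller and larger than a climate patch |
| `niche_width_factor` | 1 | widespread species; narrow endemics fail the ≥10-county rule, as in curated analyses |
| `n_per_species` | 20 | typical curated record counts (10–30) |
| `oversample` | 4 | enough raw draws for the one-per-county filter to leave n |
| `n_bg` | 4000 | ≥ a quarter of the domain; AUC and Z stable to ~1% |
| `cum_threshold` | 0.985 | keeps 3–4 components, mirroring common practice |
| `beta_multiplier` | 1 | the standard default |
| `min_records` | 10 | conventional floor for presence-only modeling |

All child seeds derive from the master seed via
`child_seed(master, stage, index) = (master·1000 + stage·100 + index) mod (2³¹−1)`,
so any stage is reproducible in isolation and every seed fits in an integer.

## 7. Numerical notes

* Circulant-embedding eigenvalues are clamped at zero; the measured
  correlation function tracks `exp(-h/L)` within ~0.03 and the marginal
  variance is 1 within ~1%.
* Population (divide-by-N) conventions are used everywhere a SD or variance
  enters a reported statistic, and tie conventions (earliest quarter, lowest
  threshold, first record) are fixed and tested.
* Exact tie handling in `relative_rank()` groups values by `match()` on the
  doubles themselves — no rounding.
* `logZ` and the logistic transform are computed in log space with max
  shifts; raw predictions sum to 1 over the background to 1e-9.

## 8. Limitations

* The landscape is a torus-free rectangle with two climate gradients and
  stationary anomalies; real orography produces heavy-tailed county
  heterogeneity this generator does not.
* Counties are Voronoi-compact; real administrative units can be elongated
  or disconnected, which worsens centroid error.
* The logistic output's prevalence `τ = 0.5` is conventional, not
  estimated; only threshold- and rank-based statistics are interpreted.
* Species' niches are axis-aligned Gaussians in component space; suitability
  interactions between components are not simulated (the model's product
  features exist, but the truth never needs them).
* Mann–Whitney AUC against a background sample is a relative, not absolute,
  discrimination measure; values are comparable across treatments of the
  same species, not across landscapes.
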