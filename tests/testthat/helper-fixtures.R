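# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; sizes are kept small so the whole suite stays fast.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a small two-region landscape with climate, counties, components, background
tiny_landscape <- function() {
  memo("tiny_landscape", function() {
    cfg <- experiment_config(n_rows = 60, n_cols = 60, mean_area_small = 16,
                             mean_area_large = 150, n_bg = 800, seed = 42)
    build_landscape(cfg)
  })
}

tiny_config <- function(..., seed = 42) {
  experiment_config(n_rows = 60, n_cols = 60, mean_area_small = 16,
                    mean_area_large = 150, n_bg = 800, seed = seed, ...)
}

# deterministic single-species fit on the tiny landscape
tiny_fit <- function() {
  memo("tiny_fit", function() {
    ls <- tiny_landscape()
    cfg <- tiny_config(n_species = 1, n_per_species = 20)
    sp <- draw_species(ls, cfg, 1)
    occ <- sample_occurrences(sp, ls$components, ls$partition, 60,
                              seed = child_seed(42, 4, 1))
    filt <- filter_records(occ, ls$partition)
    filt <- filt[seq_len(min(20, nrow(filt))), ]
    ts <- make_true_locality_dataset(filt, ls$components)
    fe <- build_features(ts$covariates, ls$background)
    model <- fit_maxent(eval_features(fe, ts$covariates),
                        eval_features(fe, ls$background$covariates), fe)
    list(landscape = ls, species = sp, occ = filt, training = ts,
         features = fe, model = model)
  })
}

# constant-climate monthly fixture (every layer spatially uniform)
constant_climate <- function(temp = 10, prec = 50, n = 6) {
  spec <- grid_spec(n, n)
  mk <- function(v) replicate(12, matrix(v, n, n), simplify = FALSE)
  structure(list(spec = spec, tmax = mk(temp + 2), tmin = mk(temp - 2),
                 precip = mk(prec)),
            class = "monthly_climate")
}

# brute-force O(n^2) relative-rank oracle with half-credit ties
rr_bruteforce <- function(a, b) {
  n <- length(a)
  num <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (a[i] == a[j] || b[i] == b[j]) num <- num + 0.5
    else if ((a[i] < a[j]) == (b[i] < b[j])) num <- num + 1
  }
  num / (n * (n - 1) / 2)
}

# brute-force AUC over all presence x background pairs
auc_bruteforce <- function(pres, bg) {
  s <- 0
  for (p in pres) for (q in bg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pres) * length(bg))
}

# exact 1-D maxent objective for the golden-section oracle
maxent_obj_1d <- function(lambda, f_pres, f_bg, beta) {
  mean(f_pres) * lambda - log(sum(exp(lambda * f_bg))) - beta * abs(lambda)
}
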