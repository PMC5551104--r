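#' Configure a synthetic coarse-occurrence experiment
#'
#' Bundles every knob of the end-to-end pipeline. The master seed fully
#' determines all child seeds via `child_seed(master, stage, index)`, so any
#' single species' pipeline is reproducible in isolation.
#'
#' @param n_rows,n_cols Landscape grid dimensions.
#' @param split_frac Position of the region split as a fraction of the x
#'   extent (counties west of it form the large-county region).
#' @param mean_area_small,mean_area_large Target county areas (cells).
#' @param gradient_strength,autocorr_length,seasonal_amplitude,noise_sd
#'   Climate-generator parameters (see [generate_monthly_climate()]).
#' @param n_species Number of virtual species.
#' @param n_per_species Target post-filter record count per species; recycled
#'   to `n_species`. The sampler oversamples raw draws
#'   (`oversample * n`, capped by the positive-suitability support), applies
#'   the one-record-per-county filter, and trims to the first `n` surviving
#'   records, so modeled sample sizes are controlled the way curated record
#'   counts are (which are all post-filter).
#' @param oversample Raw-draw multiple used to reach the post-filter target
#'   (default 4).
#' @param niche_width_factor Niche SD per component axis, as a multiple of
#'   that component's landscape SD (default 1: a moderately widespread
#'   species). Narrow endemics mostly fail the >= `min_records` multi-county
#'   rule, just as they are excluded from the real analysis.
#' @param species_region Region a species is confined to: `"any"`,
#'   `"large-county region"` or `"small-county region"`. Recycled. The niche
#'   center is drawn from the region and sampling support is restricted to
#'   it (a region endemic); model evaluation still spans the whole domain.
#' @param min_records Post-filter records required to model a species.
#' @param mix_fraction Fraction converted in the 50/50 mixes.
#' @param n_bg Background sample size.
#' @param beta_multiplier,max_iter Maxent fitting controls.
#' @param cum_threshold Cumulative variance fraction for component selection.
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_rows = 120, n_cols = 120, split_frac = 0.5,
                              mean_area_small = 25, mean_area_large = 300,
                              gradient_strength = 15, autocorr_length = 8,
                              seasonal_amplitude = 10, noise_sd = 2,
                              n_species = 20, n_per_species = 20,
                              oversample = 4, niche_width_factor = 1,
                              species_region = "any",
                              min_records = 10, mix_fraction = 0.5,
                              n_bg = 4000, beta_multiplier = 1,
                              max_iter = 500, cum_threshold = 0.985,
                              seed = 1) {
  cfg <- as.list(environment())
  cfg$n_per_species <- rep_len(cfg$n_per_species, cfg$n_species)
  cfg$species_region <- rep_len(cfg$species_region, cfg$n_species)
  class(cfg) <- "experiment_config"
  cfg
}

#' Derive a child seed from the master seed
#'
#' `(master * 1000 + stage * 100 + index) mod (2^31 - 1)`, a documented pure
#' function so any stage can be rerun in isolation.
#'
#' @param master Master seed.
#' @param stage Integer stage code (1 climate, 2 counties, 3 species,
#'   4 occurrences, 5 background, 6 mixing).
#' @param index Per-species index (0 for landscape-level stages).
#' @return An integer seed.
#' @export
child_seed <- function(master, stage, index = 0) {
  as.integer((as.numeric(master) * 1000 + stage * 100 + index) %% (2^31 - 1))
}

#' Build the shared landscape of an experiment
#'
#' Generates climate, counties, bioclim variables, normalization, PCA and
#' component selection once; every species of the experiment shares the
#' result (including one seeded background sample).
#'
#' @param config An [experiment_config()].
#' @return A list with `spec`, `monthly`, `partition`, `bioclim`, `pca`,
#'   `components`, `background`, `split_x`.
#' @export
build_landscape <- function(config) {
  spec <- grid_spec(config$n_rows, config$n_cols)
  monthly <- generate_monthly_climate(
    spec, gradient_strength = config$gradient_strength,
    autocorr_length = config$autocorr_length,
    seasonal_amplitude = config$seasonal_amplitude,
    noise_sd = config$noise_sd,
    seed = child_seed(config$seed, 1))
  split_x <- spec$origin_x + config$split_frac * config$n_cols * spec$cell_size
  partition <- generate_counties(
    spec, split_x = split_x,
    mean_area_small = config$mean_area_small,
    mean_area_large = config$mean_area_large,
    seed = child_seed(config$seed, 2))
  bio <- derive_bioclim(monthly)
  norm <- normalize_layers(bio)
  pca <- fit_pca(norm)
  comps <- select_components(pca, norm, cum_threshold = config$cum_threshold)
  bg <- sample_background(comps, n_bg = config$n_bg,
                          seed = child_seed(config$seed, 5))
  list(spec = spec, monthly = monthly, partition = partition, bioclim = bio,
       pca = pca, components = comps, background = bg, split_x = split_x)
}

#' Draw a virtual species for an experiment
#'
#' The niche center is the component vector of a cell drawn uniformly from
#' the requested region; niche widths are `niche_width_factor` times each
#' component's landscape-wide SD.
#'
#' @param landscape A [build_landscape()] result.
#' @param config The [experiment_config()].
#' @param i Species index (1-based).
#' @return A [virtual_species()].
#' @export
draw_species <- function(landscape, config, i) {
  comps <- landscape$components
  region <- config$species_region[i]
  cand <- which(comps$mask & !is.na(landscape$partition$labels))
  if (region != "any") {
    ids <- landscape$partition$counties$county_id[
      landscape$partition$counties$region == region]
    cand <- cand[landscape$partition$labels[cand] %in% ids]
  }
  sdv <- apply(stack_matrix(comps), 2, stats::sd)
  sd_seed <- child_seed(config$seed, 3, i)
  center_cell <- withr::with_seed(sd_seed, sample(cand, 1))
  virtual_species(sprintf("vsp%03d", i),
                  niche_center = drop(stack_matrix(comps, center_cell)),
                  niche_width = config$niche_width_factor * sdv,
                  seed = sd_seed)
}

region_mask <- function(landscape, region) {
  if (region == "any") return(NULL)
  ids <- landscape$partition$counties$county_id[
    landscape$partition$counties$region == region]
  m <- matrix(FALSE, landscape$spec$n_rows, landscape$spec$n_cols)
  m[!is.na(landscape$partition$labels) &
      landscape$partition$labels %in% ids] <- TRUE
  m
}

run_one_species <- function(landscape, config, i) {
  sp <- draw_species(landscape, config, i)
  supp <- region_mask(landscape, config$species_region[i])
  s <- true_suitability(sp, landscape$components)
  avail <- landscape$components$mask & !is.na(landscape$partition$labels) & s > 0
  if (!is.null(supp)) avail <- avail & supp
  n_target <- config$n_per_species[i]
  n_draw <- min(config$oversample * n_target, sum(avail))
  if (n_draw < 1) return(NULL)
  occ <- sample_occurrences(sp, landscape$components, landscape$partition,
                            n = n_draw, seed = child_seed(config$seed, 4, i),
                            support_mask = supp)
  filt <- filter_records(occ, landscape$partition, min_records = config$min_records)
  if (nrow(filt) == 0) return(NULL)
  if (nrow(filt) > n_target) {
    filt <- filt[seq_len(n_target), , drop = FALSE]  # first n in database order
    if (nrow(filt) < config$min_records) return(NULL)
  }

  comps <- landscape$components
  tsets <- list(
    true_locality = make_true_locality_dataset(filt, comps),
    county_centroid = make_centroid_dataset(filt, landscape$partition, comps),
    county_average = make_county_average_dataset(filt, landscape$partition, comps))
  mixes <- make_mixed_datasets(filt, landscape$partition, comps,
                               fraction = config$mix_fraction,
                               seed = child_seed(config$seed, 6, i))
  tsets$mix_centroid <- mixes$mix_centroid
  tsets$mix_average <- mixes$mix_average

  # one feature expansion per species: it depends on the shared background
  # and the presence count, both identical across the five treatments
  fe <- build_features(tsets$true_locality$covariates, landscape$background)
  F_bg <- eval_features(fe, landscape$background$covariates)
  models <- lapply(tsets, function(ts) {
    fit_maxent(eval_features(fe, ts$covariates), F_bg, fe,
               beta_multiplier = config$beta_multiplier,
               max_iter = config$max_iter)
  })
  cmp <- compare_species(models, tsets, comps, landscape$background)
  cmp$requested_n <- config$n_per_species[i]
  cmp$region <- config$species_region[i]
  list(species = sp, occurrences = filt, comparisons = cmp,
       true_suitability = true_suitability(sp, comps))
}

#' Run the full synthetic coarse-occurrence experiment
#'
#' Simulates the landscape, then for each virtual species: samples and
#' filters occurrence records, builds the five training-data treatments,
#' fits a maxent model to each, and scores every treatment against the
#' true-locality reference. Species whose filtered records fall below
#' `min_records` are skipped and listed; non-converged fits are flagged in
#' the per-species table and excluded from aggregates.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, per-species and summary
#'   CSVs are written there (deterministic byte-identical output for a fixed
#'   config).
#' @return An object of class `experiment_report`: `per_species` table,
#'   `summary` tables (see [summarize_experiment()]), `skipped` species ids,
#'   `config`, `landscape`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  landscape <- build_landscape(config)
  rows <- list(); skipped <- character(0)
  for (i in seq_len(config$n_species)) {
    res <- tryCatch(run_one_species(landscape, config, i),
                    error = function(e)
                      stop(sprintf("species %d failed: %s", i, conditionMessage(e)),
                           call. = FALSE))
    if (is.null(res)) { skipped <- c(skipped, sprintf("vsp%03d", i)); next }
    rows[[length(rows) + 1]] <- res$comparisons
  }
  per_species <- if (length(rows)) do.call(rbind, rows) else NULL
  report <- structure(list(per_species = per_species, skipped = skipped,
                           config = config, landscape = landscape),
                      class = "experiment_report")
  report$summary <- summarize_experiment(report)
  if (!is.null(out_dir)) write_experiment(report, out_dir)
  report
}

#' Aggregate an experiment report into paper-style summary tables
#'
#' Produces the treatment-level mean/median percent area ratios per
#' threshold, mean niche-overlap statistics per treatment, paired Wilcoxon
#' signed-rank tests of each treatment against the county-centroid
#' treatment, the east/west (small- vs large-county region) median percent
#' change contrast, and the per-species sample-size vs discrepancy table.
#' Only converged fits whose species' reference fit also converged enter the
#' aggregates.
#'
#' @param report An [run_experiment()] result.
#' @return A list of data.frames: `area_ratios`, `overlap`, `tests`,
#'   `region_contrast`, `size_effect`.
#' @export
summarize_experiment <- function(report) {
  ps <- report$per_species
  if (is.null(ps) || nrow(ps) == 0) return(NULL)
  ok_ids <- names(which(tapply(ps$converged, ps$species_id, all)))
  ps <- ps[ps$species_id %in% ok_ids, , drop = FALSE]
  if (nrow(ps) == 0) return(NULL)
  trs <- setdiff(unique(ps$treatment), "true_locality")

  area_ratios <- do.call(rbind, lapply(trs, function(tr) {
    d <- ps[ps$treatment == tr, ]
    data.frame(treatment = tr,
               mean_ratio_ses_pct = 100 * mean(d$ratio_ses, na.rm = TRUE),
               mean_ratio_mtp_pct = 100 * mean(d$ratio_mtp, na.rm = TRUE),
               median_pct_change_ses = stats::median(d$pct_change_ses, na.rm = TRUE),
               median_pct_change_mtp = stats::median(d$pct_change_mtp, na.rm = TRUE),
               n_species = nrow(d))
  }))
  overlap <- do.call(rbind, lapply(trs, function(tr) {
    d <- ps[ps$treatment == tr, ]
    data.frame(treatment = tr, mean_I = mean(d$I), mean_D = mean(d$D),
               mean_RR = mean(d$RR), mean_auc = mean(d$auc))
  }))
  tests <- NULL
  cen <- ps[ps$treatment == "county_centroid", ]
  for (tr in setdiff(trs, "county_centroid")) {
    d <- ps[ps$treatment == tr, ]
    m <- match(cen$species_id, d$species_id)
    if (all(is.na(m))) next
    for (metric in c("I", "D", "RR", "auc")) {
      wt <- wilcoxon_signed_rank(d[[metric]][m], cen[[metric]])
      tests <- rbind(tests, data.frame(
        comparison = sprintf("%s vs county_centroid", tr), metric = metric,
        statistic = wt$statistic, p_value = wt$p_value, n = wt$n))
    }
  }
  region_contrast <- {
    d <- ps[ps$treatment == "county_centroid" & ps$region != "any", ]
    if (nrow(d)) do.call(rbind, lapply(split(d, d$region), function(g)
      data.frame(region = g$region[1],
                 median_abs_pct_change_mtp = stats::median(abs(g$pct_change_mtp)),
                 median_pct_change_mtp = stats::median(g$pct_change_mtp),
                 n_species = nrow(g)))) else NULL
  }
  size_effect <- {
    d <- ps[ps$treatment == "county_centroid", ]
    data.frame(species_id = d$species_id, requested_n = d$requested_n,
               n_records = d$n_records,
               abs_ratio_minus_1_mtp = abs(d$ratio_mtp - 1),
               pct_change_mtp = d$pct_change_mtp)
  }
  list(area_ratios = area_ratios, overlap = overlap, tests = tests,
       region_contrast = region_contrast, size_effect = size_effect)
}

#' @export
print.experiment_report <- function(x, ...) {
  n_sp <- if (is.null(x$per_species)) 0 else length(unique(x$per_species$species_id))
  cat(sprintf("<experiment_report> %d species modeled (%d skipped)\n",
              n_sp, length(x$skipped)))
  if (!is.null(x$summary)) {
    cat("Mean predicted-area ratio vs true localities (%):\n")
    print(x$summary$area_ratios[, c("treatment", "mean_ratio_ses_pct",
                                    "mean_ratio_mtp_pct")], row.names = FALSE)
  }
  invisible(x)
}

write_experiment <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df)) return()
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round(v, 10))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(report$per_species, "per_species.csv")
  if (!is.null(report$summary)) {
    wr(report$summary$area_ratios, "area_ratios.csv")
    wr(report$summary$overlap, "overlap.csv")
    wr(report$summary$tests, "wilcoxon_tests.csv")
    wr(report$summary$region_contrast, "region_contrast.csv")
    wr(report$summary$size_effect, "size_effect.csv")
  }
  invisible(out_dir)
}
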