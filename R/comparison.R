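#' Presence-background AUC
#'
#' Mann-Whitney rank formulation: the fraction of (presence, background)
#' prediction pairs in which the presence scores higher, ties counting one
#' half. Invariant under strictly monotone transforms of the scores, so raw
#' and logistic outputs give identical AUC.
#'
#' @param presence_pred,background_pred Numeric prediction vectors.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(presence_pred, background_pred) {
  n1 <- length(presence_pred); n2 <- length(background_pred)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(presence_pred, background_pred), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Minimum-training-presence threshold
#'
#' The lowest predicted value among the training presences; binarizing with
#' the `>=` rule at this threshold predicts every training locality present
#' (sensitivity 1 by construction).
#'
#' @param training_pred Predictions at the training presences.
#' @return The threshold.
#' @export
threshold_min_training_presence <- function(training_pred) {
  stopifnot(length(training_pred) > 0)
  min(training_pred)
}

#' Sensitivity-equals-specificity threshold
#'
#' Scans the sorted union of observed presence and background scores and
#' returns the candidate minimizing |sensitivity - specificity|, with
#' specificity computed on the background points as pseudo-negatives and the
#' `>=` suitability rule. Ties take the lower threshold.
#'
#' @param presence_pred,background_pred Numeric prediction vectors.
#' @return The threshold.
#' @export
threshold_sens_eq_spec <- function(presence_pred, background_pred) {
  if (length(presence_pred) == 0 || length(background_pred) == 0)
    stop("need both presence and background predictions")
  cand <- sort(unique(c(presence_pred, background_pred)))
  gap <- vapply(cand, function(t) {
    sens <- mean(presence_pred >= t)
    spec <- mean(background_pred < t)
    abs(sens - spec)
  }, numeric(1))
  cand[which.min(gap)]   # which.min takes the first (lowest) on ties
}

#' Predicted suitable area
#'
#' Number of masked-in cells whose predicted value is `>=` the threshold.
#' (The `>=` rule keeps the minimum-training-presence threshold's own
#' defining record predicted present.)
#'
#' @param suitability A prediction grid (matrix; `NA` outside the mask) or
#'   numeric vector.
#' @param threshold The cut-point.
#' @return Cell count.
#' @export
predicted_area <- function(suitability, threshold) {
  sum(suitability >= threshold, na.rm = TRUE)
}

#' Overprediction ratio of a treatment model against the reference
#'
#' @param area_treatment,area_true Predicted areas in cells.
#' @return A list with `ratio` and `percent_change` (`ratio * 100 - 100`);
#'   both `NA` (with a warning) when the reference area is zero.
#' @export
area_ratio <- function(area_treatment, area_true) {
  if (area_true == 0) {
    warning("reference predicted area is zero; ratio undefined")
    return(list(ratio = NA_real_, percent_change = NA_real_))
  }
  r <- area_treatment / area_true
  list(ratio = r, percent_change = r * 100 - 100)
}

normalize_surface <- function(g) {
  v <- if (is.matrix(g)) g[!is.na(g)] else g[!is.na(g)]
  s <- sum(v)
  if (s <= 0) stop("cannot normalize a nonpositive surface")
  v / s
}

#' Schoener's D niche overlap between two suitability surfaces
#'
#' Both surfaces are normalized to sum 1 over the shared mask; then
#' `D = 1 - 0.5 * sum |pA - pB|`. 1 for identical surfaces, 0 for disjoint
#' support.
#'
#' @param gridA,gridB Suitability grids (same mask) or numeric vectors.
#' @return D in \[0, 1\].
#' @export
schoener_D <- function(gridA, gridB) {
  pa <- normalize_surface(gridA); pb <- normalize_surface(gridB)
  stopifnot(length(pa) == length(pb))
  1 - 0.5 * sum(abs(pa - pb))
}

#' Hellinger-based similarity statistic I
#'
#' `I = 1 - 0.5 * sum (sqrt(pA) - sqrt(pB))^2` on mask-normalized surfaces;
#' equals the Hellinger affinity `sum sqrt(pA * pB)`. Always `>= D`.
#'
#' @inheritParams schoener_D
#' @return I in \[0, 1\].
#' @export
similarity_I <- function(gridA, gridB) {
  pa <- normalize_surface(gridA); pb <- normalize_surface(gridB)
  stopifnot(length(pa) == length(pb))
  1 - 0.5 * sum((sqrt(pa) - sqrt(pb))^2)
}

#' Relative rank agreement between two suitability surfaces
#'
#' The probability that a random unordered pair of cells is ranked the same
#' way by both surfaces; pairs tied in either surface count one half.
#' Computed exactly in O(n log n) by merge-sort inversion counting.
#'
#' @inheritParams schoener_D
#' @return RR in \[0, 1\].
#' @export
relative_rank <- function(gridA, gridB) {
  a <- if (is.matrix(gridA)) gridA[!is.na(gridA)] else gridA[!is.na(gridA)]
  b <- if (is.matrix(gridB)) gridB[!is.na(gridB)] else gridB[!is.na(gridB)]
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  total <- n * (n - 1) / 2
  tie_pairs <- function(codes) {
    t <- tabulate(codes); sum(t * (t - 1) / 2)
  }
  ga <- match(a, unique(a))           # exact double comparison, no rounding
  gb <- match(b, unique(b))
  ta <- tie_pairs(ga); tb <- tie_pairs(gb)
  tab <- tie_pairs(match(ga * (max(gb) + 1) + gb, unique(ga * (max(gb) + 1) + gb)))
  o <- order(a, b)
  disc <- count_inversions_cpp(b[o])
  tied_either <- ta + tb - tab
  concordant <- total - tied_either - disc
  (concordant + 0.5 * tied_either) / total
}

#' Two-sided Wilcoxon signed-rank test for paired model metrics
#'
#' Drops zero differences; exact distribution when 25 or fewer nonzero pairs
#' remain and there are no rank ties, normal approximation otherwise. Returns
#' `p = 1` by convention when every difference is zero.
#'
#' @param a,b Paired numeric vectors (one entry per species).
#' @return A list with `statistic` (V, sum of positive ranks), `p_value`,
#'   and `n` (nonzero pairs used).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0 & !is.na(d)]
  if (length(d) == 0) return(list(statistic = NA_real_, p_value = 1, n = 0L))
  has_ties <- any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(
    d, exact = (length(d) <= 25 && !has_ties), correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = length(d))
}

#' Compare one species' treatment models against its true-locality model
#'
#' Computes, for every fitted treatment, AUC (training presences vs the
#' shared background), both thresholds on the logistic output, thresholded
#' predicted areas, area ratios against the true-locality reference, and the
#' niche-overlap statistics D, I and RR on the mask-normalized raw surfaces.
#'
#' @param models Named list of `maxent_model`s; must include
#'   `"true_locality"`.
#' @param training_sets Named list of `training_set`s matching `models`.
#' @param components The [env_stack()] of covariate grids.
#' @param background The shared [sample_background()].
#' @return A data.frame (class `species_comparison`), one row per treatment.
#' @export
compare_species <- function(models, training_sets, components, background) {
  stopifnot("true_locality" %in% names(models))
  ref <- "true_locality"
  # all treatments of one species usually share one feature expansion (it
  # depends only on the background and the presence count); evaluate the
  # expensive grid/background feature matrices once in that case
  shared <- all(vapply(models, function(m)
    identical(m$features, models[[1]]$features), logical(1)))
  cells <- which(components$mask)
  to_grid <- function(v) {
    g <- matrix(NA_real_, components$spec$n_rows, components$spec$n_cols)
    g[cells] <- v
    g
  }
  logistic <- function(raw, m) {
    q <- m$tau * exp(m$H + log(pmax(raw, 1e-300)))
    q / (1 + q)
  }
  if (shared) {
    F_grid <- eval_features(models[[1]]$features, stack_matrix(components, cells))
    F_bg <- eval_features(models[[1]]$features, background$covariates)
  }
  raw_grid <- lapply(models, function(m) {
    if (shared) to_grid(exp(drop(F_grid %*% m$lambda) - m$logZ))
    else predict_raw(m, components)
  })
  log_grid <- lapply(names(models), function(tr) {
    g <- raw_grid[[tr]]
    g[cells] <- logistic(g[cells], models[[tr]])
    g
  })
  names(log_grid) <- names(models)

  per_treatment <- lapply(names(models), function(tr) {
    m <- models[[tr]]
    f_pres <- eval_features(m$features, training_sets[[tr]]$covariates)
    pres_raw <- exp(drop(f_pres %*% m$lambda) - m$logZ)
    pres_log <- logistic(pres_raw, m)
    f_bg <- if (shared) F_bg else eval_features(m$features, background$covariates)
    bg_raw <- exp(drop(f_bg %*% m$lambda) - m$logZ)
    bg_log <- logistic(bg_raw, m)

    auc <- compute_auc(pres_log, bg_log)
    th_mtp <- threshold_min_training_presence(pres_log)
    th_ses <- threshold_sens_eq_spec(pres_log, bg_log)
    area_mtp <- predicted_area(log_grid[[tr]], th_mtp)
    area_ses <- predicted_area(log_grid[[tr]], th_ses)
    data.frame(
      species_id = training_sets[[tr]]$species_id, treatment = tr,
      n_records = nrow(training_sets[[tr]]$records),
      auc = auc, threshold_mtp = th_mtp, threshold_ses = th_ses,
      area_mtp = area_mtp, area_ses = area_ses,
      converged = m$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_treatment)
  ref_row <- out[out$treatment == ref, ]
  rat_mtp <- lapply(out$area_mtp, area_ratio, area_true = ref_row$area_mtp)
  rat_ses <- lapply(out$area_ses, area_ratio, area_true = ref_row$area_ses)
  out$ratio_mtp <- vapply(rat_mtp, `[[`, numeric(1), "ratio")
  out$ratio_ses <- vapply(rat_ses, `[[`, numeric(1), "ratio")
  out$pct_change_mtp <- vapply(rat_mtp, `[[`, numeric(1), "percent_change")
  out$pct_change_ses <- vapply(rat_ses, `[[`, numeric(1), "percent_change")
  out$D <- vapply(names(models), function(tr)
    schoener_D(raw_grid[[tr]], raw_grid[[ref]]), numeric(1))
  out$I <- vapply(names(models), function(tr)
    similarity_I(raw_grid[[tr]], raw_grid[[ref]]), numeric(1))
  out$RR <- vapply(names(models), function(tr)
    relative_rank(raw_grid[[tr]], raw_grid[[ref]]), numeric(1))
  rownames(out) <- NULL
  class(out) <- c("species_comparison", "data.frame")
  out
}
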