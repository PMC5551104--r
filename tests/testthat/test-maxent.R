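test_that("background sampling is uniform over the masked cells", {
  ls <- tiny_landscape()
  bg <- sample_background(ls$components, n_bg = 800, seed = 3)
  expect_length(bg$cells, 800)
  expect_true(all(ls$components$mask[bg$cells]))
  expect_false(any(duplicated(bg$cells)))
  expect_identical(bg, sample_background(ls$components, 800, seed = 3))
  # asking for more cells than exist returns every masked cell
  all_bg <- sample_background(ls$components, n_bg = 1e7, seed = 1)
  expect_equal(all_bg$cells, which(ls$components$mask))
  # uniformity: chi-square on quadrant counts pooled over seeds
  spec <- ls$components$spec
  nc <- spec$n_rows * spec$n_cols
  row_of <- (seq_len(nc) - 1L) %% spec$n_rows + 1L
  col_of <- (seq_len(nc) - 1L) %/% spec$n_rows + 1L
  quad <- (row_of > spec$n_rows / 2) + 2 * (col_of > spec$n_cols / 2)
  counts <- rep(0, 4)
  for (s in 1:20) {
    cl <- sample_background(ls$components, 400, seed = 100 + s)$cells
    counts <- counts + tabulate(quad[cl] + 1, 4)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("feature classes unlock with presence sample size", {
  ls <- tiny_landscape()
  bg <- ls$background
  z <- bg$covariates[1:100, , drop = FALSE]
  cls_at <- function(n) build_features(z[seq_len(n), , drop = FALSE], bg)$classes
  expect_setequal(cls_at(10), c("linear", "quadratic"))
  expect_setequal(cls_at(14), c("linear", "quadratic"))
  expect_setequal(cls_at(15), c("linear", "quadratic", "hinge"))
  expect_setequal(cls_at(79), c("linear", "quadratic", "hinge"))
  expect_setequal(cls_at(80), c("linear", "quadratic", "hinge", "product"))
  # explicit override wins
  fe <- build_features(z, bg, classes = c("linear"))
  expect_equal(length(fe$defs), ncol(z))
  # feature counts: k linear + k quadratic + 2 * 20 * k hinge + choose(k,2)
  k <- ncol(z)
  fe_all <- build_features(z, bg)
  expect_equal(length(fe_all$defs), 2 * k + 40 * k + choose(k, 2))
})

test_that("scaled features lie in [0,1] on the background and clamp outside it", {
  ls <- tiny_landscape()
  bg <- ls$background
  fe <- build_features(bg$covariates[1:20, ], bg)
  Fb <- eval_features(fe, bg$covariates)
  expect_gte(min(Fb), 0); expect_lte(max(Fb), 1)
  # each feature attains both endpoints on the background (its own scaling)
  expect_equal(unname(apply(Fb, 2, min)), rep(0, ncol(Fb)))
  expect_equal(unname(apply(Fb, 2, max)), rep(1, ncol(Fb)))
  # far out-of-range covariates are clamped, not extrapolated
  zx <- matrix(100, 2, ncol(bg$covariates))
  Fx <- eval_features(fe, zx)
  expect_true(all(Fx >= 0 & Fx <= 1))
})

test_that("a presence sample identical to the background yields the null model", {
  ls <- tiny_landscape()
  bg <- ls$background
  fe <- build_features(bg$covariates, bg, n_presence = 14)  # linear + quadratic
  Fb <- eval_features(fe, bg$covariates)
  m <- fit_maxent(Fb, Fb, fe)
  # presence means equal background means exactly, so lambda = 0 everywhere
  expect_equal(m$lambda, rep(0, ncol(Fb)))
  expect_true(m$converged)
  # the null model's raw output is uniform; logistic = tau/(1+tau) = 1/3
  pr <- predict_raw(m, bg$covariates[1:5, , drop = FALSE])
  expect_equal(pr, rep(1 / nrow(Fb), 5))
  pl <- predict_logistic(m, bg$covariates[1:5, , drop = FALSE])
  expect_equal(pl, rep(1 / 3, 5), tolerance = 1e-10)
})

test_that("a single-feature fit matches an independent golden-section oracle", {
  ls <- tiny_landscape()
  bg <- ls$background
  set.seed(8)
  # presences biased toward high values of covariate 1
  w <- exp(2 * scale(bg$covariates[, 1]))
  pres <- bg$covariates[sample(nrow(bg$covariates), 40, prob = w), , drop = FALSE]
  fe <- build_features(pres[, 1, drop = FALSE],
                       structure(list(cells = bg$cells,
                                      covariates = bg$covariates[, 1, drop = FALSE],
                                      seed = 1L), class = "background_sample"),
                       classes = "linear")
  f_pres <- eval_features(fe, pres[, 1, drop = FALSE])
  f_bg <- eval_features(fe, bg$covariates[, 1, drop = FALSE])
  m <- fit_maxent(f_pres, f_bg, fe)
  expect_true(m$converged)
  # independent 1-D maximization of the same objective by golden section
  gold <- stats::optimize(function(l) maxent_obj_1d(l, f_pres[, 1], f_bg[, 1],
                                                    m$beta[1]),
                          interval = c(-50, 50), maximum = TRUE)$maximum
  expect_equal(m$lambda[1], gold, tolerance = 1e-4)
  # sign oracle: presence mean exceeds background mean, so lambda > 0
  expect_gt(mean(f_pres[, 1]), mean(f_bg[, 1]))
  expect_gt(m$lambda[1], 0)
})

test_that("fitted models satisfy the KKT stationarity conditions", {
  fit <- tiny_fit()
  m <- fit$model
  ls <- fit$landscape
  Fb <- eval_features(m$features, ls$background$covariates)
  Fp <- eval_features(m$features, fit$training$covariates)
  w <- exp(drop(Fb %*% m$lambda)); w <- w / sum(w)
  mp <- colMeans(Fp)
  Ef <- drop(t(Fb) %*% w)
  g <- mp - Ef
  viol <- ifelse(m$lambda == 0,
                 pmax(0, abs(g) - m$beta),
                 abs(g - sign(m$lambda) * m$beta))
  expect_lt(max(viol), 1e-3)
})

test_that("the concave fit is initialization-invariant", {
  # the solver is tightened here because nearly-collinear hinge features make
  # the weights identifiable only to about the KKT tolerance; what must be
  # invariant is the fitted distribution, not the raw weight vector
  fit <- tiny_fit()
  ls <- fit$landscape
  fe <- fit$features
  Fp <- eval_features(fe, fit$training$covariates)
  Fb <- eval_features(fe, ls$background$covariates)
  strict <- function(init) fit_maxent(Fp, Fb, fe, tol = 1e-9, max_iter = 5000,
                                      kkt_tol = 1e-6, lambda_init = init)
  m1 <- strict(NULL)
  set.seed(12)
  m2 <- strict(runif(ncol(Fp), -0.5, 0.5))
  expect_true(m1$converged && m2$converged)
  p1 <- predict_logistic(m1, ls$background$covariates)
  p2 <- predict_logistic(m2, ls$background$covariates)
  expect_lt(max(abs(p1 - p2)), 1e-4)
  expect_lt(abs(m1$objective - m2$objective), 1e-8)
  expect_equal(m2$lambda, m1$lambda, tolerance = 1e-2)
})

test_that("raw predictions normalize over the background and rank-match logistic", {
  fit <- tiny_fit()
  ls <- fit$landscape
  raw_bg <- predict_raw(fit$model, ls$background$covariates)
  expect_equal(sum(raw_bg), 1, tolerance = 1e-9)
  expect_true(all(raw_bg > 0))
  log_bg <- predict_logistic(fit$model, ls$background$covariates)
  expect_true(all(log_bg > 0 & log_bg < 1))
  expect_equal(order(raw_bg), order(log_bg))
  # grid prediction carries the mask
  g <- predict_raw(fit$model, ls$components)
  expect_equal(dim(g), c(ls$spec$n_rows, ls$spec$n_cols))
  expect_equal(is.na(g), !ls$components$mask)
})

test_that("regularization interpolation matches the published class tables", {
  expect_equal(unname(coarsesdm:::class_beta("linear", 5)), 1)
  expect_equal(unname(coarsesdm:::class_beta("quadratic", 10)), 1)
  expect_equal(unname(coarsesdm:::class_beta("linear", 20)), 0.6)     # midpoint of 1 .. 0.2
  expect_equal(unname(coarsesdm:::class_beta("linear", 30)), 0.2)
  expect_equal(unname(coarsesdm:::class_beta("linear", 65)), 0.125)
  expect_equal(unname(coarsesdm:::class_beta("linear", 1000)), 0.05)  # constant extrapolation
  expect_equal(unname(coarsesdm:::class_beta("product", 17)), 1.6)
  expect_equal(unname(coarsesdm:::class_beta("product", 23.5)), 1.25)
  expect_equal(unname(coarsesdm:::class_beta("hinge", 7)), 0.5)
  expect_equal(unname(coarsesdm:::class_beta("hinge", 500)), 0.5)
})

test_that("the model recovers a strong virtual niche (quadratic features, n = 300)", {
  ls <- tiny_landscape()
  cfg <- tiny_config(n_species = 1)
  sp <- draw_species(ls, cfg, 1)
  occ <- sample_occurrences(sp, ls$components, ls$partition, 300, seed = 21)
  ts <- make_true_locality_dataset(occ, ls$components)
  fe <- build_features(ts$covariates, ls$background,
                       classes = c("linear", "quadratic"))
  m <- fit_maxent(eval_features(fe, ts$covariates),
                  eval_features(fe, ls$background$covariates), fe)
  expect_true(m$converged)
  pred <- predict_logistic(m, ls$components)
  s <- true_suitability(sp, ls$components)
  msk <- ls$components$mask
  r <- stats::cor(pred[msk], s[msk])
  expect_gt(r, 0.8)
})

test_that("generalization improves monotonically with sample size", {
  # frozen from a 20-replicate measurement: Spearman correlation with the
  # true suitability surface rose with n in every replicate from 10 to 100
  ls <- tiny_landscape()
  cfg <- tiny_config(n_species = 4)
  for (rep in 1:4) {
    sp <- draw_species(ls, cfg, rep)
    rho <- vapply(c(10, 100), function(n) {
      occ <- sample_occurrences(sp, ls$components, ls$partition, n,
                                seed = 9000 + rep * 10 + n)
      ts <- make_true_locality_dataset(occ, ls$components)
      fe <- build_features(ts$covariates, ls$background)
      m <- suppressWarnings(fit_maxent(eval_features(fe, ts$covariates),
                                       eval_features(fe, ls$background$covariates),
                                       fe))
      pr <- predict_raw(m, ls$components)
      s <- true_suitability(sp, ls$components)
      stats::cor(pr[ls$components$mask], s[ls$components$mask],
                 method = "spearman")
    }, numeric(1))
    expect_gt(rho[2], rho[1])
  }
})
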