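#' Fit an L1-regularized maximum-entropy distribution model
#'
#' Fits the Gibbs distribution over background cells that maximizes the
#' regularized presence log-likelihood
#' `mean_presence(eta) - log Z - sum_j beta_j |lambda_j|`,
#' where `eta = lambda . f(cell)` and `Z = sum_bg exp(eta)`. Per-feature
#' regularization follows the classic maxent rule
#' `beta_j = beta_multiplier * class_default(n) * SD_presence(f_j) / sqrt(n)`
#' with the published class-default interpolation tables (linear/quadratic:
#' 1.0 at n <= 10 down to 0.05 at n >= 100; product: 2.6 down to 0.55;
#' hinge: 0.5). The class-scaled deviation is floored at 0.001 times the
#' feature range and, for hinge features, at `0.5/sqrt(n)`, so features
#' absent from the presence sample remain penalized instead of driving
#' their weights to minus infinity.
#'
#' Optimization is cyclic coordinate descent with soft-thresholding; the
#' objective is concave, so the fit is initialization-invariant. Convergence
#' requires both a relative objective change below `tol` and Karush-Kuhn-
#' Tucker stationarity (`|presence mean - model expectation|` within
#' `beta_j`) on every feature.
#'
#' @param presence_features Scaled feature matrix of the presences (n x p),
#'   from [eval_features()].
#' @param background_features Scaled feature matrix of the background.
#' @param feature_expansion The [build_features()] object (stored for
#'   prediction).
#' @param beta_multiplier Global regularization multiplier (default 1).
#' @param tol Relative objective-change convergence tolerance (default 1e-5).
#' @param max_iter Maximum coordinate-descent cycles (default 500).
#' @param lambda_init Optional initial weights (default zeros).
#' @param kkt_tol Maximum allowed Karush-Kuhn-Tucker stationarity violation
#'   (default 1e-4); tighten it when bit-level reproducibility of the weights
#'   across initializations matters more than speed.
#' @return An object of class `maxent_model`: feature weights `lambda`, the
#'   expansion, `beta`, log-normalizer pieces, entropy `H` of the fitted raw
#'   distribution over the background, `converged` flag, and `tau` (the
#'   prevalence assumed by the logistic output, default 0.5).
#' @export
fit_maxent <- function(presence_features, background_features, feature_expansion,
                       beta_multiplier = 1, tol = 1e-5, max_iter = 500,
                       lambda_init = NULL, kkt_tol = 1e-4) {
  n <- nrow(presence_features)
  if (n < 1) stop("no presences")
  p <- ncol(presence_features)
  stopifnot(ncol(background_features) == p)
  mp <- colMeans(presence_features)
  sdp <- sqrt(pmax(colMeans(presence_features^2) - mp^2, 0))
  cls <- vapply(feature_expansion$defs, `[[`, character(1), "type")
  # deviation floored at 0.001 * feature range (= 1 after scaling), and at
  # 0.5/sqrt(n) for hinge features, so features unseen at the presences stay
  # penalized instead of diverging
  min_dev <- ifelse(cls == "hinge", 0.5 / sqrt(n), 0.001)
  beta <- beta_multiplier * pmax(class_beta(cls, n) * sdp, min_dev) / sqrt(n)
  if (is.null(lambda_init)) lambda_init <- numeric(p)
  fit <- ccd_fit(background_features, mp, beta, lambda_init,
                 tol = tol, max_iter = max_iter, kkt_tol = kkt_tol)
  if (!fit$converged)
    warning(sprintf("maxent fit did not converge in %d cycles", max_iter))
  lambda <- as.numeric(fit$lambda)
  eta_bg <- drop(background_features %*% lambda)
  shift <- max(eta_bg)
  w <- exp(eta_bg - shift)
  logZ <- log(sum(w)) + shift
  raw_bg <- w / sum(w)
  H <- -sum(raw_bg * log(pmax(raw_bg, 1e-300)))
  structure(list(lambda = lambda, features = feature_expansion, beta = beta,
                 logZ = logZ, H = H, n_presence = n,
                 n_background = nrow(background_features),
                 converged = fit$converged, iterations = fit$iterations,
                 objective = fit$objective, tau = 0.5),
            class = "maxent_model")
}

# maxent 3.3.3k default regularization tables, linearly interpolated in the
# presence sample size with constant extrapolation
class_beta <- function(classes, n) {
  interp <- function(xs, ys) stats::approx(xs, ys, xout = n, rule = 2)$y
  lq <- interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05))
  pr <- interp(c(0, 10, 17, 30, 100), c(2.6, 2.6, 1.6, 0.9, 0.55))
  vapply(classes, function(cl) switch(cl,
    linear = lq, quadratic = lq, product = pr, hinge = 0.5), numeric(1))
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features (%d active), n = %d presences, %d background; H = %.3f%s\n",
              length(x$lambda), sum(x$lambda != 0), x$n_presence,
              x$n_background, x$H,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Predict the raw (Gibbs) output of a maxent model
#'
#' `raw(cell) = exp(eta(cell)) / Z` with `Z` the normalizer over the
#' background sample, so raw values sum to 1 over the background cells.
#'
#' @param model A [fit_maxent()] result.
#' @param components An [env_stack()] of covariate grids, or a covariate
#'   matrix (rows = arbitrary covariate vectors).
#' @return A matrix grid of raw values (for a stack) or a numeric vector
#'   (for a covariate matrix).
#' @export
predict_raw <- function(model, components) {
  if (inherits(components, "env_stack")) {
    cells <- which(components$mask)
    z <- stack_matrix(components, cells)
    v <- predict_raw(model, z)
    out <- matrix(NA_real_, components$spec$n_rows, components$spec$n_cols)
    out[cells] <- v
    return(out)
  }
  f <- eval_features(model$features, components)
  exp(drop(f %*% model$lambda) - model$logZ)
}

#' Predict the logistic output of a maxent model
#'
#' The monotone transform `tau * exp(H) * raw / (1 + tau * exp(H) * raw)`
#' calibrated by an assumed prevalence `tau` (default 0.5, the conventional
#' default). Rank-identical to the raw output.
#'
#' @inheritParams predict_raw
#' @param tau Assumed prevalence in (0, 1).
#' @return Same shape as [predict_raw()], values in (0, 1).
#' @export
predict_logistic <- function(model, components, tau = model$tau) {
  r <- predict_raw(model, components)
  # exp(H) * raw computed in log space for numerical safety
  le <- model$H + log(pmax(r, 1e-300))
  q <- tau * exp(le)
  out <- q / (1 + q)
  out[is.na(r)] <- NA_real_
  out
}
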