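#' Sample background cells
#'
#' Draws `n_bg` cells uniformly without replacement from the masked-in cells
#' (all of them if the mask is smaller than `n_bg`). Presence cells are not
#' excluded: the background represents the available environment.
#'
#' @param components An [env_stack()] of covariate grids.
#' @param n_bg Target number of background cells (default 10000).
#' @param seed Integer seed.
#' @return A list (class `background_sample`) with `cells` (linear indices),
#'   `covariates` (n_bg x k matrix), `seed`.
#' @export
sample_background <- function(components, n_bg = 10000, seed = 1) {
  cells <- which(components$mask)
  take <- withr::with_seed(seed, {
    if (length(cells) <= n_bg) cells else sort(sample(cells, n_bg))
  })
  structure(list(cells = take, covariates = stack_matrix(components, take),
                 seed = as.integer(seed)),
            class = "background_sample")
}

#' Build the maxent feature expansion
#'
#' Feature classes unlock with presence sample size, following the
#' auto-feature defaults of classic maxent: linear and quadratic always,
#' hinge from 15 presences, product (pairwise interactions) from 80. Hinge
#' features use a fixed grid of `n_knots` equally spaced knots per covariate
#' over the background range, in both orientations. Every feature is scaled
#' by its background min/max to [0, 1]; values outside the background range
#' are clamped.
#'
#' @param training_covariates Presence covariate matrix (n x k).
#' @param background A [sample_background()] result.
#' @param n_presence Presence count used for the class rules (default:
#'   `nrow(training_covariates)`).
#' @param classes Optional character vector overriding the automatic class
#'   rules (subset of `c("linear", "quadratic", "product", "hinge")`).
#' @param n_knots Hinge knots per covariate per orientation (default 20).
#' @return An object of class `feature_expansion`.
#' @export
build_features <- function(training_covariates, background,
                           n_presence = nrow(training_covariates),
                           classes = NULL, n_knots = 20) {
  k <- ncol(background$covariates)
  if (k == 0) stop("no covariates")
  if (is.null(classes)) {
    classes <- c("linear", "quadratic")
    if (n_presence >= 15) classes <- c(classes, "hinge")
    if (n_presence >= 80) classes <- c(classes, "product")
  }
  rng <- apply(background$covariates, 2, range)
  defs <- list()
  add <- function(type, i1, i2 = NA_integer_, knot = NA_real_, dir = NA_integer_)
    defs[[length(defs) + 1]] <<- list(type = type, i1 = i1, i2 = i2,
                                      knot = knot, dir = dir)
  if ("linear" %in% classes) for (i in 1:k) add("linear", i)
  if ("quadratic" %in% classes) for (i in 1:k) add("quadratic", i)
  if ("product" %in% classes && k >= 2)
    for (i in 1:(k - 1)) for (j in (i + 1):k) add("product", i, j)
  if ("hinge" %in% classes) {
    for (i in 1:k) {
      knots <- seq(rng[1, i], rng[2, i], length.out = n_knots + 2)[2:(n_knots + 1)]
      for (kn in knots) { add("hinge", i, knot = kn, dir = 1L)
                          add("hinge", i, knot = kn, dir = -1L) }
    }
  }
  fe <- structure(list(defs = defs, range = rng, classes = classes,
                       k = k, n_knots = n_knots),
                  class = "feature_expansion")
  # raw feature values on the background fix the [0,1] scaling
  raw_bg <- eval_features_raw(fe, background$covariates)
  fmin <- apply(raw_bg, 2, min); fmax <- apply(raw_bg, 2, max)
  span <- fmax - fmin
  span[span == 0] <- 1
  fe$fmin <- fmin; fe$fspan <- span
  fe
}

#' @export
print.feature_expansion <- function(x, ...) {
  cat(sprintf("<feature_expansion> %d features over %d covariates (%s)\n",
              length(x$defs), x$k, paste(x$classes, collapse = ", ")))
  invisible(x)
}

eval_features_raw <- function(fe, z) {
  n <- nrow(z)
  out <- matrix(0, n, length(fe$defs))
  for (j in seq_along(fe$defs)) {
    d <- fe$defs[[j]]
    out[, j] <- switch(d$type,
      linear = z[, d$i1],
      quadratic = z[, d$i1]^2,
      product = z[, d$i1] * z[, d$i2],
      hinge = if (d$dir > 0) pmax(0, z[, d$i1] - d$knot)
              else pmax(0, d$knot - z[, d$i1]))
  }
  out
}

#' Evaluate scaled features for arbitrary covariate rows
#'
#' @param fe A [build_features()] result.
#' @param z Covariate matrix (n x k).
#' @return n x p feature matrix, each column in \[0, 1\] on the background
#'   (out-of-range inputs clamped).
#' @export
eval_features <- function(fe, z) {
  raw <- eval_features_raw(fe, z)
  f <- sweep(sweep(raw, 2, fe$fmin), 2, fe$fspan, `/`)
  f[f < 0] <- 0; f[f > 1] <- 1
  f
}
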