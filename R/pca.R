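#' Principal component analysis of an environmental stack
#'
#' Eigendecomposition of the layer-by-layer *population* covariance matrix
#' computed over masked-in cells. Components are ordered by descending
#' eigenvalue; the sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param env A normalized [env_stack()] (see [normalize_layers()]).
#' @return An object of class `pca_model`: `loadings` (layers x components,
#'   orthonormal columns), `eigenvalues`, `variance_fractions`, and the
#'   normalization constants `layer_means` / `layer_sds` carried over from the
#'   input when present.
#' @export
fit_pca <- function(env) {
  z <- stack_matrix(env)
  if (nrow(z) <= ncol(z))
    stop("need more masked-in cells than layers for a PCA")
  mu <- colMeans(z)
  zc <- sweep(z, 2, mu)
  covm <- crossprod(zc) / nrow(zc)          # population covariance
  eg <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- names(env$layers)
  colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  structure(list(loadings = vecs, eigenvalues = vals,
                 variance_fractions = vals / sum(vals),
                 center = mu,
                 layer_means = attr(env, "layer_means"),
                 layer_sds = attr(env, "layer_sds")),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  vf <- x$variance_fractions
  cat(sprintf("<pca_model> %d components; variance explained: PC1 %.1f%%, first 3 %.1f%%\n",
              length(vf), 100 * vf[1], 100 * sum(vf[seq_len(min(3, length(vf)))])))
  invisible(x)
}

#' Project a stack onto its leading principal components
#'
#' Keeps the smallest number of components whose cumulative variance fraction
#' reaches `cum_threshold` and returns the projected component grids, which
#' serve as the background environmental layers for distribution modeling.
#'
#' @param model A [fit_pca()] result.
#' @param env The normalized [env_stack()] the model was fitted to (or a
#'   compatible one).
#' @param cum_threshold Cumulative variance fraction to retain (default
#'   0.985).
#' @return An [env_stack()] of `k` component grids named `PC1` ... `PCk`.
#' @export
select_components <- function(model, env, cum_threshold = 0.985) {
  stopifnot(cum_threshold > 0, cum_threshold <= 1)
  cum <- cumsum(model$variance_fractions)
  nonzero <- sum(model$eigenvalues > .Machine$double.eps * max(model$eigenvalues))
  k <- which(cum >= cum_threshold - 1e-12)[1]
  if (is.na(k)) k <- nonzero
  k <- min(k, nonzero)
  cells <- which(env$mask)
  z <- sweep(stack_matrix(env, cells), 2, model$center)
  scores <- z %*% model$loadings[, seq_len(k), drop = FALSE]
  layers <- lapply(seq_len(k), function(j) {
    m <- matrix(NA_real_, env$spec$n_rows, env$spec$n_cols)
    m[cells] <- scores[, j]
    m
  })
  names(layers) <- paste0("PC", seq_len(k))
  out <- env_stack(layers, env$spec, env$mask)
  attr(out, "eigenvalues") <- model$eigenvalues[seq_len(k)]
  attr(out, "weights") <- model$eigenvalues[seq_len(k)] / sum(model$eigenvalues)
  out
}
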