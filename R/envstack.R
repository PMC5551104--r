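#' Build a stack of co-registered environmental layers
#'
#' @param layers Named list of numeric matrices sharing one [grid_spec()].
#' @param spec The shared [grid_spec()].
#' @param mask Logical matrix of valid cells (default: all cells with finite
#'   values in every layer). All statistics downstream are computed over
#'   masked-in cells only.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, spec, mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  for (nm in names(layers))
    stopifnot(nrow(layers[[nm]]) == spec$n_rows, ncol(layers[[nm]]) == spec$n_cols)
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, is.finite))
  }
  structure(list(layers = layers, spec = spec, mask = mask), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s%s) on %d x %d grid, %d masked-in cells\n",
              length(x$layers),
              paste(utils::head(names(x$layers), 4), collapse = ", "),
              if (length(x$layers) > 4) ", ..." else "",
              x$spec$n_rows, x$spec$n_cols, sum(x$mask)))
  invisible(x)
}

#' Extract the cell-by-layer matrix of an env_stack
#'
#' @param env An [env_stack()].
#' @param cells Linear cell indices (default: all masked-in cells).
#' @return Numeric matrix, one row per cell, one column per layer.
#' @export
stack_matrix <- function(env, cells = NULL) {
  if (is.null(cells)) cells <- which(env$mask)
  m <- vapply(env$layers, function(l) l[cells], numeric(length(cells)))
  if (length(cells) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(env$layers)))
  colnames(m) <- names(env$layers)
  m
}

#' Center and scale layers to zero mean and unit SD
#'
#' Each layer is normalized over the masked-in cell population: the mask-wide
#' mean is subtracted and the result divided by the mask-wide *population*
#' standard deviation (divide by N, the raster-statistics convention).
#' Normalization constants are recorded in attributes `layer_means` and
#' `layer_sds` for reuse on new data.
#'
#' @param env An [env_stack()].
#' @return A normalized `env_stack`; every layer has mean 0 and SD 1 over the
#'   mask to within 1e-9.
#' @export
normalize_layers <- function(env) {
  cells <- which(env$mask)
  means <- sds <- numeric(length(env$layers))
  names(means) <- names(sds) <- names(env$layers)
  out <- env$layers
  for (nm in names(env$layers)) {
    v <- env$layers[[nm]][cells]
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    if (sd_pop == 0)
      stop(sprintf("layer '%s' is constant over the mask (SD = 0)", nm))
    means[nm] <- mu; sds[nm] <- sd_pop
    l <- env$layers[[nm]]
    l[] <- (l - mu) / sd_pop
    out[[nm]] <- l
  }
  res <- env_stack(out, env$spec, env$mask)
  attr(res, "layer_means") <- means
  attr(res, "layer_sds") <- sds
  res
}
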