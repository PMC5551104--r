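#' County climate representativeness: centroid-vs-mean offset
#'
#' For each county, sums over component layers the absolute difference
#' between the component value at the county centroid cell and the mean
#' component value across the county, weighting component `k` by its
#' eigenvalue fraction `lambda_k / sum(lambda)`. Large values flag counties
#' whose geographic center is climatically unrepresentative of the county —
#' exactly the situation in which centroid-georeferenced records mislead a
#' distribution model.
#'
#' @param components An [env_stack()] of component grids from
#'   [select_components()] (carries eigenvalue weights), or any stack if
#'   `weights` is supplied.
#' @param partition A [generate_counties()] result.
#' @param weights Optional per-layer weights; default: the eigenvalue
#'   fractions attached to `components`.
#' @return A data.frame with `county_id`, `offset_metric` (>= 0).
#' @export
county_climate_offset <- function(components, partition, weights = NULL) {
  w <- component_weights(components, weights)
  cells_by <- county_cells(partition)
  cen <- centroid_cells(partition)
  z_cen <- stack_matrix(components, cen[names(cells_by)])
  off <- vapply(seq_along(cells_by), function(i) {
    z <- stack_matrix(components, cells_by[[i]])
    if (anyNA(z)) z <- z[stats::complete.cases(z), , drop = FALSE]
    if (nrow(z) == 0) stop(sprintf("county %s has no masked-in cells", names(cells_by)[i]))
    sum(w * abs(z_cen[i, ] - colMeans(z)))
  }, numeric(1))
  data.frame(county_id = as.integer(names(cells_by)), offset_metric = off)
}

#' County climate representativeness: within-county variance
#'
#' Eigenvalue-fraction-weighted sum of the per-component population variance
#' across each county's cells: an overall measure of how climatically
#' heterogeneous each county is. Single-cell counties score 0.
#'
#' @inheritParams county_climate_offset
#' @return A data.frame with `county_id`, `variance_metric` (>= 0).
#' @export
county_climate_variance <- function(components, partition, weights = NULL) {
  w <- component_weights(components, weights)
  cells_by <- county_cells(partition)
  v <- vapply(cells_by, function(cells) {
    z <- stack_matrix(components, cells)
    if (anyNA(z)) z <- z[stats::complete.cases(z), , drop = FALSE]
    if (nrow(z) == 0) stop("county has no masked-in cells")
    pv <- colMeans(z^2) - colMeans(z)^2       # population variance
    sum(w * pmax(pv, 0))
  }, numeric(1))
  data.frame(county_id = as.integer(names(cells_by)), variance_metric = v)
}

#' Within-county standard deviation of a single layer
#'
#' Population SD of the layer over each county's masked-in cells;
#' single-cell counties score 0.
#'
#' @param layer A numeric matrix on the partition's grid.
#' @param partition A [generate_counties()] result.
#' @return A data.frame with `county_id`, `sd`.
#' @export
within_county_sd <- function(layer, partition) {
  cells_by <- county_cells(partition)
  s <- vapply(cells_by, function(cells) {
    v <- layer[cells]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    sqrt(mean(v^2) - mean(v)^2)
  }, numeric(1))
  data.frame(county_id = as.integer(names(cells_by)), sd = pmax(s, 0))
}

component_weights <- function(components, weights) {
  if (is.null(weights)) weights <- attr(components, "weights")
  if (is.null(weights))
    weights <- rep(1 / length(components$layers), length(components$layers))
  stopifnot(length(weights) == length(components$layers))
  weights
}
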