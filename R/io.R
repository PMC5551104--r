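#' Write an occurrence set as CSV
#'
#' Columns `species,x,y,county_id,source_tag`, the interchange format used
#' throughout the pipeline.
#'
#' @param occ An occurrence data.frame.
#' @param path Output CSV path.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(species = occ$species_id, x = occ$x, y = occ$y,
                   county_id = occ$county_id,
                   source_tag = if ("source_tag" %in% names(occ)) occ$source_tag else "true")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence CSV
#'
#' @param path CSV with columns `species,x,y,county_id[,source_tag]`.
#' @return An occurrence data.frame (`species_id`, `x`, `y`, `county_id`,
#'   `source_tag`).
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(species_id = as.character(df$species), x = df$x, y = df$y,
                    county_id = as.integer(df$county_id),
                    source_tag = if ("source_tag" %in% names(df)) df$source_tag else "true",
                    stringsAsFactors = FALSE)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Persist a county partition
#'
#' Writes the label grid as an integer ESRI ASCII raster and the centroid
#' table as CSV alongside it.
#'
#' @param partition A [generate_counties()] result.
#' @param raster_path Path for the label raster.
#' @param centroid_path Path for the centroid CSV (default: raster path with
#'   `_centroids.csv`).
#' @export
write_partition <- function(partition, raster_path,
                            centroid_path = sub("\\.[^.]*$", "_centroids.csv", raster_path)) {
  write_ascii_grid(partition$labels, partition$spec, raster_path)
  utils::write.csv(partition$counties, centroid_path, row.names = FALSE)
  invisible(raster_path)
}

#' Persist a fitted maxent model as JSON
#'
#' Stores feature definitions, scaling constants, weights, regularization,
#' entropy, normalizer and prevalence, so predictions can be reproduced
#' without refitting.
#'
#' @param model A [fit_maxent()] result.
#' @param path Output `.json` path.
#' @export
write_maxent_model <- function(model, path) {
  fe <- model$features
  obj <- list(
    lambda = model$lambda, beta = model$beta, logZ = model$logZ, H = model$H,
    tau = model$tau, n_presence = model$n_presence,
    n_background = model$n_background, converged = model$converged,
    features = list(defs = fe$defs, range = fe$range, classes = fe$classes,
                    k = fe$k, n_knots = fe$n_knots,
                    fmin = fe$fmin, fspan = fe$fspan))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a maxent model written by [write_maxent_model()]
#'
#' @param path JSON path.
#' @return A `maxent_model`.
#' @export
read_maxent_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fe <- obj$features
  fe$defs <- lapply(fe$defs, function(d) {
    d$knot <- if (is.null(d$knot)) NA_real_ else d$knot
    d$dir <- if (is.null(d$dir)) NA_integer_ else as.integer(d$dir)
    d$i2 <- if (is.null(d$i2)) NA_integer_ else as.integer(d$i2)
    d
  })
  fe$range <- matrix(unlist(fe$range), nrow = 2)
  class(fe) <- "feature_expansion"
  structure(list(lambda = obj$lambda, features = fe, beta = obj$beta,
                 logZ = obj$logZ, H = obj$H, n_presence = obj$n_presence,
                 n_background = obj$n_background, converged = obj$converged,
                 iterations = NA_integer_, objective = NA_real_, tau = obj$tau),
            class = "maxent_model")
}
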