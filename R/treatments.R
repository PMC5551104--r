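#' Filter occurrence records the way a vetted database snapshot is filtered
#'
#' Applies, in input order: (1) drop records whose coordinates fall in a cell
#' whose county label differs from the claimed `county_id`; (2) drop exact
#' duplicates of the same species at the same cell; (3) keep only the first
#' record of each species in each county (so a species' sample size equals its
#' county-centroid sample size); (4) drop species left with fewer than
#' `min_records` records. "First" means first in input order, the stand-in
#' for database insertion order. The operation is idempotent.
#'
#' @param raw An occurrence data.frame (`species_id`, `x`, `y`, `county_id`, ...).
#' @param partition A [generate_counties()] result.
#' @param min_records Minimum post-filter records per species (default 10).
#' @return The filtered occurrence data.frame (possibly empty).
#' @export
filter_records <- function(raw, partition, min_records = 10) {
  if (nrow(raw) == 0) return(raw)
  cl <- point_to_cell(partition$spec, raw$x, raw$y)
  idx <- (cl$col - 1L) * partition$spec$n_rows + cl$row
  lab <- rep(NA_integer_, nrow(raw))
  ok <- !is.na(idx)
  lab[ok] <- partition$labels[idx[ok]]
  keep <- !is.na(lab) & lab == raw$county_id
  out <- raw[keep, , drop = FALSE]
  idx <- idx[keep]
  dup <- duplicated(paste(out$species_id, idx))
  out <- out[!dup, , drop = FALSE]
  dup_county <- duplicated(paste(out$species_id, out$county_id))
  out <- out[!dup_county, , drop = FALSE]
  counts <- table(out$species_id)
  out <- out[out$species_id %in% names(counts)[counts >= min_records], , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_training_set <- function(occ, z, treatment, converted, seed = NA_integer_) {
  dimnames(z) <- list(NULL, paste0("z", seq_len(ncol(z))))
  structure(
    list(species_id = occ$species_id[1], treatment = treatment,
         records = data.frame(x = occ$x, y = occ$y, county_id = occ$county_id,
                              converted = converted),
         covariates = z, seed = seed),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %s / %s: %d records, %d covariates (%d converted)\n",
              x$species_id, x$treatment, nrow(x$records), ncol(x$covariates),
              sum(x$records$converted)))
  invisible(x)
}

record_cells <- function(occ, spec) {
  cl <- point_to_cell(spec, occ$x, occ$y)
  (cl$col - 1L) * spec$n_rows + cl$row
}

#' Training dataset 1: true localities
#'
#' Covariates are read from the component grids at each record's own cell.
#'
#' @param occ Filtered occurrences for one species.
#' @param components Component grids ([select_components()] output).
#' @return A `training_set` with treatment `"true_locality"`.
#' @export
make_true_locality_dataset <- function(occ, components) {
  cells <- record_cells(occ, components$spec)
  if (anyNA(cells) || !all(components$mask[cells]))
    stop("record outside the mask")
  new_training_set(occ, stack_matrix(components, cells), "true_locality",
                   converted = rep(FALSE, nrow(occ)))
}

#' Training dataset 2: county centroids
#'
#' Each record's coordinates are replaced by its county's centroid and
#' covariates are read at the centroid cell — the "sister dataset" a
#' county-georeferenced database would supply.
#'
#' @inheritParams make_true_locality_dataset
#' @param partition A [generate_counties()] result.
#' @return A `training_set` with treatment `"county_centroid"`.
#' @export
make_centroid_dataset <- function(occ, partition, components) {
  cen <- partition$counties
  i <- match(occ$county_id, cen$county_id)
  if (anyNA(i)) stop("record claims a county absent from the partition")
  occ2 <- occ
  occ2$x <- cen$x[i]; occ2$y <- cen$y[i]
  cells <- record_cells(occ2, components$spec)
  ts <- new_training_set(occ2, stack_matrix(components, cells), "county_centroid",
                         converted = rep(TRUE, nrow(occ)))
  ts
}

#' Training dataset 3: county environmental averages
#'
#' Coordinates are retained for bookkeeping but each record's covariate
#' vector is the mean of every component layer over its county's cells —
#' the "whole county as the sample unit" alternative. These covariate rows
#' are not tied to any grid cell; the model fitter consumes covariates only,
#' so no special casing is needed downstream.
#'
#' @inheritParams make_centroid_dataset
#' @return A `training_set` with treatment `"county_average"`.
#' @export
make_county_average_dataset <- function(occ, partition, components) {
  means <- county_component_means(partition, components)
  i <- match(occ$county_id, as.integer(rownames(means)))
  if (anyNA(i)) stop("record claims a county absent from the partition")
  new_training_set(occ, means[i, , drop = FALSE], "county_average",
                   converted = rep(TRUE, nrow(occ)))
}

county_component_means <- function(partition, components) {
  cells_by <- county_cells(partition)
  m <- t(vapply(cells_by, function(cells) {
    z <- stack_matrix(components, cells)
    if (anyNA(z)) z <- z[stats::complete.cases(z), , drop = FALSE]
    colMeans(z)
  }, numeric(length(components$layers))))
  rownames(m) <- names(cells_by)
  m
}

#' Training datasets 4 and 5: 50/50 mixes
#'
#' Selects `floor(fraction * n)` records uniformly at random (seeded) and
#' converts them to county-scale data; the rest keep their true-locality
#' covariates. The *same* selection is used for both outputs, so the
#' centroid-mix and average-mix differ only in how the converted records are
#' degraded. With odd n, flooring leaves the extra record as a true locality.
#'
#' @inheritParams make_centroid_dataset
#' @param fraction Fraction converted, in (0, 1) (default 0.5).
#' @param seed Integer seed for the selection.
#' @return A list with `mix_centroid` and `mix_average` training sets.
#' @export
make_mixed_datasets <- function(occ, partition, components, fraction = 0.5, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  n <- nrow(occ)
  stopifnot(n >= 2)
  n_conv <- floor(fraction * n)
  conv <- withr::with_seed(seed, sort(sample.int(n, n_conv)))
  true_ts <- make_true_locality_dataset(occ, components)
  cen_ts <- make_centroid_dataset(occ, partition, components)
  avg_ts <- make_county_average_dataset(occ, partition, components)
  mk <- function(conv_ts, treatment) {
    z <- true_ts$covariates
    z[conv, ] <- conv_ts$covariates[conv, ]
    rec_occ <- occ
    rec_occ$x[conv] <- conv_ts$records$x[conv]
    rec_occ$y[conv] <- conv_ts$records$y[conv]
    converted <- seq_len(n) %in% conv
    new_training_set(rec_occ, z, treatment, converted, seed = seed)
  }
  list(mix_centroid = mk(cen_ts, "mix_centroid"),
       mix_average = mk(avg_ts, "mix_average"))
}

#' Split species into strictly-eastern and strictly-western sets
#'
#' A species is eastern iff every record lies at `x > split_x`, western iff
#' every record lies at `x < split_x`; species straddling the line are
#' excluded from both lists.
#'
#' @param occ Occurrence data.frame for any number of species.
#' @param split_x The dividing x coordinate.
#' @return A list with character vectors `east` and `west` of species ids.
#' @export
split_east_west <- function(occ, split_x) {
  if (nrow(occ) == 0) return(list(east = character(0), west = character(0)))
  by_sp <- split(occ$x, occ$species_id)
  east <- names(by_sp)[vapply(by_sp, function(x) all(x > split_x), logical(1))]
  west <- names(by_sp)[vapply(by_sp, function(x) all(x < split_x), logical(1))]
  list(east = east, west = west)
}

#' Match record-count distributions between two species sets
#'
#' Mimics selecting regional species subsets "such that the numbers of
#' records were comparable": first, species on the side with the larger
#' total whose counts fall outside the [min, max] range of the other side
#' are dropped; then species are removed one at a time, at random (seeded)
#' from the side with the larger median and from among species whose count
#' exceeds the other side's median, until the two medians differ by at most
#' `tol` records or no removal can reduce the gap.
#'
#' @param east,west Named integer vectors of record counts (names = species).
#' @param seed Integer seed.
#' @param tol Maximum allowed difference in median counts (default 2).
#' @return A list with the retained `east` and `west` count vectors.
#' @export
match_sample_sizes <- function(east, west, seed = 1, tol = 2) {
  if (length(east) == 0 || length(west) == 0)
    stop("both sides must contain at least one species")
  big_is_east <- length(east) >= length(west)
  big <- if (big_is_east) east else west
  small <- if (big_is_east) west else east
  big <- big[big >= min(small) & big <= max(small)]
  if (length(big) == 0) stop("no overlap in record-count ranges")
  withr::with_seed(seed, {
    repeat {
      d <- stats::median(big) - stats::median(small)
      if (abs(d) <= tol) break
      side_hi <- if (d > 0) "big" else "small"
      v <- if (side_hi == "big") big else small
      if (length(v) <= 1) break
      cand <- which(v > stats::median(if (side_hi == "big") small else big))
      if (length(cand) == 0) break
      helps <- vapply(cand, function(i) {
        v2 <- v[-i]
        m2 <- if (side_hi == "big") abs(stats::median(v2) - stats::median(small))
              else abs(stats::median(big) - stats::median(v2))
        m2 < abs(d)
      }, logical(1))
      cand <- cand[helps]
      if (length(cand) == 0) break
      drop_i <- if (length(cand) == 1) cand else sample(cand, 1)
      if (side_hi == "big") big <- v[-drop_i] else small <- v[-drop_i]
    }
  })
  if (big_is_east) list(east = big, west = small) else list(east = small, west = big)
}
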