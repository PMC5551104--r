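#' Generate a two-region county tessellation
#'
#' Partitions the grid into counties by a seeded Voronoi tessellation of cell
#' centers. The domain is split at `split_x` into a western region of few,
#' large counties and an eastern region of many, small counties — the size
#' contrast that makes coarse (county-resolution) georeferencing much more
#' damaging on one side of the domain than the other. Voronoi seeds are drawn
#' uniformly within each region with density `1 / mean_area`.
#'
#' County centroids are the arithmetic mean of member cell centers; if that
#' mean falls outside the county (possible for concave counties), it is
#' snapped to the nearest member cell center so every centroid is always
#' resolvable to a county cell.
#'
#' @param spec A [grid_spec()].
#' @param split_x Map x coordinate dividing the large-county (west, `x <
#'   split_x`) and small-county (east) regions. Use `-Inf` or `Inf` for a
#'   single-region landscape.
#' @param mean_area_small,mean_area_large Target mean county areas in cells;
#'   `mean_area_large > mean_area_small >= 4`.
#' @param seed Integer seed.
#' @param mask Optional logical matrix of cells in the study area (default all).
#' @return An object of class `county_partition`: list with `spec`, `labels`
#'   (integer matrix, `NA` outside mask), and `counties` (data.frame with
#'   `county_id`, `x`, `y` centroid coordinates, `region`, `n_cells`).
#' @export
generate_counties <- function(spec, split_x, mean_area_small = 25,
                              mean_area_large = 400, seed = 1, mask = NULL) {
  if (!(mean_area_large > mean_area_small && mean_area_small >= 4))
    stop("need mean_area_large > mean_area_small >= 4")
  if (is.null(mask)) mask <- matrix(TRUE, spec$n_rows, spec$n_cols)
  cc <- cell_centers(spec)
  west <- cc$x < split_x & mask
  east <- !west & mask

  n_seed <- function(region_cells, mean_area) {
    n <- sum(region_cells)
    if (n == 0) return(0L)
    max(1L, as.integer(round(n / mean_area)))
  }
  k_w <- n_seed(west, mean_area_large)
  k_e <- n_seed(east, mean_area_small)
  if (k_w + k_e == 0) stop("empty mask")
  if (k_w > 0 && k_e > 0 && (k_w < 2 || k_e < 2))
    stop("region too small to host at least 2 counties")

  seeds <- withr::with_seed(seed, {
    pick <- function(region_cells, k) {
      idx <- which(region_cells)
      if (k == 0) return(integer(0))
      sample(idx, min(k, length(idx)))
    }
    list(w = pick(west, k_w), e = pick(east, k_e))
  })
  seed_idx <- c(seeds$w, seeds$e)
  seed_region <- rep(c("large-county region", "small-county region"),
                     c(length(seeds$w), length(seeds$e)))
  sx <- cc$x[seed_idx]; sy <- cc$y[seed_idx]

  # nearest seed per cell, constrained to the seed's own region so counties
  # never straddle the split line
  labels <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  assign_region <- function(region_cells, which_seeds) {
    idx <- which(region_cells)
    if (length(idx) == 0 || length(which_seeds) == 0) return()
    px <- cc$x[idx]; py <- cc$y[idx]
    best <- rep(1L, length(idx))
    bestd <- (px - sx[which_seeds[1]])^2 + (py - sy[which_seeds[1]])^2
    for (s in seq_along(which_seeds)[-1]) {
      d <- (px - sx[which_seeds[s]])^2 + (py - sy[which_seeds[s]])^2
      upd <- d < bestd
      best[upd] <- s
      bestd[upd] <- d[upd]
    }
    labels[idx] <<- which_seeds[best]
  }
  assign_region(west, seq_along(seeds$w))
  assign_region(east, length(seeds$w) + seq_along(seeds$e))

  ids <- sort(unique(labels[!is.na(labels)]))
  counties <- do.call(rbind, lapply(ids, function(id) {
    m <- which(labels == id)
    mx <- mean(cc$x[m]); my <- mean(cc$y[m])
    cell <- point_to_cell(spec, mx, my)
    inside <- !is.na(cell$row) &&
      isTRUE(labels[cell$row, cell$col] == id)
    if (!inside) {  # concave county: snap to nearest member cell center
      d <- (cc$x[m] - mx)^2 + (cc$y[m] - my)^2
      j <- m[which.min(d)]
      mx <- cc$x[j]; my <- cc$y[j]
    }
    data.frame(county_id = id, x = mx, y = my,
               region = seed_region[id], n_cells = length(m))
  }))
  rownames(counties) <- NULL
  structure(list(spec = spec, labels = labels, counties = counties),
            class = "county_partition")
}

#' @export
print.county_partition <- function(x, ...) {
  cat(sprintf("<county_partition> %d counties on %d x %d grid (%s)\n",
              nrow(x$counties), x$spec$n_rows, x$spec$n_cols,
              paste(sprintf("%s: %d", names(table(x$counties$region)),
                            as.integer(table(x$counties$region))),
                    collapse = ", ")))
  invisible(x)
}

#' Per-county cell indices
#'
#' @param partition A [generate_counties()] result.
#' @return A named list mapping county id to the linear indices of its cells.
#' @export
county_cells <- function(partition) {
  lab <- partition$labels
  ok <- !is.na(lab)
  split(which(ok), lab[ok])
}

#' Resolve county centroids to grid cells
#'
#' @param partition A [generate_counties()] result.
#' @return Integer vector of linear cell indices, named by county id.
#' @export
centroid_cells <- function(partition) {
  cl <- point_to_cell(partition$spec, partition$counties$x, partition$counties$y)
  idx <- (cl$col - 1L) * partition$spec$n_rows + cl$row
  names(idx) <- partition$counties$county_id
  idx
}
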