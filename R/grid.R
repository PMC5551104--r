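#' Define a regular raster grid
#'
#' A `grid_spec` describes a regular planar grid of square cells. Cells are
#' stored as R matrices with row 1 at the *southern* edge, so the cell at
#' `[row, col]` has its center at
#' `(origin_x + (col - 0.5) * cell_size, origin_y + (row - 0.5) * cell_size)`.
#' Coordinates are arbitrary planar map units (the pipeline deliberately does
#' no geodesy; an equal-area planar frame is assumed throughout).
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Side length of a cell in map units (default 1).
#' @param origin_x,origin_y Map coordinates of the lower-left corner.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1, origin_x = 0, origin_y = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, origin_x = origin_x, origin_y = origin_y),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell size %g, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

n_cells <- function(spec) spec$n_rows * spec$n_cols

#' Coordinates of cell centers
#'
#' @param spec A [grid_spec()].
#' @return A list with matrices `x` and `y` (n_rows x n_cols) of cell-center
#'   coordinates.
#' @export
cell_centers <- function(spec) {
  xs <- spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  ys <- spec$origin_y + (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  list(x = matrix(xs, spec$n_rows, spec$n_cols, byrow = TRUE),
       y = matrix(ys, spec$n_rows, spec$n_cols))
}

#' Map a point to the grid cell containing it
#'
#' Cells are half-open intervals `[edge, edge + cell_size)` on both axes, so
#' every point inside the grid extent maps to exactly one cell.
#'
#' @param spec A [grid_spec()].
#' @param x,y Point coordinates (vectors of equal length).
#' @return A data.frame with integer columns `row` and `col`; `NA` for points
#'   outside the grid extent.
#' @export
point_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((y - spec$origin_y) / spec$cell_size) + 1
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

cell_center_xy <- function(spec, row, col) {
  list(x = spec$origin_x + (col - 0.5) * spec$cell_size,
       y = spec$origin_y + (row - 0.5) * spec$cell_size)
}

#' Write a grid layer as an ESRI ASCII raster
#'
#' Persists a single matrix layer in the plain-text ESRI ASCII grid format
#' (readable by common GIS software). Row 1 of the matrix is the southern
#' edge, so rows are written north-to-south as the format requires.
#'
#' @param layer A numeric matrix on `spec`.
#' @param spec A [grid_spec()].
#' @param path Output file path.
#' @param nodata Value written for `NA` cells.
#' @export
write_ascii_grid <- function(layer, spec, path, nodata = -9999) {
  stopifnot(nrow(layer) == spec$n_rows, ncol(layer) == spec$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  m <- layer
  m[is.na(m)] <- nodata
  for (r in rev(seq_len(spec$n_rows))) {
    writeLines(paste(format(m[r, ], digits = 10, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return A list with `layer` (matrix, row 1 = south) and `spec`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  spec <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  m <- m[rev(seq_len(spec$n_rows)), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(layer = m, spec = spec)
}
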