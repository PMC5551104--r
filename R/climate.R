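#' Generate synthetic monthly climate normals
#'
#' Builds 36 co-registered layers (12 months each of maximum temperature,
#' minimum temperature and precipitation) emulating the structure of gridded
#' climate normals: a large-scale linear gradient, a seasonal sinusoid, and a
#' spatially autocorrelated anomaly field with exponential covariance.
#'
#' Temperature (deg C) runs along the y axis (a latitude-like gradient);
#' precipitation (mm) has its gradient along x, so one side of the domain is
#' wetter, mimicking a continental east-west moisture contrast. The diurnal
#' range is `1 + softplus(field)`, which guarantees `tmax - tmin >= 1` at
#' every cell, and precipitation is obtained by a softplus map so it is
#' nonnegative while preserving the autocorrelation structure near zero.
#'
#' @param spec A [grid_spec()].
#' @param gradient_strength Temperature change (deg C) across the full y
#'   extent of the domain; the precipitation gradient scales with it.
#' @param autocorr_length Correlation length of the anomaly fields, map units.
#' @param seasonal_amplitude Half-range of the seasonal temperature cycle
#'   (deg C); July is the warmest month.
#' @param seed Integer seed; the output is a deterministic function of all
#'   arguments.
#' @param noise_sd SD (deg C) of the persistent spatial temperature anomaly.
#' @param month_noise_sd SD (deg C) of independent per-month anomaly fields.
#' @param base_temp Domain-wide mean annual temperature (deg C).
#' @param precip_scale Scale (mm) of monthly precipitation.
#' @return An object of class `monthly_climate`: a list with `spec` and
#'   12-element lists `tmax`, `tmin`, `precip` of matrices.
#' @export
generate_monthly_climate <- function(spec, gradient_strength = 15,
                                     autocorr_length = 8,
                                     seasonal_amplitude = 10, seed = 1,
                                     noise_sd = 2, month_noise_sd = 0.5,
                                     base_temp = 12, precip_scale = 60) {
  if (autocorr_length <= 0) stop("`autocorr_length` must be positive")
  if (spec$n_rows < 4 || spec$n_cols < 4)
    stop("degenerate grid: need at least 4 cells per axis")
  cc <- cell_centers(spec)
  yfrac <- (cc$y - spec$origin_y) / (spec$n_rows * spec$cell_size) - 0.5
  xfrac <- (cc$x - spec$origin_x) / (spec$n_cols * spec$cell_size) - 0.5

  grf <- function(k) {
    if (noise_sd == 0 && month_noise_sd == 0) return(matrix(0, spec$n_rows, spec$n_cols))
    gaussian_random_field(spec, autocorr_length, seed = seed * 101L + k)
  }
  softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)

  tmean_anom <- grf(1L) * noise_sd
  drange <- 1 + softplus(grf(2L) * 0.8 + 1.5)      # diurnal range, >= 1 by construction
  p_anom <- grf(3L)

  tmax <- tmin <- precip <- vector("list", 12)
  for (m in 1:12) {
    season <- seasonal_amplitude * cos(2 * pi * (m - 7) / 12)
    tm <- base_temp - gradient_strength * yfrac + season + tmean_anom +
      if (month_noise_sd > 0) grf(10L + m) * month_noise_sd else 0
    tmax[[m]] <- tm + drange / 2
    tmin[[m]] <- tm - drange / 2
    # wetter east (positive xfrac); mild seasonal cycle peaking in early summer
    pfield <- 1.5 * xfrac * (gradient_strength / 15) +
      0.4 * cos(2 * pi * (m - 6) / 12) + 0.8 * p_anom +
      if (month_noise_sd > 0) grf(30L + m) * 0.3 else 0
    precip[[m]] <- softplus(pfield) * precip_scale
  }
  structure(list(spec = spec, tmax = tmax, tmin = tmin, precip = precip),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("<monthly_climate> 36 layers on %d x %d grid\n",
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}
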