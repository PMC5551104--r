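#' Sample a stationary Gaussian random field with exponential covariance
#'
#' Draws one realization of a zero-mean, unit-variance Gaussian process on the
#' grid with covariance `C(h) = exp(-h / range)` (h in map units), using
#' circulant embedding on a doubled torus evaluated by FFT. The embedding of
#' the exponential kernel is not always positive semidefinite on a finite
#' torus; negative eigenvalues are clamped to zero, which perturbs the target
#' covariance by a negligible amount for `range` small relative to the domain.
#'
#' @param spec A [grid_spec()].
#' @param range Correlation length in map units (> 0). The semivariogram of
#'   the field reaches 95% of its sill at lag ~ 3 * range.
#' @param seed Integer seed; the draw is a deterministic function of
#'   `(spec, range, seed)`. The global RNG state is left untouched.
#' @return A numeric matrix (`n_rows` x `n_cols`) with approximately N(0, 1)
#'   margins.
#' @export
gaussian_random_field <- function(spec, range, seed) {
  if (range <= 0) stop("`range` must be positive")
  nr <- spec$n_rows; nc <- spec$n_cols
  if (nr < 4 || nc < 4) stop("grid too small: need at least 4 cells per axis")
  M <- 2L * nr; N <- 2L * nc
  # torus distances in map units
  di <- pmin(0:(M - 1), M - (0:(M - 1))) * spec$cell_size
  dj <- pmin(0:(N - 1), N - (0:(N - 1))) * spec$cell_size
  D <- sqrt(outer(di^2, dj^2, `+`))
  C <- exp(-D / range)
  S <- Re(stats::fft(C))
  S[S < 0] <- 0
  withr::with_seed(seed, {
    E <- matrix(stats::rnorm(M * N), M, N) + 1i * matrix(stats::rnorm(M * N), M, N)
  })
  # With unit-variance real and imaginary noise parts, Re(X) and Im(X) are
  # independent fields each with covariance C: Var(Re X) = sum(S)/(M*N) = C(0).
  X <- stats::fft(sqrt(S) * E) / sqrt(M * N)
  Re(X)[seq_len(nr), seq_len(nc), drop = FALSE]
}
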