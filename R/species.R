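#' Define a virtual species with a product-Gaussian climatic niche
#'
#' The species' habitat suitability is a separable Gaussian in environmental
#' covariate space: `s(z) = prod_k exp(-(z_k - c_k)^2 / (2 w_k^2))`, which is
#' 1 exactly at the niche center and decays smoothly away from it. Because the
#' true suitability surface is known everywhere, model error downstream can be
#' measured exactly — the core advantage of a virtual-species design.
#'
#' @param species_id Character identifier.
#' @param niche_center Numeric vector `c` in covariate space.
#' @param niche_width Positive numeric vector `w` (per-axis SD), same length.
#' @param seed Integer seed associated with the species (used by samplers).
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(species_id, niche_center, niche_width, seed = 1) {
  stopifnot(length(niche_center) == length(niche_width), all(niche_width > 0))
  structure(list(species_id = species_id, niche_center = niche_center,
                 niche_width = niche_width, seed = as.integer(seed)),
            class = "virtual_species")
}

#' True habitat suitability of a virtual species over a landscape
#'
#' @param species A [virtual_species()].
#' @param env An [env_stack()] whose layers are the covariate axes of the
#'   niche (same number and order).
#' @return A matrix of suitabilities in \[0, 1\] (`NA` outside the mask).
#' @export
true_suitability <- function(species, env) {
  k <- length(env$layers)
  if (k != length(species$niche_center))
    stop(sprintf("niche dimensionality (%d) does not match the stack (%d layers)",
                 length(species$niche_center), k))
  cells <- which(env$mask)
  z <- stack_matrix(env, cells)
  d2 <- sweep(z, 2, species$niche_center)^2
  d2 <- sweep(d2, 2, 2 * species$niche_width^2, `/`)
  s <- exp(-rowSums(d2))
  out <- matrix(NA_real_, env$spec$n_rows, env$spec$n_cols)
  out[cells] <- s
  out
}

#' Sample occurrence records proportional to suitability
#'
#' Draws `n` distinct cells without replacement with inclusion probability
#' proportional to true suitability, emulating collection records that
#' accumulate where the species actually occurs. Each record carries the true
#' coordinates of its cell center and the county id at that cell.
#'
#' @param species A [virtual_species()].
#' @param env An [env_stack()] of niche covariates.
#' @param partition A [generate_counties()] result on the same grid.
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param support_mask Optional logical matrix restricting the cells records
#'   may be drawn from (e.g. a dispersal region); default: the whole mask.
#' @return A data.frame (class `occurrence_set`) with columns `species_id`,
#'   `x`, `y`, `county_id`, `source_tag` (all `"true"`).
#' @export
sample_occurrences <- function(species, env, partition, n, seed = 1,
                               support_mask = NULL) {
  stopifnot(n >= 1)
  s <- true_suitability(species, env)
  ok <- env$mask & !is.na(partition$labels) & s > 0
  if (!is.null(support_mask)) ok <- ok & support_mask
  ok <- which(ok)
  if (length(ok) < n)
    stop(sprintf("only %d cells with positive suitability; cannot sample n = %d",
                 length(ok), n))
  pick <- withr::with_seed(seed, {
    if (length(ok) == n) ok else sample(ok, n, prob = s[ok])
  })
  rc <- arrayInd(pick, dim(s))
  xy <- cell_center_xy(env$spec, rc[, 1], rc[, 2])
  out <- data.frame(species_id = species$species_id, x = xy$x, y = xy$y,
                    county_id = partition$labels[pick],
                    source_tag = "true", stringsAsFactors = FALSE)
  class(out) <- c("occurrence_set", "data.frame")
  out
}
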