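#' Derive the 19 bioclim variables from monthly climate normals
#'
#' Computes the standard ANUCLIM/WorldClim bioclimatic summaries per cell.
#' Quarters are the 12 consecutive 3-month windows starting at each month,
#' with December-January wraparound; when two quarters tie (equally wettest,
#' warmest, ...), the earliest window in January-start order wins. Monthly
#' standard deviations (BIO4, BIO15) use the population convention (divide by
#' 12), and the BIO15 denominator is `1 + BIO12/12` so arid cells do not
#' divide by zero.
#'
#' @param monthly A [generate_monthly_climate()] result (or any
#'   `monthly_climate` object).
#' @return An [env_stack()] with layers `BIO1` ... `BIO19`. Units follow the
#'   inputs: temperatures in deg C, precipitation in mm.
#' @export
derive_bioclim <- function(monthly) {
  spec <- monthly$spec
  if (length(monthly$tmax) != 12 || length(monthly$tmin) != 12 ||
      length(monthly$precip) != 12)
    stop("need 12 months of tmax, tmin and precip")
  nc <- n_cells(spec)
  tmax <- vapply(monthly$tmax, as.vector, numeric(nc))   # ncell x 12
  tmin <- vapply(monthly$tmin, as.vector, numeric(nc))
  prec <- vapply(monthly$precip, as.vector, numeric(nc))
  if (any(tmax < tmin, na.rm = TRUE))
    stop("tmax < tmin at some cell; invalid monthly climate")
  tavg <- (tmax + tmin) / 2

  pop_sd <- function(m) sqrt(rowMeans(m^2) - rowMeans(m)^2)
  qwin <- lapply(1:12, function(q) ((q - 1):(q + 1)) %% 12 + 1)
  qtemp <- vapply(qwin, function(w) rowMeans(tavg[, w, drop = FALSE]), numeric(nc))
  qprec <- vapply(qwin, function(w) rowSums(prec[, w, drop = FALSE]), numeric(nc))
  pick <- function(value, by, decreasing) {
    # per cell: value of the quarter extremizing `by`, earliest quarter on ties
    j <- max.col(if (decreasing) by else -by, ties.method = "first")
    value[cbind(seq_len(nc), j)]
  }

  b <- list()
  b$BIO1 <- rowMeans(tavg)
  b$BIO2 <- rowMeans(tmax - tmin)
  b$BIO5 <- apply(tmax, 1, max)
  b$BIO6 <- apply(tmin, 1, min)
  b$BIO7 <- b$BIO5 - b$BIO6
  b$BIO3 <- 100 * b$BIO2 / b$BIO7
  b$BIO4 <- 100 * pop_sd(tavg)
  b$BIO8 <- pick(qtemp, qprec, TRUE)    # mean temp of wettest quarter
  b$BIO9 <- pick(qtemp, qprec, FALSE)   # ... of driest quarter
  b$BIO10 <- pick(qtemp, qtemp, TRUE)   # ... of warmest quarter
  b$BIO11 <- pick(qtemp, qtemp, FALSE)  # ... of coldest quarter
  b$BIO12 <- rowSums(prec)
  b$BIO13 <- apply(prec, 1, max)
  b$BIO14 <- apply(prec, 1, min)
  b$BIO15 <- 100 * pop_sd(prec) / (1 + b$BIO12 / 12)
  b$BIO16 <- pick(qprec, qprec, TRUE)   # precip of wettest quarter
  b$BIO17 <- pick(qprec, qprec, FALSE)  # ... of driest quarter
  b$BIO18 <- pick(qprec, qtemp, TRUE)   # ... of warmest quarter
  b$BIO19 <- pick(qprec, qtemp, FALSE)  # ... of coldest quarter

  layers <- lapply(b[paste0("BIO", 1:19)], function(v)
    matrix(v, spec$n_rows, spec$n_cols))
  env_stack(layers, spec)
}
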