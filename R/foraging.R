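#' Flower visitation rates of central-place foragers
#'
#' Allocates the foragers nesting in every cell j across the flowering
#' cells i of the landscape in proportion to floral value discounted by
#' distance:
#' \deqn{V_i = \sum_j X_j \frac{F_i e^{-d_{ij}/\beta}}
#'   {\sum_q F_q e^{-d_{qj}/\beta}} \rho_F^{d_{ij}}}
#' with Euclidean center-to-center distances, the exponential kernel
#' truncated at its `kernel_quantile` quantile (applied consistently in
#' numerator and denominator), and `rho_F` the per-meter survival during
#' foraging. Foragers have full information about resources within the
#' truncation disc; with `rho_F = 1` every forager is allocated somewhere,
#' so total visits equal total foragers. A source cell whose whole
#' normalization sum is zero (no flowers in reach) contributes no visits.
#'
#' The double sum is evaluated exactly (up to floating-point round-off)
#' as two truncated-kernel convolutions computed by zero-padded FFT.
#'
#' @param X Matrix of foraging bees nesting per cell (queens in period 1,
#'   `p_w * W` workers in period 2).
#' @param F Matrix of floral values for the period (see
#'   [build_floral_raster()]).
#' @param params A [bb_params()] object.
#' @param cell_size Cell side length in meters.
#' @param denom Optional precomputed normalization raster
#'   `sum_q F_q K(d_qj)` (one kernel convolution of `F`); pass it when
#'   calling repeatedly on the same floral raster.
#' @return Matrix of visitation rates received per cell (visits, >= 0).
#' @export
visitation_rates <- function(X, F, params, cell_size = 25, denom = NULL) {
  check_congruent(X, F)
  if (any(X < 0)) stop("forager counts must be >= 0")
  if (any(F < 0)) stop("floral values must be >= 0")
  q <- params$kernel_quantile
  if (is.null(denom))
    denom <- disc_convolve(F, params$beta, cell_size, q)
  S <- X
  ## a normalization sum below FFT round-off noise is genuinely zero:
  ## that source has no flowers in reach and contributes no visits
  pos <- denom > 1e-10 * max(denom)
  S[pos] <- X[pos] / denom[pos]
  S[!pos] <- 0
  F * disc_convolve(S, params$beta, cell_size, q, rho = params$rho_F)
}

#' Resources collected per nest
#'
#' The resources collected per nest in cell i during a period are the
#' per-nest number of foragers times the kernel-weighted mean floral
#' value around the nest:
#' \deqn{R_i = \frac{X_i}{N_i}
#'   \frac{\sum_j F_j e^{-d_{ij}/\beta}}{\sum_j e^{-d_{ij}/\beta}}}
#' with both sums over the cells of the truncation disc that lie in the
#' landscape. Floral resources are not depleted, so there is no
#' exploitation competition between nests.
#'
#' @param X Matrix of foragers per cell.
#' @param N Matrix of nests per cell; must be positive wherever `X > 0`.
#' @inheritParams visitation_rates
#' @param numer,denom Optional precomputed kernel convolutions of `F` and
#'   of a matrix of ones (reused across years on a static landscape).
#' @return Matrix of resource intakes per nest (0 where there are no
#'   foragers).
#' @export
resources_per_nest <- function(X, N, F, params, cell_size = 25,
                               numer = NULL, denom = NULL) {
  check_congruent(X, N, F)
  if (any(X < 0) || any(F < 0)) stop("X and F must be >= 0")
  if (any(X > 0 & N <= 0))
    stop("cells with foragers (X > 0) must contain nests (N > 0)")
  q <- params$kernel_quantile
  if (is.null(numer))
    numer <- disc_convolve(F, params$beta, cell_size, q)
  if (is.null(denom))
    denom <- disc_convolve(matrix(1, nrow(F), ncol(F)),
                           params$beta, cell_size, q)
  perforager <- X
  pos <- X > 0
  perforager[pos] <- X[pos] / N[pos]
  perforager[!pos] <- 0
  perforager * numer / denom
}

#' Visitation per unit flower cover
#'
#' The pollination-service proxy: visits received by a cell divided by
#' its flowering area (coverage times cell area in hectares). Cells
#' without flowers get `NA`.
#'
#' @param V Visitation raster (from [visitation_rates()]).
#' @param cover Flowering coverage raster (from [build_cover_raster()]).
#' @param cell_size Cell side length in meters.
#' @return Matrix of visits per hectare of flowers; `NA` where cover is 0.
#' @export
per_flower_visitation <- function(V, cover, cell_size = 25) {
  check_congruent(V, cover)
  out <- V / (cover * cell_area_ha(cell_size))
  out[cover <= 0] <- NA_real_
  out
}

check_congruent <- function(...) {
  mats <- list(...)
  d <- dim(mats[[1]])
  for (m in mats[-1])
    if (!identical(dim(m), d)) stop("grids must have identical dimensions")
  invisible(TRUE)
}
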