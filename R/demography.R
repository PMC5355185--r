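#' Saturating resource-to-offspring production function
#'
#' Offspring production saturates with collected resources following the
#' cumulative distribution function of a lognormal distribution
#' parameterized by its median `a` (resources at which half the maximum
#' offspring are produced) and its variance `b` (steepness: smaller
#' variance means a sharper switch around the median). The lognormal
#' parameters follow from `meanlog = log(a)` and the variance identity
#' `(exp(s2) - 1) * exp(2 * meanlog + s2) = b`, which is quadratic in
#' `exp(s2)` and solved in closed form:
#' `s2 = log((1 + sqrt(1 + 4 b / a^2)) / 2)`.
#'
#' @param R Collected resources, >= 0 (vector or matrix).
#' @param a Median of the production curve (> 0).
#' @param b Variance/steepness of the curve (> 0). The default
#'   configuration ties `b = 2 * a`.
#' @return Proportion of the maximum production realized, in \[0, 1\];
#'   `growth_cdf(a, a, b)` is exactly 0.5. Shape and dimensions of `R`
#'   are preserved.
#' @examples
#' growth_cdf(100, 100, 200)   # 0.5
#' @export
growth_cdf <- function(R, a, b) {
  if (a <= 0 || b <= 0) stop("a and b must be > 0")
  if (any(R < 0)) stop("resources must be >= 0")
  out <- stats::plnorm(R, meanlog = log(a),
                       sdlog = sqrt(lognormal_sigma2(a, b)))
  dim(out) <- dim(R)
  out
}

## sigma^2 of a lognormal with median a and variance b
lognormal_sigma2 <- function(a, b) {
  log((1 + sqrt(1 + 4 * b / a^2)) / 2)
}

#' Within-season colony growth
#'
#' `worker_growth()` turns the resources collected by each foraging queen
#' in period 1 into workers: `W_i = Q_i * w_max * G(R1_i, a_w, b_w)`.
#' `queen_production()` turns period-2 worker foraging into new queens:
#' the foraging force is `X2 = p_w * W`, its per-nest intake `R2` comes
#' from [resources_per_nest()], and
#' `Q_E,i = Q_i * q_max * G(R2_i, a_q, b_q)`.
#'
#' @param Q Matrix of queens (= colonies) per cell.
#' @param R1 Matrix of per-nest resources collected in period 1.
#' @param params A [bb_params()] object.
#' @return `worker_growth()`: matrix of workers per cell, bounded by
#'   `Q * w_max`.
#' @export
worker_growth <- function(Q, R1, params) {
  check_congruent(Q, R1)
  if (any(Q < 0)) stop("queen counts must be >= 0")
  Q * params$w_max * growth_cdf(R1, params$a_w, params$b_w)
}

#' @rdname worker_growth
#' @param W Matrix of workers per cell.
#' @param F2 Period-2 floral raster.
#' @param cell_size Cell side length in meters.
#' @param numer,denom Optional precomputed convolutions, as in
#'   [resources_per_nest()].
#' @return `queen_production()`: matrix of end-of-season new queens,
#'   bounded by `Q * q_max`.
#' @export
queen_production <- function(Q, W, F2, params, cell_size = 25,
                             numer = NULL, denom = NULL) {
  check_congruent(Q, W, F2)
  if (any(W < 0)) stop("worker counts must be >= 0")
  R2 <- resources_per_nest(params$p_w * W, Q, F2, params, cell_size,
                           numer = numer, denom = denom)
  Q * params$q_max * growth_cdf(R2, params$a_q, params$b_q)
}

#' Overwinter dispersal and density-dependent settlement
#'
#' New queens overwinter in their natal cell, then disperse with an
#' exponential kernel of mean `beta_nest`, choosing destination cells in
#' proportion to a destination weight (by default the nesting capacity;
#' optionally the literal current queen numbers) discounted by distance.
#' The expected number of arrivals per cell is truncated at the cell's
#' nesting capacity (density-dependent mortality of nest-searching
#' queens), and the realized number of new colonies is then drawn from a
#' Poisson distribution with the truncated intensity -- the only
#' stochastic and integer-valued step of the year.
#'
#' Queens produced in cells from which no positively weighted destination
#' is reachable are lost (recorded in `lost`, not an error).
#'
#' @param Q_E Matrix of end-of-season new queens per cell.
#' @param capacity Nesting-capacity matrix (colonies per cell), from
#'   [build_nesting_raster()].
#' @param params A [bb_params()] object (`beta_nest`, `rho_N`,
#'   `dispersal_weight`).
#' @param cell_size Cell side length in meters.
#' @param Q Current queen matrix; required only when
#'   `params$dispersal_weight == "queens"`.
#' @param denom Optional precomputed convolution of the destination
#'   weight raster.
#' @return A list: `Q_next` (integer-valued matrix of settled colonies),
#'   `intensity` (the truncated Poisson intensities, never above
#'   `capacity`), and `lost` (queens with no reachable destination).
#'   Uses the current RNG state; seed it for reproducibility.
#' @export
overwinter_disperse <- function(Q_E, capacity, params, cell_size = 25,
                                Q = NULL, denom = NULL) {
  check_congruent(Q_E, capacity)
  if (any(Q_E < 0) || any(capacity < 0)) stop("inputs must be >= 0")
  w <- switch(params$dispersal_weight,
              capacity = capacity,
              queens = {
                if (is.null(Q))
                  stop("dispersal_weight 'queens' needs the current Q")
                Q
              })
  qq <- params$kernel_quantile
  if (is.null(denom))
    denom <- disc_convolve(w, params$beta_nest, cell_size, qq)
  S <- Q_E
  ## below FFT round-off noise the weight sum is genuinely zero: no
  ## nesting habitat in reach, those queens are lost
  pos <- denom > 1e-10 * max(denom)
  S[pos] <- Q_E[pos] / denom[pos]
  S[!pos] <- 0
  lost <- sum(Q_E[!pos])
  arrivals <- w * disc_convolve(S, params$beta_nest, cell_size, qq,
                                rho = params$rho_N)
  intensity <- pmin(arrivals, capacity)
  Q_next <- matrix(stats::rpois(length(intensity), intensity),
                   nrow(intensity), ncol(intensity))
  list(Q_next = Q_next, intensity = intensity, lost = lost)
}
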