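#' Model parameters for the central-place forager model
#'
#' Bundles every scalar the model needs. Defaults are the published values
#' for common early-active bumble bees: 19.6 nests/ha at maximum nesting
#' quality, a mean foraging distance of 530 m, a mean nest-searching
#' dispersal distance of 1000 m, worker growth with median 100 and
#' steepness 200, queen growth with median 15000 and steepness 30000
#' (steepness fixed at twice the median), at most 600 workers per queen and
#' 160 new queens per colony, and half of the workers foraging.
#'
#' @param n_max Maximum colony density (nests per hectare) in a cell of
#'   nesting quality 1.
#' @param beta Mean foraging dispersal distance in meters.
#' @param beta_nest Mean dispersal distance of nest-searching queens in
#'   meters (roughly twice the foraging distance).
#' @param a_w,b_w Median and steepness (variance) of the lognormal-CDF
#'   worker production function, in resource units.
#' @param a_q,b_q Median and steepness of the queen production function.
#' @param w_max Maximum number of workers produced per queen.
#' @param q_max Maximum number of new queens produced per colony.
#' @param p_w Proportion of workers that forage in the second period.
#' @param rho_F Per-meter survival during foraging flights, in (0, 1].
#'   1 means no en-route mortality.
#' @param rho_N Per-meter survival during nest-searching flights.
#' @param kernel_quantile Quantile of the exponential distance kernel
#'   beyond which the kernel is truncated to zero.
#' @param dispersal_weight Destination weighting used when nest-searching
#'   queens choose cells: `"capacity"` weights cells by their nesting
#'   capacity, `"queens"` by the current number of queens.
#'
#' @return An object of class `bb_params` (a named list).
#' @examples
#' p <- bb_params()
#' p$beta
#' @export
bb_params <- function(n_max = 19.6,
                      beta = 530,
                      beta_nest = 1000,
                      a_w = 100, b_w = 2 * a_w,
                      a_q = 15000, b_q = 2 * a_q,
                      w_max = 600,
                      q_max = 160,
                      p_w = 0.5,
                      rho_F = 1,
                      rho_N = 1,
                      kernel_quantile = 0.99,
                      dispersal_weight = c("capacity", "queens")) {
  dispersal_weight <- match.arg(dispersal_weight)
  p <- list(n_max = n_max, beta = beta, beta_nest = beta_nest,
            a_w = a_w, b_w = b_w, a_q = a_q, b_q = b_q,
            w_max = w_max, q_max = q_max, p_w = p_w,
            rho_F = rho_F, rho_N = rho_N,
            kernel_quantile = kernel_quantile,
            dispersal_weight = dispersal_weight)
  validate_bb_params(p)
  class(p) <- "bb_params"
  p
}

validate_bb_params <- function(p) {
  stopifnot(
    p$n_max >= 0,
    p$beta > 0, p$beta_nest > 0,
    p$a_w > 0, p$b_w > 0, p$a_q > 0, p$b_q > 0,
    p$w_max >= 0, p$q_max >= 0,
    p$p_w >= 0, p$p_w <= 1,
    p$rho_F > 0, p$rho_F <= 1,
    p$rho_N > 0, p$rho_N <= 1,
    p$kernel_quantile > 0, p$kernel_quantile < 1
  )
  invisible(p)
}

#' @export
print.bb_params <- function(x, ...) {
  cat("Central-place forager model parameters\n")
  cat(sprintf("  n_max %.3g nests/ha | beta %g m | beta_nest %g m\n",
              x$n_max, x$beta, x$beta_nest))
  cat(sprintf("  workers: a_w %g, b_w %g, w_max %g | queens: a_q %g, b_q %g, q_max %g\n",
              x$a_w, x$b_w, x$w_max, x$a_q, x$b_q, x$q_max))
  cat(sprintf("  p_w %g | rho_F %g | rho_N %g | kernel quantile %g | settle by %s\n",
              x$p_w, x$rho_F, x$rho_N, x$kernel_quantile, x$dispersal_weight))
  invisible(x)
}
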