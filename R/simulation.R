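#' Initialize the queen population
#'
#' Seeds the first spring with colonies drawn cellwise from a Poisson
#' distribution with mean `init_fill * capacity`. The burn-in period of
#' [run_simulation()] then levels populations off, so the exact
#' initialization matters little.
#'
#' @param capacity Nesting-capacity matrix.
#' @param init_fill Fraction of capacity initially occupied, in (0, 1].
#' @return Integer-valued matrix of founding queens. Uses the current
#'   RNG state.
#' @export
initialize_population <- function(capacity, init_fill = 0.5) {
  stopifnot(init_fill > 0, init_fill <= 1)
  matrix(stats::rpois(length(capacity), init_fill * capacity),
         nrow(capacity), ncol(capacity))
}

## precomputed kernel convolutions that depend only on the resource
## rasters (reused across rotation cycles)
season_context <- function(res, params) {
  cs <- res$cell_size
  q <- params$kernel_quantile
  ones <- matrix(1, nrow(res$capacity), ncol(res$capacity))
  list(
    FK = lapply(res$F, disc_convolve, beta = params$beta,
                cell_size = cs, q = q),
    onesK = disc_convolve(ones, params$beta, cs, q),
    capK = if (params$dispersal_weight == "capacity")
      disc_convolve(res$capacity, params$beta_nest, cs, q) else NULL
  )
}

#' Run one full season
#'
#' Chains the within- and between-season processes for one year: queens
#' forage in period 1 (visitation + per-nest resources), workers are
#' produced, the foraging share of workers forages in period 2, new
#' queens are produced from period-2 resources, and finally the new
#' queens disperse, settle under density dependence and are realized by
#' Poisson draws.
#'
#' @param Q Matrix of founding queens (= colonies) this spring.
#' @param res A `bb_resources` object ([build_resources()] or
#'   [apply_scenario()]).
#' @param params A [bb_params()] object.
#' @param ctx Optional precomputed convolution context (internal
#'   optimization used by [run_simulation()]).
#' @return A list with all intermediate rasters: `Q`, `V1`, `R1`, `W`,
#'   `V2`, `R2`, `Q_E`, `settle_intensity`, `Q_next`, `lost`. Uses the
#'   current RNG state (the Poisson settlement draw).
#' @export
run_season <- function(Q, res, params, ctx = NULL) {
  stopifnot(inherits(res, "bb_resources"))
  if (any(Q < 0)) stop("queen counts must be >= 0")
  cs <- res$cell_size
  if (is.null(ctx)) ctx <- season_context(res, params)
  V1 <- visitation_rates(Q, res$F[[1]], params, cs, denom = ctx$FK[[1]])
  R1 <- resources_per_nest(Q, Q, res$F[[1]], params, cs,
                           numer = ctx$FK[[1]], denom = ctx$onesK)
  W <- worker_growth(Q, R1, params)
  X2 <- params$p_w * W
  V2 <- visitation_rates(X2, res$F[[2]], params, cs, denom = ctx$FK[[2]])
  R2 <- resources_per_nest(X2, Q, res$F[[2]], params, cs,
                           numer = ctx$FK[[2]], denom = ctx$onesK)
  Q_E <- Q * params$q_max * growth_cdf(R2, params$a_q, params$b_q)
  disp <- overwinter_disperse(Q_E, res$capacity, params, cs, Q = Q,
                              denom = ctx$capK)
  list(Q = Q, V1 = V1, R1 = R1, W = W, V2 = V2, R2 = R2, Q_E = Q_E,
       settle_intensity = disp$intensity, Q_next = disp$Q_next,
       lost = disp$lost)
}

## buffer-aggregated response row for one simulated year; `strip` is
## the (scenario-independent) strip placement mask, excluded from the
## non-strip visitation metric in every scenario so that the metric
## compares like with like across treatments
aggregate_responses <- function(season, res, mask, cell_size,
                                strip, osr_code = 1L) {
  area_ha <- cell_area_ha(cell_size)
  buffer_ha <- sum(mask) * area_ha
  Qs <- sum(season$Q[mask])
  pf <- function(V, cover, sub = TRUE) {
    sel <- mask & sub & cover > 0
    fa <- sum(cover[sel]) * area_ha
    if (fa > 0) sum(V[sel]) / fa else 0
  }
  osr <- res$landuse == osr_code & mask
  data.frame(
    colonies_per_ha = Qs / buffer_ha,
    mean_workers_per_colony = if (Qs > 0) sum(season$W[mask]) / Qs else 0,
    mean_queens_per_colony = if (Qs > 0) sum(season$Q_E[mask]) / Qs else 0,
    visit_per_flower_p1 = pf(season$V1, res$cover[[1]]),
    visit_per_flower_p2 = pf(season$V2, res$cover[[2]]),
    visit_per_flower_p2_nonstrip = pf(season$V2, res$cover[[2]], !strip),
    osr_visitation = if (any(osr)) sum(season$V1[osr]) / (sum(osr) * area_ha)
                     else 0
  )
}

#' Run a multi-year simulation
#'
#' Replays a rotation of land-use maps for `burn_in_cycles` baseline
#' cycles (to level off the population after initialization) followed by
#' `n_cycles` cycles under the configured management scenario; the
#' population state carries over from burn-in into the treated years.
#' Flower strips are re-placed every year on that year's land use with a
#' deterministic algorithm, so treatments stay comparable. Responses are
#' aggregated within a circular buffer around the landscape center.
#' Extinction is a legitimate trajectory: the run continues with zeros.
#'
#' @param rotation A list of [landscape_year()] objects (e.g. from
#'   [generate_landscape()]), replayed cyclically.
#' @param lut A [resource_lookup()] table.
#' @param params A [bb_params()] object.
#' @param scen A [scenario()] object (baseline by default).
#' @param n_cycles Number of treated rotation cycles (default 5, i.e. 35
#'   years for a 7-year rotation).
#' @param burn_in_cycles Number of baseline cycles before treatment
#'   (default 1).
#' @param seed Integer seed governing every random draw of the run.
#' @param buffer_radius Radius (m) of the response-aggregation buffer;
#'   must fit inside the raster extent.
#' @param init_fill Initial occupancy passed to
#'   [initialize_population()].
#' @param osr_code Land-use code of oilseed rape.
#' @param verbose Print a one-line summary per year?
#' @return A `bb_responses` data.frame with one row per treated year:
#'   `year` (1-based, treatment years only), `colonies_per_ha`,
#'   `mean_workers_per_colony`, `mean_queens_per_colony`,
#'   `visit_per_flower_p1`, `visit_per_flower_p2`,
#'   `visit_per_flower_p2_nonstrip`, `osr_visitation`, `osr_area_ha`,
#'   `edge_area_ha`. Colony counts in year 1 are identical across
#'   scenarios sharing a seed (settlement happens at the end of the
#'   year), which is why analyses typically drop year 1 for population
#'   size.
#' @export
run_simulation <- function(rotation, lut, params = bb_params(),
                           scen = scenario(), n_cycles = 5,
                           burn_in_cycles = 1, seed = 1,
                           buffer_radius = 3000, init_fill = 0.5,
                           osr_code = 1L, verbose = FALSE) {
  stopifnot(n_cycles >= 1, burn_in_cycles >= 0, length(rotation) >= 1)
  land1 <- rotation[[1]]
  cs <- land1$cell_size
  nr <- nrow(land1$landuse); nc <- ncol(land1$landuse)
  if (2 * buffer_radius > min(nr, nc) * cs)
    stop("buffer does not fit within the raster extent")
  mask <- buffer_mask(nr, nc, cs, buffer_radius)
  base_scen <- scenario()
  ## deterministic strip placement per rotation-year: identical across
  ## scenarios, and used to keep the non-strip visitation metric on the
  ## same cell set whether or not strips are sown
  strips <- lapply(rotation, place_flower_strips, lut = lut,
                   params = params, strip_quota = scen$strip_quota)
  strip_masks <- lapply(strips, attr, "mask")
  ## per rotation-year resources and convolution contexts
  base_res <- lapply(rotation, apply_scenario, lut = lut,
                     scen = base_scen, params = params)
  base_ctx <- lapply(base_res, season_context, params = params)
  if (identical(unclass(scen), unclass(base_scen))) {
    trt_res <- base_res; trt_ctx <- base_ctx
  } else {
    trt_res <- lapply(seq_along(rotation), function(y)
      apply_scenario(rotation[[y]], lut, scen, params,
                     strips = strips[[y]]))
    trt_ctx <- lapply(trt_res, season_context, params = params)
  }
  set.seed(seed)
  Q <- initialize_population(base_res[[1]]$capacity, init_fill)
  nyr_rot <- length(rotation)
  for (cyc in seq_len(burn_in_cycles)) {
    for (y in seq_len(nyr_rot)) {
      s <- run_season(Q, base_res[[y]], params, base_ctx[[y]])
      Q <- s$Q_next
    }
  }
  rows <- vector("list", n_cycles * nyr_rot)
  extinct_warned <- FALSE
  yr <- 0L
  for (cyc in seq_len(n_cycles)) {
    for (y in seq_len(nyr_rot)) {
      yr <- yr + 1L
      s <- run_season(Q, trt_res[[y]], params, trt_ctx[[y]])
      cov <- landscape_covariates(rotation[[y]], buffer_radius,
                                  margin_width = margin_width(scen),
                                  osr_code = osr_code)
      row <- aggregate_responses(s, trt_res[[y]], mask, cs,
                                 strip_masks[[y]], osr_code)
      rows[[yr]] <- cbind(data.frame(year = yr), row,
                          data.frame(osr_area_ha = unname(cov[1]),
                                     edge_area_ha = unname(cov[2])))
      if (verbose)
        message(sprintf(
          "year %2d: %.3f colonies/ha, %.1f workers/colony, %.1f queens/colony",
          yr, row$colonies_per_ha, row$mean_workers_per_colony,
          row$mean_queens_per_colony))
      Q <- s$Q_next
      if (sum(Q) == 0 && !extinct_warned) {
        warning("population went extinct in year ", yr,
                "; continuing with zeros", call. = FALSE)
        extinct_warned <- TRUE
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bb_responses", "data.frame")
  out
}

#' Log10 response ratio between a treatment and the baseline
#'
#' @param treatment,baseline Numeric vectors (e.g. yearly response
#'   series); `log10(treatment / baseline)` elementwise. A zero or
#'   negative baseline yields `NaN` with a warning rather than being
#'   dropped.
#' @return Numeric vector of log10 ratios.
#' @export
log_response_ratio <- function(treatment, baseline) {
  stopifnot(length(treatment) == length(baseline))
  bad <- baseline <= 0
  out <- rep(NaN, length(treatment))
  out[!bad] <- log10(treatment[!bad] / baseline[!bad])
  if (any(bad))
    warning(sum(bad), " element(s) with non-positive baseline -> NaN")
  out
}

#' Write a response series to CSV
#'
#' Plain deterministic CSV export (fixed column order, no row names), so
#' identical runs yield byte-identical files.
#'
#' @param responses A `bb_responses` data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
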