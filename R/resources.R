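#' Derive floral and nesting resource rasters from land use
#'
#' Each cell is treated as a mixture of its land-use patch and the grassy
#' field-margin habitat that runs along any field-block edge it contains.
#' The margin fraction of a cell is
#' `f_edge = min(1, edge_length * margin_width / cell_area)`, an
#' area-weighted linear mixing that conserves total habitat area: widening
#' margins displaces crop area rather than adding to it. The floral value
#' of a cell for period k is then
#' `(1 - f_edge) * coverage * attractiveness` of the patch land use plus
#' `f_edge` times the same product for the margin entry of the lookup
#' table; nesting capacity mixes nesting-quality scores the same way and
#' converts to colonies per cell via `n_max` (nests/ha at quality 1) times
#' the cell area in hectares.
#'
#' @param land A [landscape_year()] object.
#' @param lut A [resource_lookup()] table.
#' @param period Floral period, 1 (mass-flowering-crop season) or 2
#'   (late season).
#' @param margin_width Width of the uncultivated field margin in meters
#'   (baseline 2.4, widened 4.8).
#' @return `build_floral_raster()`: a numeric matrix of floral values
#'   (coverage x attractiveness, >= 0).
#' @export
build_floral_raster <- function(land, lut, period, margin_width = 2.4) {
  stopifnot(inherits(land, "bb_landscape"), margin_width >= 0)
  if (!period %in% c(1, 2)) stop("period must be 1 or 2")
  f <- edge_fraction(land, margin_width)
  cov <- lookup_field(lut, land$landuse, paste0("coverage_p", period))
  att <- lookup_field(lut, land$landuse, paste0("attract_p", period))
  m <- lookup_row(lut, "field_margin")
  mF <- m[[paste0("coverage_p", period)]] * m[[paste0("attract_p", period)]]
  (1 - f) * cov * att + f * mF
}

#' @rdname build_floral_raster
#' @return `build_cover_raster()`: a matrix of flowering coverage
#'   proportions (the denominator of per-flower visitation rates).
#' @export
build_cover_raster <- function(land, lut, period, margin_width = 2.4) {
  stopifnot(inherits(land, "bb_landscape"), margin_width >= 0)
  if (!period %in% c(1, 2)) stop("period must be 1 or 2")
  f <- edge_fraction(land, margin_width)
  cov <- lookup_field(lut, land$landuse, paste0("coverage_p", period))
  m <- lookup_row(lut, "field_margin")
  (1 - f) * cov + f * m[[paste0("coverage_p", period)]]
}

#' @rdname build_floral_raster
#' @param params A [bb_params()] object (supplies `n_max`).
#' @return `build_nesting_raster()`: a matrix of maximum colony numbers
#'   per cell (nesting capacity), constant over the season.
#' @export
build_nesting_raster <- function(land, lut, params, margin_width = 2.4) {
  stopifnot(inherits(land, "bb_landscape"), margin_width >= 0)
  f <- edge_fraction(land, margin_width)
  nq <- lookup_field(lut, land$landuse, "nesting_quality")
  nq_m <- lookup_row(lut, "field_margin")$nesting_quality
  ((1 - f) * nq + f * nq_m) * params$n_max * cell_area_ha(land$cell_size)
}

## margin fraction of the cell area, capped at 1
edge_fraction <- function(land, margin_width) {
  pmin(1, land$edge_length * margin_width / land$cell_size^2)
}

#' Bundle all resource rasters for one landscape-year
#'
#' @inheritParams build_floral_raster
#' @param params A [bb_params()] object.
#' @return A `bb_resources` object: floral rasters `F[[k]]` and coverage
#'   rasters `cover[[k]]` for periods k = 1, 2, the nesting `capacity`
#'   raster, and bookkeeping fields (`cell_size`, `margin_width`,
#'   `landuse`).
#' @export
build_resources <- function(land, lut, params, margin_width = 2.4) {
  structure(list(
    F = list(build_floral_raster(land, lut, 1, margin_width),
             build_floral_raster(land, lut, 2, margin_width)),
    cover = list(build_cover_raster(land, lut, 1, margin_width),
                 build_cover_raster(land, lut, 2, margin_width)),
    capacity = build_nesting_raster(land, lut, params, margin_width),
    cell_size = land$cell_size,
    margin_width = margin_width,
    landuse = land$landuse
  ), class = "bb_resources")
}

#' @export
print.bb_resources <- function(x, ...) {
  cat(sprintf("Resource rasters %d x %d (margin width %g m)\n",
              nrow(x$capacity), ncol(x$capacity), x$margin_width))
  cat(sprintf("  total floral value: period 1 %.4g, period 2 %.4g\n",
              sum(x$F[[1]]), sum(x$F[[2]])))
  cat(sprintf("  nesting capacity: %.4g colonies total\n", sum(x$capacity)))
  invisible(x)
}
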