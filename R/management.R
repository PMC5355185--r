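#' Management scenarios
#'
#' The four agri-environment alternatives: baseline (no intervention),
#' widened grassy field margins (2.4 m broadened to 4.8 m, adding nesting
#' habitat), annually re-sown late-flowering flower strips (25 x 50 m
#' strips on ~1.25% of the agricultural land, adding period-2 floral
#' resources), and both combined.
#'
#' @param margins Widen field margins from 2.4 to 4.8 m?
#' @param strips Sow flower strips?
#' @param strip_quota Proportion of agricultural land converted to
#'   strips (default 0.0125, i.e. 1.25%).
#' @return A `bb_scenario` object.
#' @export
scenario <- function(margins = FALSE, strips = FALSE, strip_quota = 0.0125) {
  stopifnot(strip_quota >= 0, strip_quota <= 0.1)
  structure(list(margins = margins, strips = strips,
                 strip_quota = strip_quota),
            class = "bb_scenario")
}

#' @export
print.bb_scenario <- function(x, ...) {
  lab <- c(if (x$margins) "widened margins",
           if (x$strips) sprintf("flower strips (%.3g%% of agric. land)",
                                 100 * x$strip_quota))
  cat("Scenario:", if (length(lab)) paste(lab, collapse = " + ")
      else "baseline", "\n")
  invisible(x)
}

#' Field-margin width implied by a scenario
#'
#' Margins are 2.4 m wide in the baseline and 4.8 m when the
#' margin-widening intervention is active; the widened strip carries
#' maximum nesting quality and very low floral value, so widening can
#' only increase nesting capacity and never increases the floral value of
#' cells bordering a mass-flowering crop.
#'
#' @param scen A [scenario()] object.
#' @return Margin width in meters.
#' @export
margin_width <- function(scen) if (scen$margins) 4.8 else 2.4

#' Place flower strips where they are most beneficial
#'
#' A deterministic stand-in for an optimized placement: candidate strips
#' are horizontal 1 x 2 cell pairs (25 x 50 m) lying fully on
#' agricultural land, ranked by a benefit score -- by default the
#' kernel-weighted nesting capacity within foraging reach minus the
#' kernel-weighted existing period-2 floral supply, so strips go where
#' many colonies can nest but late flowers are scarce. Strips are
#' selected greedily without overlap until
#' `ceiling(quota * agricultural_area / strip_area)` strips are placed
#' (or the agricultural land is exhausted, recorded as a shortfall); ties
#' are broken by row-major cell order. The score is computed from the
#' baseline (2.4 m margin) resources of the unmodified landscape, so all
#' scenarios of a landscape-year select identical strip cells.
#'
#' @param land A [landscape_year()] object.
#' @param lut A [resource_lookup()] table.
#' @param params A [bb_params()] object.
#' @param strip_quota Proportion of agricultural land to convert.
#' @param benefit_score Optional matrix overriding the default score.
#' @return A data.frame with columns `row`, `col1`, `col2` (one row per
#'   strip) and attributes `mask` (logical matrix of strip cells) and
#'   `shortfall` (strips requested but not placeable).
#' @export
place_flower_strips <- function(land, lut, params, strip_quota = 0.0125,
                                benefit_score = NULL) {
  lu <- land$landuse
  nr <- nrow(lu); nc <- ncol(lu)
  ag <- lookup_field(lut, lu, "is_agricultural")
  area_ha <- cell_area_ha(land$cell_size)
  n_strips <- ceiling(strip_quota * sum(ag) * area_ha / (2 * area_ha))
  empty <- data.frame(row = integer(), col1 = integer(), col2 = integer())
  if (n_strips == 0) {
    attr(empty, "mask") <- matrix(FALSE, nr, nc)
    attr(empty, "shortfall") <- 0L
    return(empty)
  }
  if (is.null(benefit_score)) {
    base <- build_resources(land, lut, params, margin_width = 2.4)
    q <- params$kernel_quantile
    capK <- disc_convolve(base$capacity, params$beta, land$cell_size, q)
    f2K <- disc_convolve(base$F[[2]], params$beta, land$cell_size, q)
    ## the two terms live on different scales; standardize each to its
    ## landscape mean so "many potential nests" and "few late flowers"
    ## weigh equally
    benefit_score <- capK / mean(capK) -
      if (mean(f2K) > 0) f2K / mean(f2K) else 0
  }
  check_congruent(lu, benefit_score)
  ## candidate pairs: (r, c) and (r, c + 1), both agricultural
  if (nc < 2) {
    attr(empty, "mask") <- matrix(FALSE, nr, nc)
    attr(empty, "shortfall") <- n_strips
    return(empty)
  }
  left <- which(ag[, -nc, drop = FALSE] & ag[, -1, drop = FALSE])
  r <- ((left - 1) %% nr) + 1
  c1 <- ((left - 1) %/% nr) + 1
  score <- benefit_score[cbind(r, c1)] + benefit_score[cbind(r, c1 + 1)]
  ## rank by score (desc), ties by row-major index of the left cell
  ord <- order(-score, (r - 1) * nc + c1)
  used <- matrix(FALSE, nr, nc)
  sel_r <- integer(0); sel_c <- integer(0)
  for (i in ord) {
    if (length(sel_r) >= n_strips) break
    ri <- r[i]; ci <- c1[i]
    if (used[ri, ci] || used[ri, ci + 1]) next
    used[ri, ci] <- used[ri, ci + 1] <- TRUE
    sel_r <- c(sel_r, ri); sel_c <- c(sel_c, ci)
  }
  shortfall <- n_strips - length(sel_r)
  if (shortfall > 0)
    message("flower-strip shortfall: only ", length(sel_r), " of ",
            n_strips, " strips fit on agricultural land")
  out <- data.frame(row = sel_r, col1 = sel_c, col2 = sel_c + 1L)
  attr(out, "mask") <- used
  attr(out, "shortfall") <- as.integer(shortfall)
  out
}

#' Apply a management scenario to a landscape-year
#'
#' Builds the resource rasters after intervention: flower-strip cells are
#' converted to the `flower_strip` land use (annual re-sowing: the strip
#' replaces the crop for the whole season, so a strip on an early
#' mass-flowering crop removes that cell's period-1 flowers and the total
#' crop area shrinks accordingly), and field margins are built at the
#' scenario's width. The two modifications are independent, so applying
#' them in either order yields the same rasters, and the baseline
#' scenario reproduces the plain [build_resources()] output.
#'
#' @param land A [landscape_year()] object.
#' @param lut A [resource_lookup()] table.
#' @param scen A [scenario()] object.
#' @param params A [bb_params()] object.
#' @param strips Optional precomputed [place_flower_strips()] result
#'   (placement is deterministic, so passing it is purely an
#'   optimization).
#' @return A `bb_resources` object with an extra logical `strip_mask`
#'   field marking strip cells.
#' @export
apply_scenario <- function(land, lut, scen, params, strips = NULL) {
  mask <- matrix(FALSE, nrow(land$landuse), ncol(land$landuse))
  if (scen$strips) {
    if (is.null(strips))
      strips <- place_flower_strips(land, lut, params, scen$strip_quota)
    mask <- attr(strips, "mask")
    land$landuse[mask] <- lookup_row(lut, "flower_strip")$code
  }
  res <- build_resources(land, lut, params, margin_width = margin_width(scen))
  res$strip_mask <- mask
  res
}
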