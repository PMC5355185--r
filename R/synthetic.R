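#' Specification of a synthetic agricultural landscape
#'
#' Describes a square landscape emulating the intensively farmed mosaics
#' of Scania (southern Sweden): rectangular field blocks produced by
#' recursive random splitting, a fixed share of permanent land covers
#' (seminatural grassland, ley, non-habitat), and a crop rotation that
#' moves the mass-flowering crop (oilseed rape, OSR) between arable
#' blocks from year to year so that the OSR share of arable land stays
#' near its target while individual blocks fluctuate.
#'
#' Structural heterogeneity is controlled through `mean_field_size`:
#' smaller blocks mean more field-block edges and hence more grassy
#' margin habitat.
#'
#' @param extent Side length of the square landscape in meters
#'   (default 10000; must be a multiple of `cell_size`).
#' @param cell_size Raster resolution in meters (default 25).
#' @param mean_field_size Target mean field-block area in hectares.
#' @param osr_target Proportion of arable land in oilseed rape each year.
#' @param seminatural_frac,ley_frac,nonhab_frac Area fractions of
#'   permanent (non-rotating) covers; the remainder is arable.
#' @param rotation_length Years in the rotation cycle (default 7).
#' @param seed Integer seed; the same spec always generates the same
#'   landscape.
#' @return A `bb_landscape_spec` object.
#' @export
landscape_spec <- function(extent = 10000, cell_size = 25,
                           mean_field_size = 8, osr_target = 0.12,
                           seminatural_frac = 0.08, ley_frac = 0.15,
                           nonhab_frac = 0.05, rotation_length = 7,
                           seed = 1) {
  stopifnot(extent %% cell_size == 0, extent >= 4 * cell_size,
            mean_field_size > 0,
            osr_target >= 0, osr_target <= 0.5,
            seminatural_frac >= 0, ley_frac >= 0, nonhab_frac >= 0,
            seminatural_frac + ley_frac + nonhab_frac < 1,
            rotation_length >= 1)
  structure(list(extent = extent, cell_size = cell_size,
                 mean_field_size = mean_field_size,
                 osr_target = osr_target,
                 seminatural_frac = seminatural_frac,
                 ley_frac = ley_frac, nonhab_frac = nonhab_frac,
                 rotation_length = as.integer(rotation_length),
                 seed = as.integer(seed)),
            class = "bb_landscape_spec")
}

## run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic landscape rotation
#'
#' Tessellates the extent into rectangular field blocks (recursive binary
#' splitting with randomized split points, aiming at the spec's mean
#' block area), assigns permanent covers to whole blocks by area quota,
#' and builds one land-use raster per rotation year by assigning oilseed
#' rape to a changing subset of arable blocks (never the same block in
#' two consecutive years, wrapping around the cycle) until the OSR area
#' target is met; remaining arable blocks grow cereal. The field-edge
#' raster holds meters of field-block boundary per cell (half of each
#' shared boundary is booked to either side; only cells of agricultural
#' land uses carry margins) and is identical across years since block
#' geometry is fixed.
#'
#' @param spec A [landscape_spec()] object.
#' @return A list of `rotation_length` [landscape_year()] objects with
#'   attributes `block_id` (integer matrix) and `spec`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "bb_landscape_spec"))
  with_seed(spec$seed, {
    n <- spec$extent / spec$cell_size
    blocks <- split_blocks(n, n, spec$mean_field_size /
                                   cell_area_ha(spec$cell_size))
    block_id <- matrix(0L, n, n)
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      block_id[bl$r1:bl$r2, bl$c1:bl$c2] <- b
    }
    areas <- vapply(blocks, function(b)
      (b$r2 - b$r1 + 1) * (b$c2 - b$c1 + 1), numeric(1))
    total <- sum(areas)
    cent_r <- vapply(blocks, function(b) (b$r1 + b$r2) / 2, numeric(1))
    cent_c <- vapply(blocks, function(b) (b$c1 + b$c2) / 2, numeric(1))
    ## permanent covers assigned to whole blocks by area quota;
    ## seminatural grassland clusters around a few foci (streams,
    ## pastures), as in real agricultural mosaics, rather than being
    ## scattered uniformly
    type <- rep("arable", length(blocks))
    pick_cluster <- function(frac, n_foci, avoid) {
      if (frac <= 0) return(integer(0))
      foci <- sample.int(length(blocks), n_foci)
      d <- sapply(foci, function(f)
        sqrt((cent_r - cent_r[f])^2 + (cent_c - cent_c[f])^2))
      dmin <- if (is.matrix(d)) apply(d, 1, min) else d
      ord <- setdiff(order(dmin), avoid)
      ord[cumsum(areas[ord]) <= frac * total]
    }
    semi <- pick_cluster(spec$seminatural_frac, 2, integer(0))
    type[semi] <- "seminatural"
    ley <- pick_cluster(spec$ley_frac, 3, semi)
    type[ley] <- "ley"
    nh_cand <- setdiff(sample.int(length(blocks)), c(semi, ley))
    nh <- nh_cand[cumsum(areas[nh_cand]) <= spec$nonhab_frac * total]
    type[nh] <- "non_habitat"
    arable <- which(type == "arable")
    arable_area <- sum(areas[arable])
    ## per-year OSR block sets: seeded order, no block two years running
    osr_sets <- vector("list", spec$rotation_length)
    prev <- integer(0)
    for (y in seq_len(spec$rotation_length)) {
      cand <- arable[order(stats::runif(length(arable)))]
      pick <- integer(0); acc <- 0
      for (b in cand) {
        if (acc >= spec$osr_target * arable_area) break
        if (b %in% prev) next
        ## year 1 and the last year are adjacent in the replayed cycle
        if (y == spec$rotation_length && b %in% osr_sets[[1]]) next
        pick <- c(pick, b); acc <- acc + areas[b]
      }
      osr_sets[[y]] <- pick
      prev <- pick
    }
    code <- c(oilseed_rape = 1L, cereal = 2L, ley = 3L, seminatural = 4L,
              non_habitat = 5L)
    base_code <- code[c(arable = "cereal", seminatural = "seminatural",
                        ley = "ley", non_habitat = "non_habitat")[type]]
    edge <- edge_raster(block_id, spec$cell_size)
    years <- vector("list", spec$rotation_length)
    for (y in seq_len(spec$rotation_length)) {
      bc <- base_code
      bc[osr_sets[[y]]] <- code[["oilseed_rape"]]
      lu <- matrix(bc[block_id], n, n)
      ## margins only along edges of agricultural (arable) cells
      ag <- lu %in% c(code[["oilseed_rape"]], code[["cereal"]],
                      code[["ley"]])
      e <- edge
      e[!matrix(ag, n, n)] <- 0
      years[[y]] <- landscape_year(lu, e, spec$cell_size, year_index = y)
    }
    attr(years, "block_id") <- block_id
    attr(years, "spec") <- spec
    years
  })
}

## recursive binary splitting of an nr x nc grid into rectangles with
## target area (cells); randomized split fractions in [0.35, 0.65]
split_blocks <- function(nr, nc, target_cells) {
  out <- list()
  queue <- list(list(r1 = 1L, r2 = nr, c1 = 1L, c2 = nc))
  while (length(queue)) {
    b <- queue[[1]]; queue <- queue[-1]
    h <- b$r2 - b$r1 + 1L; w <- b$c2 - b$c1 + 1L
    ## randomize the stopping area so block sizes vary around the target
    if (h * w <= target_cells * stats::runif(1, 0.6, 1.8) ||
        (h < 2 && w < 2)) {
      out[[length(out) + 1L]] <- b
      next
    }
    f <- stats::runif(1, 0.35, 0.65)
    if (h >= w) {
      cut <- b$r1 + max(0L, min(h - 2L, as.integer(round(f * h)) - 1L))
      queue <- c(queue, list(list(r1 = b$r1, r2 = cut, c1 = b$c1, c2 = b$c2),
                             list(r1 = cut + 1L, r2 = b$r2,
                                  c1 = b$c1, c2 = b$c2)))
    } else {
      cut <- b$c1 + max(0L, min(w - 2L, as.integer(round(f * w)) - 1L))
      queue <- c(queue, list(list(r1 = b$r1, r2 = b$r2, c1 = b$c1, c2 = cut),
                             list(r1 = b$r1, r2 = b$r2,
                                  c1 = cut + 1L, c2 = b$c2)))
    }
  }
  out
}

## meters of block boundary per cell: half of each shared 4-neighbor
## boundary; the raster border is not counted (the world continues)
edge_raster <- function(block_id, cell_size) {
  nr <- nrow(block_id); nc <- ncol(block_id)
  e <- matrix(0, nr, nc)
  half <- cell_size / 2
  dif <- block_id[-nr, ] != block_id[-1, ]
  e[-nr, ] <- e[-nr, ] + half * dif
  e[-1, ] <- e[-1, ] + half * dif
  dif <- block_id[, -nc] != block_id[, -1]
  e[, -nc] <- e[, -nc] + half * dif
  e[, -1] <- e[, -1] + half * dif
  e
}

#' Landscape-scale covariates within the analysis buffer
#'
#' The two landscape descriptors of the study design: the area of
#' oilseed rape and the area of field-block edge habitat (structural
#' heterogeneity, HET) within a circular buffer around the landscape
#' center.
#'
#' @param land A [landscape_year()] object.
#' @param buffer_radius Buffer radius in meters.
#' @param margin_width Margin width used to convert edge length to edge
#'   area (baseline 2.4 m).
#' @param osr_code Land-use code of oilseed rape (default 1).
#' @return Named numeric vector `c(osr_area_ha, edge_area_ha)`.
#' @export
landscape_covariates <- function(land, buffer_radius, margin_width = 2.4,
                                 osr_code = 1L) {
  m <- buffer_mask(nrow(land$landuse), ncol(land$landuse),
                   land$cell_size, buffer_radius)
  c(osr_area_ha = sum(land$landuse[m] == osr_code) *
      cell_area_ha(land$cell_size),
    edge_area_ha = sum(land$edge_length[m]) * margin_width / 1e4)
}

#' Sample an ensemble of landscape specs with uncorrelated gradients
#'
#' Draws `n` specs whose oilseed-rape targets and mean field sizes
#' (hence edge densities) are sampled independently, emulating a
#' landscape selection along uncorrelated gradients of mass-flowering
#' crop cover and structural heterogeneity. Default ranges are chosen so
#' that, at the default 10-km extent with a 3-km analysis buffer, OSR
#' area spans roughly 14-323 ha and edge area roughly 17-78 ha.
#'
#' @param n Number of landscapes.
#' @param seed Integer seed.
#' @param extent,cell_size Passed to [landscape_spec()].
#' @param osr_range Range of `osr_target` (uniform draw).
#' @param field_size_range Range of `mean_field_size` in hectares
#'   (log-uniform draw).
#' @param ... Further arguments passed to [landscape_spec()].
#' @return A list of `n` [landscape_spec()] objects.
#' @export
sample_landscape_specs <- function(n, seed = 1, extent = 10000,
                                   cell_size = 25,
                                   osr_range = c(0.008, 0.17),
                                   field_size_range = c(2.5, 55), ...) {
  with_seed(seed, {
    lapply(seq_len(n), function(i)
      landscape_spec(extent = extent, cell_size = cell_size,
                     osr_target = stats::runif(1, osr_range[1], osr_range[2]),
                     mean_field_size = exp(stats::runif(
                       1, log(field_size_range[1]), log(field_size_range[2]))),
                     seed = seed * 1000L + i, ...))
  })
}
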