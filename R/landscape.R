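#' A land-use raster plus field-edge raster for one year
#'
#' The physical template of the model: a categorical land-use/crop grid
#' and a grid holding the length (m) of field-block edges per cell, both
#' at the same resolution (25 m cells by default). Field-block edges are
#' where the uncultivated grassy margins sit.
#'
#' @param landuse Integer matrix of land-use codes (see [resource_lookup()]).
#' @param edge_length Numeric matrix, meters of field-block edge per cell.
#'   Must have the same dimensions as `landuse`; each cell can hold at
#'   most `4 * cell_size` meters of edge (two crossing borders).
#' @param cell_size Cell side length in meters (default 25).
#' @param year_index Position of this map in a rotation sequence.
#' @return A `bb_landscape` object.
#' @export
landscape_year <- function(landuse, edge_length = NULL, cell_size = 25,
                           year_index = 1L) {
  landuse <- as.matrix(landuse)
  storage.mode(landuse) <- "integer"
  if (is.null(edge_length))
    edge_length <- matrix(0, nrow(landuse), ncol(landuse))
  edge_length <- as.matrix(edge_length)
  if (!identical(dim(landuse), dim(edge_length)))
    stop("landuse and edge_length must have identical dimensions")
  if (any(edge_length < 0))
    stop("edge_length must be >= 0 everywhere")
  if (any(edge_length > 4 * cell_size + 1e-9))
    stop("edge_length exceeds the geometric maximum of 4 * cell_size")
  stopifnot(cell_size > 0)
  structure(list(landuse = landuse, edge_length = edge_length,
                 cell_size = cell_size, year_index = as.integer(year_index)),
            class = "bb_landscape")
}

#' @export
print.bb_landscape <- function(x, ...) {
  cat(sprintf("Landscape year %d: %d x %d cells of %g m (%.1f ha)\n",
              x$year_index, nrow(x$landuse), ncol(x$landuse), x$cell_size,
              length(x$landuse) * cell_area_ha(x$cell_size)))
  tab <- table(x$landuse)
  cat("  land-use codes:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

cell_area_ha <- function(cell_size) cell_size^2 / 1e4

## cell-center coordinates (m) for an nr x nc grid; rows run north-south
cell_centers <- function(nr, nc, cell_size) {
  list(x = (seq_len(nc) - 0.5) * cell_size,
       y = (seq_len(nr) - 0.5) * cell_size)
}

#' Circular buffer mask around the landscape center
#'
#' Cells belong to the buffer when their center lies within
#' `buffer_radius` of the center of the raster extent.
#'
#' @param nr,nc Grid dimensions.
#' @param cell_size Cell side length (m).
#' @param buffer_radius Radius in meters.
#' @return A logical matrix.
#' @export
buffer_mask <- function(nr, nc, cell_size, buffer_radius) {
  cc <- cell_centers(nr, nc, cell_size)
  cx <- nc * cell_size / 2
  cy <- nr * cell_size / 2
  outer((cc$y - cy)^2, (cc$x - cx)^2, "+") <= buffer_radius^2
}
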