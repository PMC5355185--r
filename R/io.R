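#' Read and write rasters as ESRI ASCII grids
#'
#' Minimal plain-text raster I/O in the widely used ESRI ASCII grid
#' (`.asc`) format, enough to exchange land-use, edge and result rasters
#' with GIS software. Row 1 of the matrix is the northernmost row, as in
#' the format itself. No installed package in this stack handles the
#' format, so the (six-line-header) parser is implemented here.
#'
#' @param mat Numeric matrix to write.
#' @param path File path.
#' @param cell_size Cell size in meters (written as `cellsize`).
#' @param xllcorner,yllcorner Coordinates of the lower-left corner.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `write_ascii_grid()` invisibly returns `path`;
#'   `read_ascii_grid()` returns a numeric matrix with attribute
#'   `cell_size` (NODATA cells become `NA`).
#' @export
write_ascii_grid <- function(mat, path, cell_size = 25,
                             xllcorner = 0, yllcorner = 0,
                             nodata = -9999) {
  mat[is.na(mat)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", xllcorner),
    paste("yllcorner", yllcorner),
    paste("cellsize", cell_size),
    paste("NODATA_value", nodata)), con)
  utils::write.table(mat, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  n_hdr <- sum(keys %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                           "cellsize", "nodata_value"))
  body <- scan(path, skip = n_hdr, quiet = TRUE)
  mat <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
                byrow = TRUE)
  if ("nodata_value" %in% keys)
    mat[mat == vals[["nodata_value"]]] <- NA
  attr(mat, "cell_size") <- unname(vals[["cellsize"]])
  mat
}
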