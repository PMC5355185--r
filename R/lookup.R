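#' Land-use resource lookup tables
#'
#' A resource lookup table maps every categorical land-use code that can
#' occur in a land-use raster to the quantities the model needs: the
#' proportion of the cell area covered by flowering plants in each of the
#' two floral periods (`coverage_p1`, `coverage_p2`), a species-specific
#' attractiveness score per period (`attract_p1`, `attract_p2`), a nesting
#' quality score in \[0, 1\] (`nesting_quality`), and whether the land use
#' is agricultural and hence eligible for management interventions
#' (`is_agricultural`). The per-cell floral resource value for period k is
#' the product coverage x attractiveness.
#'
#' Two special land uses must always be present, referenced by name:
#' `field_margin` (the uncultivated grassy strip along field-block edges;
#' maximum nesting quality, very low floral value) and `flower_strip`
#' (sown late-flowering strips; high period-2 coverage, maximum
#' attractiveness, low nesting quality).
#'
#' @param df A data.frame with columns `code`, `name`, `coverage_p1`,
#'   `coverage_p2`, `attract_p1`, `attract_p2`, `nesting_quality`,
#'   `is_agricultural`.
#' @return A validated `bb_lookup` data.frame.
#' @seealso [default_resource_lookup()], [read_resource_lookup()]
#' @export
resource_lookup <- function(df) {
  need <- c("code", "name", "coverage_p1", "coverage_p2", "attract_p1",
            "attract_p2", "nesting_quality", "is_agricultural")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("lookup table lacks columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$code <- as.integer(df$code)
  df$is_agricultural <- as.logical(df$is_agricultural)
  if (anyDuplicated(df$code))
    stop("duplicated land-use codes in lookup table")
  cov <- as.matrix(df[c("coverage_p1", "coverage_p2")])
  if (any(cov < 0 | cov > 1))
    stop("floral coverages must lie in [0, 1]")
  if (any(df[c("attract_p1", "attract_p2")] < 0))
    stop("attractiveness scores must be >= 0")
  if (any(df$nesting_quality < 0 | df$nesting_quality > 1))
    stop("nesting_quality must lie in [0, 1]")
  for (nm in c("field_margin", "flower_strip"))
    if (!nm %in% df$name)
      stop("lookup table must contain a '", nm, "' entry")
  class(df) <- c("bb_lookup", "data.frame")
  df
}

#' Default synthetic resource lookup table
#'
#' A documented stand-in for an expert-elicited scoring of southern
#' Swedish agricultural land uses. It is synthetic: values were chosen to
#' honour the qualitative structure of the system -- oilseed rape is a
#' mass-flowering crop with a large period-1 pulse and nothing in period
#' 2; cereal offers almost no resources; leys and seminatural grassland
#' flower moderately in both periods, with seminatural land also the best
#' nesting habitat; field margins have maximum nesting quality but very
#' low floral value in both periods; flower strips have high period-2
#' coverage at maximum attractiveness but poor nesting quality -- and
#' scaled so that, with the default growth parameters, baseline
#' populations persist without saturating the landscape. Late-season
#' (period 2) flowers are the scarce, limiting resource.
#'
#' @return A `bb_lookup` data.frame with seven land uses.
#' @export
default_resource_lookup <- function() {
  resource_lookup(data.frame(
    code = 1:7,
    name = c("oilseed_rape", "cereal", "ley", "seminatural",
             "non_habitat", "flower_strip", "field_margin"),
    coverage_p1 = c(0.90, 0.02, 0.40, 0.60, 0, 0.00, 0.04),
    coverage_p2 = c(0.00, 0.01, 0.15, 0.30, 0, 0.90, 0.05),
    attract_p1  = c( 600,  100, 1000, 1000, 0,    0,   60),
    attract_p2  = c(   0,  100,  133,  620, 0, 1000,   60),
    nesting_quality = c(0.05, 0.05, 0.30, 1.00, 0, 0.05, 1.00),
    is_agricultural = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  ))
}

#' Read / write resource lookup tables as CSV
#'
#' @param path Path to a CSV file with the columns listed in
#'   [resource_lookup()].
#' @return `read_resource_lookup()` returns a `bb_lookup`;
#'   `write_resource_lookup()` invisibly returns `path`.
#' @export
read_resource_lookup <- function(path) {
  resource_lookup(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_resource_lookup
#' @param lut A `bb_lookup` table.
#' @export
write_resource_lookup <- function(lut, path) {
  utils::write.csv(as.data.frame(lut), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

lookup_row <- function(lut, name) {
  i <- match(name, lut$name)
  if (is.na(i)) stop("lookup table has no '", name, "' entry")
  lut[i, ]
}

## map a land-use code matrix to a lookup column, failing on unknown codes
lookup_field <- function(lut, codes, field) {
  i <- match(codes, lut$code)
  if (anyNA(i[!is.na(codes)])) {
    bad <- unique(codes[is.na(i) & !is.na(codes)])
    stop("unknown land-use code(s): ", paste(bad, collapse = ", "))
  }
  out <- lut[[field]][i]
  dim(out) <- dim(codes)
  out
}
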