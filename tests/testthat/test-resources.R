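simple_lut <- function() {
  resource_lookup(data.frame(
    code = c(1L, 2L, 7L, 6L),
    name = c("crop", "bare", "field_margin", "flower_strip"),
    coverage_p1 = c(0.8, 0, 0.1, 0),
    coverage_p2 = c(0.0, 0, 0.1, 0.9),
    attract_p1 = c(1.0, 0, 1.0, 0),
    attract_p2 = c(1.0, 0, 1.0, 1.0),
    nesting_quality = c(0, 0, 1, 0.05),
    is_agricultural = c(TRUE, FALSE, FALSE, FALSE)
  ))
}

test_that("floral raster is coverage x attractiveness with margin mixing", {
  lut <- simple_lut()
  # no-edge cell: pure product
  land <- landscape_year(matrix(1L, 2, 2))
  expect_equal(build_floral_raster(land, lut, 1),
               matrix(0.8, 2, 2))
  # zero coverage in period 2 (crop after flowering) -> F2 = 0
  expect_equal(build_floral_raster(land, lut, 2), matrix(0, 2, 2))
  # mixing: cell area 625 m2, 50 m edge, 2.4 m margin -> f_edge = 0.192;
  # patch F = 1, margin F = 0.1 -> 0.808 * 1 + 0.192 * 0.1 = 0.8272
  lut2 <- simple_lut()
  lut2$coverage_p1[1] <- 1; lut2$attract_p1[1] <- 1
  land2 <- landscape_year(matrix(1L, 1, 1), matrix(50, 1, 1))
  expect_equal(build_floral_raster(land2, lut2, 1, margin_width = 2.4)[1, 1],
               0.8272)
  expect_error(build_floral_raster(land, lut, 3), "period")
  land3 <- landscape_year(matrix(99L, 1, 1))
  expect_error(build_floral_raster(land3, lut, 1), "99")
})

test_that("nesting raster converts quality scores to colonies per cell", {
  lut <- simple_lut()
  p <- bb_params()
  # NQ = 1 margin-only comparison: a hypothetical NQ = 1 cell holds
  # n_max * cell_area = 19.6 * 0.0625 = 1.225 colonies
  lutq <- simple_lut(); lutq$nesting_quality[1] <- 1
  land <- landscape_year(matrix(1L, 1, 1))
  expect_equal(build_nesting_raster(land, lutq, p)[1, 1], 1.225)
  # NQ = 0, no edges -> 0
  expect_equal(build_nesting_raster(land, simple_lut(), p)[1, 1], 0)
  # margin NQ = 1, patch NQ = 0, f_edge = 0.192 -> 0.192 * 1.225
  land2 <- landscape_year(matrix(1L, 1, 1), matrix(50, 1, 1))
  expect_equal(build_nesting_raster(land2, simple_lut(), p)[1, 1],
               0.192 * 1.225)
})

test_that("widening margins never lowers capacity nor raises floral value
           next to a mass-flowering crop", {
  lut <- default_resource_lookup()
  p <- bb_params()
  land <- toy_landscape()
  for (w in list(c(2.4, 4.8), c(4.8, 9.6))) {
    cap1 <- build_nesting_raster(land, lut, p, w[1])
    cap2 <- build_nesting_raster(land, lut, p, w[2])
    expect_true(all(cap2 - cap1 >= -1e-12))
  }
  f1a <- build_floral_raster(land, lut, 1, 2.4)
  f1b <- build_floral_raster(land, lut, 1, 4.8)
  osr_edge <- land$landuse == 1L & land$edge_length > 0
  expect_true(all(f1b[osr_edge] <= f1a[osr_edge] + 1e-12))
})

test_that("edge fraction saturates and capacity respects n_max", {
  lut <- simple_lut()
  p <- bb_params()
  land <- landscape_year(matrix(1L, 1, 1), matrix(100, 1, 1))
  # 100 m x 10 m margin > cell area -> f_edge capped at 1
  cap <- build_nesting_raster(land, lut, p, margin_width = 10)
  expect_equal(cap[1, 1], 1.225)
  land2 <- toy_landscape()
  cap2 <- build_nesting_raster(land2, default_resource_lookup(), p, 4.8)
  expect_true(all(cap2 <= p$n_max * 0.0625 + 1e-12))
})

test_that("resource building is a pure per-cell map", {
  lut <- default_resource_lookup()
  p <- bb_params()
  land <- toy_landscape()
  res <- build_resources(land, lut, p)
  # transposing inputs transposes outputs exactly (traversal-order free)
  landT <- landscape_year(t(land$landuse), t(land$edge_length))
  resT <- build_resources(landT, lut, p)
  expect_identical(t(res$F[[1]]), resT$F[[1]])
  expect_identical(t(res$capacity), resT$capacity)
})

test_that("lookup table validation catches malformed input", {
  expect_error(resource_lookup(data.frame(code = 1)), "lacks columns")
  bad <- as.data.frame(default_resource_lookup())
  bad$coverage_p1[1] <- 1.4
  expect_error(resource_lookup(bad), "\\[0, 1\\]")
  dup <- as.data.frame(default_resource_lookup())
  dup$code[2] <- dup$code[1]
  expect_error(resource_lookup(dup), "duplicated")
})

test_that("lookup CSV round-trips", {
  path <- tempfile(fileext = ".csv")
  lut <- default_resource_lookup()
  write_resource_lookup(lut, path)
  back <- read_resource_lookup(path)
  expect_equal(as.data.frame(back), as.data.frame(lut))
})
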