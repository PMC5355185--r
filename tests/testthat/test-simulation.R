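test_that("population initialization is Poisson around the target fill", {
  cap <- matrix(c(0, 1.225), 2, 50)
  set.seed(1)
  Q <- initialize_population(cap, init_fill = 1)
  expect_true(all(Q[cap == 0] == 0))
  expect_true(all(Q >= 0))
  expect_true(all(Q == round(Q)))
  set.seed(7); a <- initialize_population(cap, 0.5)
  set.seed(7); b <- initialize_population(cap, 0.5)
  expect_identical(a, b)
  # large-sample mean close to init_fill * capacity
  set.seed(2)
  big <- initialize_population(matrix(1.225, 100, 100), 1)
  expect_equal(mean(big), 1.225, tolerance = 0.05)
})

test_that("an empty landscape stays empty through a season", {
  lut <- default_resource_lookup()
  p <- bb_params()
  land <- toy_landscape()
  res <- build_resources(land, lut, p)
  s <- run_season(matrix(0, 16, 16), res, p)
  for (f in c("V1", "W", "V2", "Q_E", "settle_intensity", "Q_next"))
    expect_true(all(s[[f]] == 0), info = f)
})

test_that("a two-cell season reproduces the hand-computed chain", {
  p <- bb_params()
  cs <- 25
  F1 <- c(200, 50); F2 <- c(40, 10)
  Q <- c(2, 1); cap <- c(1.0, 0.8)
  lut <- resource_lookup(data.frame(
    code = c(1L, 2L, 6L, 7L),
    name = c("a", "b", "flower_strip", "field_margin"),
    coverage_p1 = c(0.5, 0.5, 0, 0.1),
    coverage_p2 = c(0.5, 0.5, 0.9, 0.1),
    attract_p1 = c(F1 / 0.5, 0, 0),
    attract_p2 = c(F2 / 0.5, 1000, 0),
    nesting_quality = c(cap / 1.225, 0.05, 1),
    is_agricultural = c(TRUE, TRUE, FALSE, FALSE)))
  land <- landscape_year(matrix(c(1L, 2L), 1, 2))
  res <- build_resources(land, lut, p)
  expect_equal(res$F[[1]], matrix(F1, 1, 2))
  expect_equal(res$capacity, matrix(cap, 1, 2), tolerance = 1e-12)

  set.seed(31)
  s <- run_season(matrix(Q, 1, 2), res, p)

  ## independent scalar computation of the full season
  K <- exp(-cs / p$beta)
  D <- c(F1[1] + F1[2] * K, F1[2] + F1[1] * K)  # normalization per source
  V1 <- c(Q[1] * F1[1] / D[1] + Q[2] * F1[1] * K / D[2],
          Q[1] * F1[2] * K / D[1] + Q[2] * F1[2] / D[2])
  R1 <- c((F1[1] + F1[2] * K), (F1[2] + F1[1] * K)) / (1 + K)
  W <- Q * p$w_max * bf_growth_cdf(R1, p$a_w, p$b_w)
  X2 <- p$p_w * W
  D2 <- c(F2[1] + F2[2] * K, F2[2] + F2[1] * K)
  V2 <- c(X2[1] * F2[1] / D2[1] + X2[2] * F2[1] * K / D2[2],
          X2[1] * F2[2] * K / D2[1] + X2[2] * F2[2] / D2[2])
  R2 <- (X2 / Q) * c(F2[1] + F2[2] * K, F2[2] + F2[1] * K) / (1 + K)
  QE <- Q * p$q_max * bf_growth_cdf(R2, p$a_q, p$b_q)
  Kn <- exp(-cs / p$beta_nest)
  Dw <- c(cap[1] + cap[2] * Kn, cap[2] + cap[1] * Kn)
  A <- c(cap[1] * (QE[1] / Dw[1] + QE[2] * Kn / Dw[2]),
         cap[2] * (QE[1] * Kn / Dw[1] + QE[2] / Dw[2]))
  intensity <- pmin(A, cap)

  expect_equal(as.numeric(s$V1), V1, tolerance = 1e-9)
  expect_equal(as.numeric(s$R1), R1, tolerance = 1e-9)
  expect_equal(as.numeric(s$W), W, tolerance = 1e-9)
  expect_equal(as.numeric(s$V2), V2, tolerance = 1e-9)
  expect_equal(as.numeric(s$R2), R2, tolerance = 1e-9)
  expect_equal(as.numeric(s$Q_E), QE, tolerance = 1e-9)
  expect_equal(as.numeric(s$settle_intensity), intensity, tolerance = 1e-9)
})

test_that("the driver produces one response row per simulated year", {
  lut <- default_resource_lookup()
  p <- reference_params()
  rot <- generate_landscape(landscape_spec(extent = 1000, seed = 4,
                                           mean_field_size = 2))
  r <- suppressWarnings(run_simulation(rot, lut, p, n_cycles = 5,
                                       burn_in_cycles = 0, seed = 3,
                                       buffer_radius = 400))
  expect_s3_class(r, "bb_responses")
  expect_equal(nrow(r), 35)
  expect_equal(r$year, 1:35)
  expect_true(all(vapply(r, is.numeric, TRUE)))
  expect_true(all(as.matrix(r) >= 0))
})

test_that("identical configuration and seed give identical responses", {
  lut <- default_resource_lookup()
  p <- reference_params()
  rot <- generate_landscape(landscape_spec(extent = 1000, seed = 8,
                                           mean_field_size = 2))
  run1 <- suppressWarnings(run_simulation(rot, lut, p, scenario(TRUE, TRUE),
                                          n_cycles = 1, seed = 11,
                                          buffer_radius = 400))
  run2 <- suppressWarnings(run_simulation(rot, lut, p, scenario(TRUE, TRUE),
                                          n_cycles = 1, seed = 11,
                                          buffer_radius = 400))
  expect_identical(run1, run2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_responses(run1, f1); write_responses(run2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("extinction is a warned, legitimate trajectory", {
  lut <- default_resource_lookup()
  p <- bb_params()
  land <- landscape_year(matrix(5L, 20, 20))  # all non-habitat
  expect_warning(
    r <- run_simulation(list(land), lut, p, n_cycles = 2, seed = 1,
                        buffer_radius = 200),
    "extinct")
  expect_true(all(r$colonies_per_ha == 0))
})

test_that("buffer aggregation is consistent with the population raster", {
  lut <- default_resource_lookup()
  p <- bb_params()
  rot <- generate_landscape(landscape_spec(extent = 1000, seed = 12,
                                           mean_field_size = 2))
  r <- suppressWarnings(run_simulation(rot, lut, p, n_cycles = 1,
                                       burn_in_cycles = 0, seed = 21,
                                       buffer_radius = 400))
  ## replay the driver's first year by hand with the same seed
  res <- apply_scenario(rot[[1]], lut, scenario(), p)
  set.seed(21)
  Q <- initialize_population(res$capacity, 0.5)
  mask <- buffer_mask(40, 40, 25, 400)
  expect_equal(r$colonies_per_ha[1], sum(Q[mask]) / (sum(mask) * 0.0625),
               tolerance = 1e-12)
})

test_that("log response ratios behave", {
  expect_equal(log_response_ratio(c(1, 10, 0.5), c(1, 1, 1)),
               c(0, 1, log10(0.5)))
  expect_equal(log_response_ratio(2, 4), log10(0.5), tolerance = 1e-12)
  expect_warning(out <- log_response_ratio(c(1, 2), c(1, 0)),
                 "non-positive")
  expect_true(is.nan(out[2]))
  expect_equal(out[1], 0)
})
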