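test_that("growth CDF has the median and limit properties", {
  expect_equal(growth_cdf(100, 100, 200), 0.5)
  expect_equal(growth_cdf(15000, 15000, 30000), 0.5)
  expect_equal(growth_cdf(0, 100, 200), 0)
  # strictly increasing (within the numerically representable range)
  r <- seq(0, 200, by = 10)
  expect_true(all(diff(growth_cdf(r, 100, 200)) > 0))
  expect_error(growth_cdf(10, -1, 200), "> 0")
  expect_error(growth_cdf(-1, 100, 200), ">= 0")
  # matrix shape preserved
  m <- matrix(c(0, 100, 200, 300), 2, 2)
  expect_identical(dim(growth_cdf(m, 100, 200)), c(2L, 2L))
})

test_that("closed-form sigma^2 satisfies the lognormal variance identity
           and matches a numeric root-find", {
  for (ab in list(c(100, 200), c(15000, 30000), c(3, 10))) {
    a <- ab[1]; b <- ab[2]
    s2 <- bombusim:::lognormal_sigma2(a, b)
    expect_equal((exp(s2) - 1) * exp(2 * log(a) + s2), b,
                 tolerance = 1e-12)
    expect_equal(growth_cdf(1.3 * a, a, b), bf_growth_cdf(1.3 * a, a, b),
                 tolerance = 1e-9)
  }
})

test_that("worker growth saturates at w_max per queen", {
  p <- bb_params()
  Q <- matrix(1, 2, 2)
  expect_equal(worker_growth(Q, matrix(100, 2, 2), p),
               matrix(300, 2, 2))
  expect_equal(worker_growth(Q, matrix(0, 2, 2), p), matrix(0, 2, 2))
  expect_equal(worker_growth(2 * Q, matrix(1e9, 2, 2), p),
               matrix(1200, 2, 2), tolerance = 1e-9)
})

test_that("queen production follows period-2 resources", {
  p <- bb_params()
  # uniform landscape, R2 = p_w * W/Q * F2-mean; choose W so R2 = a_q
  Q <- matrix(1, 6, 6)
  W <- matrix(600, 6, 6)
  F2 <- matrix(p$a_q / (p$p_w * 600), 6, 6)
  QE <- queen_production(Q, W, F2, p, 25)
  expect_equal(QE, matrix(80, 6, 6), tolerance = 1e-9)
  expect_equal(queen_production(Q, matrix(0, 6, 6), F2, p, 25),
               matrix(0, 6, 6))
  # more foraging workers never hurt
  p25 <- bb_params(p_w = 0.25)
  p50 <- bb_params(p_w = 0.5)
  set.seed(5)
  W <- matrix(runif(36, 0, 600), 6, 6)
  F2 <- matrix(runif(36, 0, 100), 6, 6)
  expect_true(all(queen_production(Q, W, F2, p50, 25) >=
                  queen_production(Q, W, F2, p25, 25) - 1e-12))
})

test_that("demographic bounds hold on random inputs", {
  p <- bb_params()
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    Q <- matrix(rpois(n * n, 2), n, n)
    R1 <- matrix(rexp(n * n, 1 / 150), n, n)
    W <- worker_growth(Q, R1, p)
    expect_true(all(W <= Q * 600 + 1e-9))
    F2 <- matrix(rexp(n * n, 1 / 50), n, n)
    QE <- queen_production(Q, W, F2, p, 25)
    expect_true(all(QE <= Q * 160 + 1e-9))
    cap <- matrix(runif(n * n, 0, 19.6 * 0.0625), n, n)
    disp <- overwinter_disperse(QE, cap, p, 25)
    expect_true(all(disp$intensity <= cap + 1e-12))
    expect_true(all(disp$intensity <= 19.6 * 0.0625 + 1e-12))
    # no colonies where nesting quality is zero
    expect_true(all(disp$Q_next[cap == 0] == 0))
  }
})

test_that("dispersal conserves queens in expectation without truncation", {
  p <- bb_params()
  QE <- matrix(0, 11, 11); QE[6, 6] <- 50
  cap <- matrix(1e9, 11, 11)
  disp <- overwinter_disperse(QE, cap, p, 25)
  expect_equal(sum(disp$intensity), 50, tolerance = 1e-9)
  # single-cell landscape: everything stays put
  d1 <- overwinter_disperse(matrix(7, 1, 1), matrix(1e9, 1, 1), p, 25)
  expect_equal(sum(d1$intensity), 7, tolerance = 1e-12)
})

test_that("settlement intensity matches the brute-force kernel sum", {
  p <- bb_params(beta_nest = 150, rho_N = 0.999)
  set.seed(23)
  QE <- matrix(rpois(100, 3), 10, 10)
  cap <- matrix(runif(100, 0, 2), 10, 10)
  disp <- overwinter_disperse(QE, cap, p, 25)
  oracle <- bf_settlement_intensity(QE, cap, cap, 150, 25, rho = 0.999)
  expect_lt(max(abs(disp$intensity - oracle)), 1e-10)
})

test_that("dispersal with the literal queen-weighted destination works", {
  p <- bb_params(dispersal_weight = "queens")
  QE <- matrix(c(10, 0, 0, 5), 2, 2)
  Q <- matrix(c(1, 0, 0, 1), 2, 2)
  cap <- matrix(2, 2, 2)
  disp <- overwinter_disperse(QE, cap, p, 25, Q = Q)
  # only currently occupied cells receive queens
  expect_true(all(disp$intensity[Q == 0] == 0))
  expect_error(overwinter_disperse(QE, cap, p, 25), "needs the current Q")
})

test_that("queens with no reachable destination are lost, not an error", {
  p <- bb_params(beta_nest = 30)  # truncation ~138 m = 5 cells
  QE <- matrix(0, 20, 20); QE[1, 1] <- 12
  cap <- matrix(0, 20, 20); cap[20, 20] <- 5
  disp <- overwinter_disperse(QE, cap, p, 25)
  expect_equal(disp$lost, 12)
  expect_equal(sum(disp$intensity), 0)
})

test_that("seeded dispersal is bit-identical across runs", {
  p <- bb_params()
  QE <- matrix(rpois(64, 4), 8, 8)
  cap <- matrix(1, 8, 8)
  set.seed(99); a <- overwinter_disperse(QE, cap, p, 25)
  set.seed(99); b <- overwinter_disperse(QE, cap, p, 25)
  expect_identical(a$Q_next, b$Q_next)
})

test_that("larger nesting dispersal distance spreads settlement wider", {
  QE <- matrix(0, 1, 101); QE[1, 51] <- 1000
  cap <- matrix(1e9, 1, 101)
  spread <- sapply(c(100, 300, 900), function(bn) {
    p <- bb_params(beta_nest = bn)
    A <- overwinter_disperse(QE, cap, p, 25)$intensity
    d <- (abs(seq_len(101) - 51) * 25)
    sum(A * d^2) / sum(A)
  })
  expect_true(all(diff(spread) > 0))
})
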