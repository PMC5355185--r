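# Brute-force oracles: direct double loops over all (source, target)
# cell pairs, written independently of the package's FFT convolution
# path.

bf_kernel <- function(d, beta, q = 0.99, rho = 1) {
  w <- exp(-d / beta) * rho^d
  w[d > -beta * log(1 - q)] <- 0
  w
}

bf_visitation <- function(X, F, beta, cell_size, q = 0.99, rho = 1) {
  nr <- nrow(X); nc <- ncol(X)
  V <- matrix(0, nr, nc)
  for (rj in seq_len(nr)) for (cj in seq_len(nc)) {
    if (X[rj, cj] == 0) next
    d <- cell_size * sqrt(outer((seq_len(nr) - rj)^2,
                                (seq_len(nc) - cj)^2, "+"))
    K <- bf_kernel(d, beta, q)
    den <- sum(F * K)
    if (den <= 0) next
    V <- V + X[rj, cj] * F * K * rho^d / den
  }
  V
}

bf_resources_per_nest <- function(X, N, F, beta, cell_size, q = 0.99) {
  nr <- nrow(X); nc <- ncol(X)
  R <- matrix(0, nr, nc)
  for (ri in seq_len(nr)) for (ci in seq_len(nc)) {
    if (X[ri, ci] == 0) next
    d <- cell_size * sqrt(outer((seq_len(nr) - ri)^2,
                                (seq_len(nc) - ci)^2, "+"))
    K <- bf_kernel(d, beta, q)
    R[ri, ci] <- X[ri, ci] / N[ri, ci] * sum(F * K) / sum(K)
  }
  R
}

bf_settlement_intensity <- function(Q_E, w, capacity, beta, cell_size,
                                    q = 0.99, rho = 1) {
  nr <- nrow(Q_E); nc <- ncol(Q_E)
  A <- matrix(0, nr, nc)
  for (rj in seq_len(nr)) for (cj in seq_len(nc)) {
    if (Q_E[rj, cj] == 0) next
    d <- cell_size * sqrt(outer((seq_len(nr) - rj)^2,
                                (seq_len(nc) - cj)^2, "+"))
    K <- bf_kernel(d, beta, q)
    den <- sum(w * K)
    if (den <= 0) next
    A <- A + Q_E[rj, cj] * w * K * rho^d / den
  }
  pmin(A, capacity)
}

# lognormal CDF with median a and variance b, sigma^2 recovered by
# numeric root-finding (independent of the closed-form conversion)
bf_growth_cdf <- function(R, a, b) {
  s2 <- uniroot(function(v) (exp(v) - 1) * exp(2 * log(a) + v) - b,
                c(1e-12, 50), tol = 1e-14)$root
  plnorm(R, meanlog = log(a), sdlog = sqrt(s2))
}

# small fixed landscape used across tests: 16 x 16 cells, a central
# seminatural patch, one OSR field, cereal matrix, some edges
toy_landscape <- function(n = 16, cell_size = 25) {
  lu <- matrix(2L, n, n)
  lu[5:8, 5:8] <- 4L      # seminatural patch
  lu[1:4, 9:14] <- 1L     # OSR field
  lu[12:15, 2:6] <- 3L    # ley
  edge <- matrix(0, n, n)
  edge[c(4, 9), ] <- 25
  edge[, c(4, 9)] <- edge[, c(4, 9)] + 12.5
  landscape_year(lu, pmin(edge, 4 * cell_size), cell_size)
}

# independent scalar computation of a full 1 x 2 cell season
# (visitation, per-nest resources, worker growth, queen production,
# settlement intensity), written without any package spatial code
bf_two_cell_season <- function(F1, F2, Q, cap, p, cell_size = 25) {
  K <- exp(-cell_size / p$beta)
  D <- c(F1[1] + F1[2] * K, F1[2] + F1[1] * K)
  V1 <- c(Q[1] * F1[1] / D[1] + Q[2] * F1[1] * K / D[2],
          Q[1] * F1[2] * K / D[1] + Q[2] * F1[2] / D[2])
  R1 <- c(F1[1] + F1[2] * K, F1[2] + F1[1] * K) / (1 + K)
  W <- Q * p$w_max * bf_growth_cdf(R1, p$a_w, p$b_w)
  X2 <- p$p_w * W
  D2 <- c(F2[1] + F2[2] * K, F2[2] + F2[1] * K)
  V2 <- c(X2[1] * F2[1] / D2[1] + X2[2] * F2[1] * K / D2[2],
          X2[1] * F2[2] * K / D2[1] + X2[2] * F2[2] / D2[2])
  R2 <- (X2 / Q) * c(F2[1] + F2[2] * K, F2[2] + F2[1] * K) / (1 + K)
  QE <- Q * p$q_max * bf_growth_cdf(R2, p$a_q, p$b_q)
  Kn <- exp(-cell_size / p$beta_nest)
  Dw <- c(cap[1] + cap[2] * Kn, cap[2] + cap[1] * Kn)
  A <- c(cap[1] * (QE[1] / Dw[1] + QE[2] * Kn / Dw[2]),
         cap[2] * (QE[1] * Kn / Dw[1] + QE[2] / Dw[2]))
  list(V1 = V1, R1 = R1, W = W, V2 = V2, R2 = R2, Q_E = QE,
       intensity = pmin(A, cap))
}
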