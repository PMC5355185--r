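#' Truncated exponential dispersal kernels
#'
#' Distance weighting of foraging and dispersal follows an exponential
#' kernel `exp(-d / beta)` with mean distance `beta`, set to zero beyond
#' the truncation radius -- the `q`-th quantile of the exponential
#' distance distribution -- for computational reasons.
#'
#' @param d Distance(s) in meters, >= 0.
#' @param beta Mean dispersal distance in meters, > 0.
#' @param q Truncation quantile in (0, 1); default 0.99.
#' @return `kernel_weight()`: weights in \[0, 1\], zero where
#'   `d > truncation_radius(beta, q)`.
#' @examples
#' kernel_weight(530, 530)            # exp(-1)
#' truncation_radius(530, 0.99)       # ~2440.7 m
#' @export
kernel_weight <- function(d, beta, q = 0.99) {
  if (any(d < 0)) stop("distances must be >= 0")
  stopifnot(beta > 0)
  w <- exp(-d / beta)
  w[d > truncation_radius(beta, q)] <- 0
  w
}

#' @rdname kernel_weight
#' @return `truncation_radius()`: the distance below which the kernel is
#'   retained, `-beta * log(1 - q)`.
#' @export
truncation_radius <- function(beta, q = 0.99) {
  stopifnot(beta > 0)
  if (any(q <= 0) || any(q >= 1)) stop("q must lie in (0, 1)")
  -beta * log1p(-q)
}

## ---- internal FFT convolution machinery -------------------------------
##
## Every spatial sum in the model has the form
##   out_i = sum_j m_j * K(d_ij),  K(d) = exp(-d/beta) * rho^d, d <= r
## i.e. a linear convolution of a grid with a radially symmetric
## truncated kernel.  We evaluate it by zero-padded FFT; kernel FFTs are
## cached per (padded size, beta, rho, q, cell size).

.bb_kernel_cache <- new.env(parent = emptyenv())

## smallest 5-smooth integer >= n (keeps mixed-radix FFTs fast)
good_fft_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

## kernel stencil values on integer offsets -rc..rc (matrix), plus rc
kernel_stencil <- function(beta, cell_size, q = 0.99, rho = 1) {
  r <- truncation_radius(beta, q)
  rc <- floor(r / cell_size)
  off2 <- (-rc:rc)^2
  d <- cell_size * sqrt(outer(off2, off2, "+"))
  w <- exp(-d / beta) * rho^d
  w[d > r] <- 0
  list(w = w, rc = rc)
}

kernel_fft <- function(pr, pc, beta, cell_size, q, rho) {
  key <- paste(pr, pc, beta, cell_size, q, rho, sep = "|")
  got <- .bb_kernel_cache[[key]]
  if (!is.null(got)) return(got)
  st <- kernel_stencil(beta, cell_size, q, rho)
  rc <- st$rc
  kpad <- matrix(0, pr, pc)
  idx_r <- ((-rc:rc) %% pr) + 1L
  idx_c <- ((-rc:rc) %% pc) + 1L
  kpad[idx_r, idx_c] <- st$w
  kf <- stats::fft(kpad)
  .bb_kernel_cache[[key]] <- kf
  kf
}

## convolve a grid with the truncated kernel; cells outside the raster
## contribute nothing (zero padding)
disc_convolve <- function(mat, beta, cell_size, q = 0.99, rho = 1) {
  nr <- nrow(mat); nc <- ncol(mat)
  rc <- floor(truncation_radius(beta, q) / cell_size)
  pr <- good_fft_size(nr + rc)
  pc <- good_fft_size(nc + rc)
  kf <- kernel_fft(pr, pc, beta, cell_size, q, rho)
  mpad <- matrix(0, pr, pc)
  mpad[seq_len(nr), seq_len(nc)] <- mat
  out <- Re(stats::fft(stats::fft(mpad) * kf, inverse = TRUE)) / (pr * pc)
  out <- out[seq_len(nr), seq_len(nc), drop = FALSE]
  ## FFT round-off can leave tiny negatives on an all-nonnegative input
  if (all(mat >= 0)) out[out < 0] <- 0
  out
}
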