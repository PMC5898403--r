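# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers never observe a side effect.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  code
}

# DFT sample frequencies (cycles per length unit), numpy-fftfreq layout.
fft_freq <- function(n, d = 1) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * d)
}

# Min-max normalization to [0,1]; constant input maps to all zeros.
norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[2] <= r[1]) return(array(0, dim = dim(x) %||% length(x)))
  (x - r[1]) / (r[2] - r[1])
}

rmse <- function(x, y = 0) sqrt(mean((x - y)^2))

#' Bilinear interpolation at fractional (row, col) positions
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of 1-based fractional coordinates.
#' @param fill value for samples outside the image (default NA).
#' @return numeric vector with attribute `valid` (logical, inside image).
#' @keywords internal
bilinear_sample <- function(img, r, c, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  valid <- r >= 1 & r <= nr & c >= 1 & c <= nc
  r0 <- pmin(pmax(floor(r), 1), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1), nc - 1L)
  fr <- pmin(pmax(r - r0, 0), 1)
  fc <- pmin(pmax(c - c0, 0), 1)
  i00 <- (c0 - 1) * nr + r0
  v <- img[i00]       * (1 - fr) * (1 - fc) +
       img[i00 + 1]   * fr       * (1 - fc) +
       img[i00 + nr]  * (1 - fr) * fc +
       img[i00 + nr + 1] * fr    * fc
  v[!valid] <- fill
  attr(v, "valid") <- valid
  v
}

# Keys bicubic kernel (a = -0.5), edge-replicated; used by warp().
cubic_weight <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * (at[i2]^3 - 5 * at[i2]^2 + 8 * at[i2] - 4)
  w
}

bicubic_sample <- function(img, r, c, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  valid <- r >= 1 & r <= nr & c >= 1 & c <= nc
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  v <- numeric(length(r))
  wr <- list(); wc <- list()
  for (k in -1:2) {
    wr[[k + 2]] <- cubic_weight(fr - k)
    wc[[k + 2]] <- cubic_weight(fc - k)
  }
  for (i in -1:2) {
    ri <- pmin(pmax(r0 + i, 1), nr)
    for (j in -1:2) {
      cj <- pmin(pmax(c0 + j, 1), nc)
      v <- v + img[(cj - 1) * nr + ri] * wr[[i + 2]] * wc[[j + 2]]
    }
  }
  v[!valid] <- fill
  attr(v, "valid") <- valid
  v
}

# 2-D "same" convolution with zero padding; kernel dims must be odd.
conv2_same <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  nr <- nrow(img); nc <- ncol(img)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  pad <- matrix(0, nr + 2 * pr, nc + 2 * pc)
  pad[(pr + 1):(pr + nr), (pc + 1):(pc + nc)] <- img
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kern[i, j]
      if (w == 0) next
      # convolution: kernel index (i,j) pairs with image offset (-(i-kr/2),...)
      out <- out + w * pad[(kr - i + 1):(kr - i + nr), (kc - j + 1):(kc - j + nc)]
    }
  }
  out
}

pad_replicate <- function(img, p) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, p), seq_len(nr), rep(nr, p))
  ci <- c(rep(1L, p), seq_len(nc), rep(nc, p))
  img[ri, ci, drop = FALSE]
}

#' Gaussian smoothing of an image
#'
#' FFT-based isotropic Gaussian blur with replicate edge padding.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns `img`.
#' @return smoothed matrix of the same dimensions.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  p <- ceiling(3 * sigma) + 1L
  x <- pad_replicate(img, p)
  nr <- nrow(x); nc <- ncol(x)
  gr <- exp(-pmin(0:(nr - 1), nr - 0:(nr - 1))^2 / (2 * sigma^2))
  gc <- exp(-pmin(0:(nc - 1), nc - 0:(nc - 1))^2 / (2 * sigma^2))
  K <- outer(gr / sum(gr), gc / sum(gc))
  y <- Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  y[(p + 1):(p + nrow(img)), (p + 1):(p + ncol(img))]
}

# Fill cells where `known` is FALSE by iterated 3x3 means of known neighbours.
fill_holes <- function(x, known) {
  if (all(known)) return(x)
  ones <- matrix(1, 3, 3)
  x[!known] <- 0
  for (it in 1:512) {
    cnt <- conv2_same(known * 1, ones)
    sums <- conv2_same(x * known, ones)
    new <- !known & cnt > 0
    if (any(new)) {
      x[new] <- sums[new] / cnt[new]
      known <- known | new
    }
    if (all(known)) break
  }
  if (!all(known)) x[!known] <- mean(x[known])
  x
}

# Box filter by integer factor: block means (dims must be divisible).
box_downsample <- function(img, factor) {
  if (factor == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  stopifnot(nr %% factor == 0, nc %% factor == 0)
  m <- matrix(colMeans(matrix(img, nrow = factor)), nrow = nr %/% factor)
  t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = nc %/% factor))
}
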