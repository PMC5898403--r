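# Diagnostic measures: sum-modified-Laplacian focus measure, Prewitt compass
# gradient, line-profile sampling, fringe-cycle counting, two-point
# resolution test.

#' Sum-modified-Laplacian focus measure
#'
#' Sums, over all interior pixels, the absolute second differences in both
#' axes at unit step:
#' `|2 I(x,y) - I(x-1,y) - I(x+1,y)| + |2 I(x,y) - I(x,y-1) - I(x,y+1)|`.
#' Larger values indicate a sharper (better focused / better propagated)
#' image; the measure is invariant to constant intensity offsets and
#' vanishes on constant images.
#'
#' @param image numeric matrix, at least 3x3.
#' @return non-negative scalar.
#' @examples
#' lapm(matrix(5, 10, 10))  # 0
#' @export
lapm <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3)
    stop("`image` must be a matrix of at least 3x3")
  nr <- nrow(image); nc <- ncol(image)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  core <- image[ri, ci]
  mlap <- abs(2 * core - image[ri - 1, ci] - image[ri + 1, ci]) +
          abs(2 * core - image[ri, ci - 1] - image[ri, ci + 1])
  sum(mlap)
}

# The eight 3x3 Prewitt compass kernels: the east kernel's border ring is
# rotated one position per orientation.
prewitt_kernels <- function() {
  ring_idx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3), c(3, 3),
                    c(3, 2), c(3, 1), c(2, 1))
  ring0 <- c(-1, 0, 1, 1, 1, 0, -1, -1)  # east-gradient kernel
  lapply(0:7, function(s) {
    k <- matrix(0, 3, 3)
    k[ring_idx] <- ring0[((seq_len(8) - 1 + s) %% 8) + 1]
    k
  })
}

#' Prewitt compass edge response
#'
#' Convolves the image with the eight 3x3 Prewitt compass kernels (the east
#' kernel rotated in 45-degree steps) and returns, per pixel, the maximum
#' absolute response over all orientations — an orientation-independent
#' approximation of the intensity gradient magnitude, used to make hologram
#' fringes visible.
#'
#' @param image numeric matrix, at least 3x3.
#' @return numeric matrix of the same dimension (edge-replicated borders).
#' @export
prewitt_compass <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3)
    stop("`image` must be a matrix of at least 3x3")
  nr <- nrow(image); nc <- ncol(image)
  padded <- pad_replicate(image, 1L)
  resp <- NULL
  for (k in prewitt_kernels()) {
    r <- abs(conv2_same(padded, k))[2:(nr + 1), 2:(nc + 1)]
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  resp
}

#' Sample an intensity profile along a line segment
#'
#' Bilinearly samples the image at `n_samples` equally spaced points from
#' `p0` to `p1` (inclusive), where points are `c(row, col)` coordinates
#' (1-based, fractional allowed).
#'
#' @param image numeric matrix.
#' @param p0,p1 numeric length-2 endpoints `c(row, col)`, inside the image.
#' @param n_samples number of samples, at least 2.
#' @return An object of class `profile_measurement`: list with `positions`
#'   (distance along the line, pixels), `intensities`, `endpoints`, `step`.
#' @export
line_profile <- function(image, p0, p1, n_samples = 100) {
  if (n_samples < 2) stop("`n_samples` must be at least 2")
  inb <- function(p) length(p) == 2 && p[1] >= 1 && p[1] <= nrow(image) &&
    p[2] >= 1 && p[2] <= ncol(image)
  if (!inb(p0) || !inb(p1)) stop("profile endpoints must lie inside the image")
  t <- seq(0, 1, length.out = n_samples)
  r <- p0[1] + t * (p1[1] - p0[1])
  c <- p0[2] + t * (p1[2] - p0[2])
  len <- sqrt(sum((p1 - p0)^2))
  v <- bilinear_sample(image, r, c)
  structure(list(positions = t * len, intensities = as.numeric(v),
                 endpoints = rbind(p0, p1), step = len / (n_samples - 1)),
            class = "profile_measurement")
}

# Local maxima of a 1-D sequence with topographic prominence.
# Plateau peaks are reported once, at their left edge. Returns a data.frame
# with columns `index`, `value`, `prominence`.
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(), value = numeric(),
                               prominence = numeric()))
  # collapse plateaus: runs of equal values
  r <- rle(x)
  k <- length(r$values)
  starts <- cumsum(c(1, r$lengths[-k]))
  peaks <- integer()
  for (i in seq_len(k)) {
    lo <- if (i > 1) r$values[i - 1] < r$values[i] else FALSE
    hi <- if (i < k) r$values[i + 1] < r$values[i] else FALSE
    if (lo && hi) peaks <- c(peaks, starts[i])
  }
  if (!length(peaks)) return(data.frame(index = integer(), value = numeric(),
                                        prominence = numeric()))
  prom <- vapply(peaks, function(p) {
    v <- x[p]
    lmin <- v; i <- p
    while (i > 1) { i <- i - 1; if (x[i] > v) break; lmin <- min(lmin, x[i]) }
    lbase <- if (i >= 1 && x[i] > v) lmin else min(x[1:p])
    rmin <- v; i <- p
    while (i < n) { i <- i + 1; if (x[i] > v) break; rmin <- min(rmin, x[i]) }
    rbase <- if (i <= n && x[i] > v) rmin else min(x[p:n])
    v - max(lbase, rbase)
  }, numeric(1))
  data.frame(index = peaks, value = x[peaks], prominence = prom)
}

#' Count fringe cycles along an intensity profile
#'
#' Counts local maxima of the profile whose topographic prominence is at
#' least `prominence_fraction` times the profile's full dynamic range.
#' Plateau maxima are counted once, at their left edge. The count is
#' invariant to affine rescaling of the intensities and quantifies how many
#' holographic fringe cycles the profile resolves.
#'
#' @param profile a [line_profile()] result, or a numeric vector.
#' @param prominence_fraction required prominence as a fraction of
#'   `max - min`, in (0, 1). Default 0.2.
#' @return integer cycle count (0 for a constant profile).
#' @examples
#' count_cycles(sin(seq(0, 16 * pi, length.out = 400)))  # 8
#' @export
count_cycles <- function(profile, prominence_fraction = 0.2) {
  if (prominence_fraction <= 0 || prominence_fraction >= 1)
    stop("`prominence_fraction` must lie in (0, 1)")
  x <- if (inherits(profile, "profile_measurement")) profile$intensities
       else as.numeric(profile)
  rng <- diff(range(x))
  if (rng == 0) return(0L)
  pk <- find_peaks(x)
  sum(pk$prominence >= prominence_fraction * rng)
}

#' Measured dip between two intensity peaks
#'
#' Samples the profile between two nominal peak locations, finds the local
#' maxima nearest each endpoint, and returns the fractional dip
#' `1 - min_between / lesser_peak`. `NA` when two distinct peaks cannot be
#' located (with a warning).
#'
#' @param image numeric matrix (peaks must be bright; invert dark features
#'   before calling).
#' @param p_a,p_b `c(row, col)` positions of the two features, inside the
#'   image, distinct.
#' @param n_samples profile sampling density (default: 8 samples per pixel
#'   of separation, minimum 32).
#' @return scalar fractional dip in [0, 1], or NA.
#' @export
two_point_dip <- function(image, p_a, p_b, n_samples = NULL) {
  if (isTRUE(all(p_a == p_b))) stop("`p_a` and `p_b` must be distinct")
  sep <- sqrt(sum((p_b - p_a)^2))
  if (is.null(n_samples)) n_samples <- max(32L, ceiling(8 * sep))
  # extend the segment slightly so maxima just outside [p_a, p_b] are seen
  ext <- 0.25
  q0 <- p_a - ext * (p_b - p_a); q1 <- p_b + ext * (p_b - p_a)
  clamp <- function(p) c(min(max(p[1], 1), nrow(image)),
                         min(max(p[2], 1), ncol(image)))
  pr <- line_profile(image, clamp(q0), clamp(q1), n_samples)
  x <- pr$intensities
  pk <- find_peaks(x)
  if (nrow(pk) < 2) {
    warning("could not locate two distinct intensity maxima")
    return(NA_real_)
  }
  # positions of the nominal points along the sampled (extended) segment
  tt <- seq(0, 1, length.out = n_samples)
  ta <- ext / (1 + 2 * ext); tb <- (ext + 1) / (1 + 2 * ext)
  ia <- pk$index[which.min(abs(tt[pk$index] - ta))]
  ib <- pk$index[which.min(abs(tt[pk$index] - tb))]
  if (ia == ib) {
    warning("both nominal points map to the same intensity maximum")
    return(NA_real_)
  }
  lo <- min(ia, ib); hi <- max(ia, ib)
  valley <- min(x[lo:hi])
  lesser <- min(x[ia], x[ib])
  if (lesser <= 0) return(NA_real_)
  1 - valley / lesser
}

#' Two-point resolution test
#'
#' Declares two point-like features resolved when the intensity between
#' their peaks dips by at least `dip_fraction` relative to the lesser peak
#' (a Rayleigh-style saddle criterion). Returns FALSE (with a warning) when
#' two distinct peaks cannot be found near the nominal positions.
#'
#' @inheritParams two_point_dip
#' @param dip_fraction required relative dip, default 0.2.
#' @return logical.
#' @export
two_point_resolved <- function(image, p_a, p_b, dip_fraction = 0.2,
                               n_samples = NULL) {
  dip <- two_point_dip(image, p_a, p_b, n_samples)
  !is.na(dip) && dip >= dip_fraction
}
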