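# Scalar-diffraction engine: angular-spectrum propagation between detector
# and object planes, and assembly of the reconstruction planes.

#' Angular-spectrum transfer function
#'
#' Builds the frequency-domain transfer function of free-space scalar
#' diffraction over a signed distance `z`:
#' \deqn{H(f_x,f_y) = \exp\!\big(i\,\tfrac{2\pi}{\lambda} z
#'   \sqrt{1-(\lambda f_x)^2-(\lambda f_y)^2}\big)}
#' on the propagating band \eqn{(\lambda f_x)^2+(\lambda f_y)^2 \le 1}, and
#' zero on the evanescent band (hard cutoff). Frequencies follow the DFT
#' layout of the grid, in cycles per micrometre.
#'
#' @param shape integer vector `c(nrow, ncol)` of the field grid.
#' @param params a [propagation_params()] object (wavelength, pitch, z).
#' @return complex matrix of dimension `shape`; unit modulus on the
#'   propagating band, zero beyond it.
#' @examples
#' H <- angular_spectrum_transfer(c(32, 32), propagation_params(z = 100))
#' all(abs(Mod(H)[Mod(H) > 0] - 1) < 1e-12)
#' @export
angular_spectrum_transfer <- function(shape, params) {
  stopifnot(inherits(params, "propagation_params"))
  if (length(shape) != 2 || any(shape < 2)) stop("`shape` must be two dims >= 2")
  lam <- params$wavelength
  fr <- fft_freq(shape[1], params$pitch)
  fc <- fft_freq(shape[2], params$pitch)
  arg <- 1 - outer((lam * fr)^2, (lam * fc)^2, `+`)
  prop <- arg >= 0
  H <- matrix(0 + 0i, shape[1], shape[2])
  H[prop] <- exp(2i * pi / lam * params$z * sqrt(arg[prop]))
  H
}

#' Propagate a complex field by the angular-spectrum method
#'
#' Transforms the field to the spatial-frequency domain, applies the
#' band-limited angular-spectrum transfer function for distance `z`, and
#' transforms back. With `pad = TRUE` (default) the field is zero-padded to
#' twice each dimension before propagation and cropped after, which
#' suppresses wrap-around interference from the periodic DFT; the mean field
#' (a plane wave, eigenfunction of free-space propagation) is carried
#' analytically so a constant background does not diffract at the pad edge.
#' With `pad = FALSE` propagation is strictly unitary on the grid:
#' `propagate(propagate(U, z), -z)` is the identity to machine precision and
#' total energy `sum(|U|^2)` is conserved.
#'
#' A warning is emitted when |z| exceeds the aliasing-free limit
#' `N * pitch^2 / wavelength` of the (padded) grid; the computation proceeds.
#'
#' @param field a [complex_field()].
#' @param z signed propagation distance (micrometres); positive z moves away
#'   from the source, negative z back-propagates.
#' @param pad logical; zero-pad 2x before propagation (default TRUE).
#' @return a [complex_field()] of the same shape, pitch and wavelength.
#' @examples
#' u <- complex_field(matrix(complex(real = rnorm(256), imaginary = rnorm(256)),
#'                           16, 16), pitch = 1.67, wavelength = 0.385)
#' v <- propagate(propagate(u, 50, pad = FALSE), -50, pad = FALSE)
#' max(Mod(v$values - u$values))
#' @export
propagate <- function(field, z, pad = TRUE) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.finite(z)) stop("`z` must be finite")
  U <- field$values
  nr <- nrow(U); nc <- ncol(U)
  n_eff <- if (pad) 2L * min(nr, nc) else min(nr, nc)
  zmax <- n_eff * field$pitch^2 / field$wavelength
  if (abs(z) > zmax)
    warning(sprintf(
      "|z| = %.4g um exceeds the aliasing-free angular-spectrum limit %.4g um for this grid",
      abs(z), zmax))
  params <- propagation_params(field$wavelength, field$pitch, z)
  if (pad) {
    mu <- mean(U)
    P <- matrix(0 + 0i, 2L * nr, 2L * nc)
    r0 <- nr %/% 2; c0 <- nc %/% 2
    P[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)] <- U - mu
    H <- angular_spectrum_transfer(dim(P), params)
    V <- stats::fft(stats::fft(P) * H, inverse = TRUE) / length(P)
    out <- V[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)] +
      mu * exp(2i * pi * z / field$wavelength)
  } else {
    H <- angular_spectrum_transfer(dim(U), params)
    out <- stats::fft(stats::fft(U) * H, inverse = TRUE) / length(U)
  }
  complex_field(out, field$pitch, field$wavelength)
}

#' Assemble the reconstruction planes of a propagated field
#'
#' Splits a complex object-plane field into the five rasters used for
#' inspection and visualization: real part, imaginary part, amplitude
#' (modulus), phase (argument, in (-pi, pi]) and the composition signal
#' (real + imaginary).
#'
#' @param field a [complex_field()].
#' @return An object of class `reconstructed_planes`: a list with elements
#'   `real_part`, `imag_part`, `amplitude`, `phase`, `composition`.
#' @export
reconstructed_planes <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  U <- field$values
  structure(list(real_part = Re(U), imag_part = Im(U),
                 amplitude = Mod(U), phase = Arg(U),
                 composition = Re(U) + Im(U)),
            class = "reconstructed_planes")
}

#' @export
print.reconstructed_planes <- function(x, ...) {
  cat(sprintf("<reconstructed_planes %d x %d>\n",
              nrow(x$amplitude), ncol(x$amplitude)))
  invisible(x)
}

#' Reconstruct object planes from an in-line hologram
#'
#' Embeds a recorded intensity hologram as a detector-plane field (by default
#' its square root, the amplitude-hologram assumption) and back-propagates it
#' by the angular-spectrum method to each distance in `z_list`, returning one
#' set of reconstruction planes per distance. Scanning `z` walks through the
#' object planes of the sample.
#'
#' @param hologram non-negative numeric matrix of recorded intensities.
#' @param params a [propagation_params()]; its `z` slot is ignored in favour
#'   of `z_list`.
#' @param z_list numeric vector of positive object-to-detector distances
#'   (micrometres); each is back-propagated as `-z`.
#' @param from_sqrt embed `sqrt(hologram)` (default) or the raw intensity.
#' @param pad passed to [propagate()].
#' @return list of [reconstructed_planes()] objects, one per `z`.
#' @examples
#' h <- matrix(1, 32, 32); h[16, 16] <- 0.2
#' planes <- reconstruct_hologram(h, propagation_params(), z_list = c(200, 400))
#' length(planes)
#' @export
reconstruct_hologram <- function(hologram, params, z_list,
                                 from_sqrt = TRUE, pad = TRUE) {
  stopifnot(inherits(params, "propagation_params"))
  if (length(z_list) < 1) stop("`z_list` must be non-empty")
  if (any(hologram < 0)) stop("`hologram` must be non-negative")
  base <- if (from_sqrt) sqrt(hologram) else hologram
  field <- complex_field(base + 0i, params$pitch, params$wavelength)
  lapply(z_list, function(z) reconstructed_planes(propagate(field, -z, pad = pad)))
}

#' Compose an RGB visualization from reconstruction planes
#'
#' Maps the real part, the imaginary part and the composition signal
#' (real + imaginary) onto the R, G and B channels respectively, each
#' min-max normalized over the frame. Morphologically distinct structures
#' (e.g. sperm heads versus tails) diffract differently into the real and
#' imaginary parts and therefore attain distinct channel dominance.
#'
#' @param planes a [reconstructed_planes()] object.
#' @return numeric array `nrow x ncol x 3` with values in [0, 1]; a
#'   degenerate (constant) plane yields an all-zero channel.
#' @export
compose_rgb <- function(planes) {
  stopifnot(inherits(planes, "reconstructed_planes"))
  d <- dim(planes$real_part)
  out <- array(0, c(d, 3L))
  out[, , 1] <- norm01(planes$real_part)
  out[, , 2] <- norm01(planes$imag_part)
  out[, , 3] <- norm01(planes$composition)
  out
}

#' Sharpness scan over reconstruction distances (autofocus)
#'
#' Back-propagates a hologram over a list of candidate distances and scores
#' the amplitude plane of each; the distance maximizing the score estimates
#' the true object-to-detector distance.
#'
#' The default score is the Tamura coefficient (standard deviation over
#' mean) of the amplitude, which peaks at focus for absorbing objects in
#' coherent reconstructions. The sum-modified Laplacian ([lapm()]) is also
#' available; note that on coherent amplitude reconstructions LAPM keeps
#' rising with defocus (out-of-focus fringes add second-difference
#' content), so it suits hologram-domain sharpness rather than
#' object-plane autofocus.
#'
#' @inheritParams reconstruct_hologram
#' @param metric "tamura" (default), "variance" or "lapm".
#' @param window optional `c(r0, r1, c0, c1)` sub-window (pixel bounds) to
#'   score, e.g. around the object of interest; default: whole frame.
#' @return data.frame with columns `z` and `score`.
#' @export
focus_scan <- function(hologram, params, z_list, from_sqrt = TRUE, pad = TRUE,
                       metric = c("tamura", "variance", "lapm"),
                       window = NULL) {
  metric <- match.arg(metric)
  planes <- reconstruct_hologram(hologram, params, z_list,
                                 from_sqrt = from_sqrt, pad = pad)
  score <- vapply(planes, function(p) {
    a <- p$amplitude
    if (!is.null(window)) a <- a[window[1]:window[2], window[3]:window[4]]
    switch(metric,
           tamura = stats::sd(a) / mean(a),
           variance = stats::var(as.vector(a)),
           lapm = lapm(a))
  }, numeric(1))
  data.frame(z = z_list, score = score)
}
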