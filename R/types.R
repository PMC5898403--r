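# Core value types: complex optical fields, propagation parameters,
# reconstructed plane sets, low-resolution frame stacks.

#' Complex optical field
#'
#' A complex-valued 2-D field sampled on a regular grid, together with the
#' physical pixel pitch and the illumination wavelength. This is the unit the
#' angular-spectrum engine propagates: holograms are embedded into a
#' `complex_field` before numerical diffraction.
#'
#' @param values complex (or numeric) matrix, at least 2x2, all finite.
#' @param pitch physical sampling pitch, in the same length unit as
#'   `wavelength` (micrometres throughout the package). Must be positive.
#' @param wavelength illumination wavelength (micrometres). Must be positive.
#' @return An object of class `complex_field` with elements `values`,
#'   `pitch`, `wavelength`.
#' @examples
#' f <- complex_field(matrix(1 + 0i, 8, 8), pitch = 1.67, wavelength = 0.385)
#' dim(f$values)
#' @export
complex_field <- function(values, pitch, wavelength) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 2 || ncol(values) < 2) stop("field grid must be at least 2x2")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite")
  if (!is.numeric(pitch) || length(pitch) != 1 || pitch <= 0)
    stop("`pitch` must be a positive scalar")
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0)
    stop("`wavelength` must be a positive scalar")
  structure(list(values = as.matrix(values) + 0i, pitch = pitch,
                 wavelength = wavelength),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field %d x %d, pitch %.4g um, wavelength %.4g um>\n",
              nrow(x$values), ncol(x$values), x$pitch, x$wavelength))
  invisible(x)
}

#' Propagation parameters for the angular-spectrum method
#'
#' Bundles the optical constants of the acquisition: wavelength, detector
#' pixel pitch and a (signed) propagation distance. Defaults follow the
#' platform this package models: a 385 nm ultraviolet LED and a monochrome
#' CMOS sensor with 1.67 um pixels.
#'
#' @param wavelength wavelength in micrometres (default 0.385).
#' @param pitch pixel pitch in micrometres (default 1.67).
#' @param z signed propagation distance in micrometres; positive z propagates
#'   away from the source (object to detector), negative z back-propagates.
#'   `z = 0` is the identity.
#' @return An object of class `propagation_params`.
#' @export
propagation_params <- function(wavelength = 0.385, pitch = 1.67, z = 0) {
  if (wavelength <= 0) stop("`wavelength` must be positive")
  if (pitch <= 0) stop("`pitch` must be positive")
  if (!is.finite(z)) stop("`z` must be finite")
  structure(list(wavelength = wavelength, pitch = pitch, z = z),
            class = "propagation_params")
}

#' Stack of low-resolution hologram frames
#'
#' An ordered set of m single-channel frames sharing one detector geometry,
#' optionally carrying the ground-truth per-frame alignment shifts when the
#' stack came from the synthetic acquisition simulator. Frames are stored as
#' numeric matrices in linear intensity units (background approximately 1).
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param pitch detector pixel pitch of the frames (micrometres).
#' @param shifts optional m x 2 matrix of ground-truth alignment translations
#'   (rows: frames; columns: row/col shift in LR pixels mapping frame
#'   coordinates onto reference-scene coordinates).
#' @return An object of class `lr_stack`.
#' @export
lr_stack <- function(frames, pitch = 1.67, shifts = NULL) {
  if (!is.list(frames) || length(frames) < 1) stop("`frames` must be a non-empty list")
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !is.numeric(f)) stop("each frame must be a numeric matrix")
    if (!identical(dim(f), d)) stop("all frames must share the same dimensions")
  }
  if (!is.null(shifts)) {
    shifts <- as.matrix(shifts)
    if (nrow(shifts) != length(frames) || ncol(shifts) != 2)
      stop("`shifts` must be an m x 2 matrix")
  }
  structure(list(frames = frames, pitch = pitch, shifts = shifts),
            class = "lr_stack")
}

#' @export
print.lr_stack <- function(x, ...) {
  cat(sprintf("<lr_stack of %d frames, %d x %d, pitch %.4g um%s>\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pitch, if (is.null(x$shifts)) "" else ", with ground truth"))
  invisible(x)
}

#' @export
length.lr_stack <- function(x) length(x$frames)
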