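# Ready-made validation scenes: reproducible study conditions used by the
# package's tests, the acceptance script and the worked examples.

#' Multi-cell validation scene
#'
#' A field of view containing a handful of micron-scale absorbing cells
#' (disks of 1.5-2.5 um radius, transmittance 0-0.3) at reproducible random
#' positions — the workhorse scene for registration and offset-recovery
#' studies. The HR canvas matches `lr_dim * factor` detector-grid pixels.
#'
#' @param lr_dim LR frame side in pixels (default 64).
#' @param factor upsampling factor (default 4).
#' @param z scene-to-detector distance, micrometres (default 200; within
#'   the band-limited propagation validity of the default canvas).
#' @param n_objects number of cells (default 6).
#' @param pitch detector pixel pitch, micrometres (default 1.67).
#' @param wavelength illumination wavelength, micrometres (default 0.385).
#' @param seed placement seed.
#' @return a [scene_spec()].
#' @export
fixture_cell_scene <- function(lr_dim = 64, factor = 4, z = 200,
                               n_objects = 6, pitch = 1.67,
                               wavelength = 0.385, seed = 3L) {
  hr_dim <- lr_dim * factor
  pitch_hr <- pitch / factor
  fov <- hr_dim * pitch_hr
  objs <- with_seed(seed, lapply(seq_len(n_objects), function(i) {
    list(shape = "disk",
         centre = stats::runif(2, 0.25 * fov, 0.75 * fov),
         size = stats::runif(1, 1.5, 2.5),
         transmittance = stats::runif(1, 0, 0.3))
  }))
  scene_spec(dim = c(hr_dim, hr_dim), pitch = pitch_hr, objects = objs,
             z = z, wavelength = wavelength)
}

#' Two-point resolution scene
#'
#' Two small opaque points separated by `separation` LR pixels at the
#' centre of the field, surrounded by a few context cells away from the
#' measurement region (a featureless frame would defeat any feature-based
#' pre-alignment). Used by the two-point resolvability study: the pair is
#' below the single-frame sampling limit but above the fused-HR limit.
#'
#' @inheritParams fixture_cell_scene
#' @param separation point separation in LR pixels (default 1.2).
#' @param point_radius point radius in micrometres (default 0.5).
#' @param z scene-to-detector distance (default 120).
#' @return list with `spec` (a [scene_spec()]), `p_a`, `p_b` (point
#'   positions in scene micrometres).
#' @export
fixture_two_point_scene <- function(lr_dim = 64, factor = 4, z = 120,
                                    separation = 1.2, point_radius = 0.5,
                                    pitch = 1.67, wavelength = 0.385) {
  hr_dim <- lr_dim * factor
  pitch_hr <- pitch / factor
  fov <- hr_dim * pitch_hr
  sep_um <- separation * pitch
  ctr <- fov / 2
  p_a <- c(ctr, ctr - sep_um / 2)
  p_b <- c(ctr, ctr + sep_um / 2)
  objs <- list(
    list(shape = "disk", centre = p_a, size = point_radius, transmittance = 0),
    list(shape = "disk", centre = p_b, size = point_radius, transmittance = 0),
    list(shape = "disk", centre = c(0.30, 0.30) * fov, size = 2.0, transmittance = 0.1),
    list(shape = "disk", centre = c(0.32, 0.70) * fov, size = 1.6, transmittance = 0.15),
    list(shape = "disk", centre = c(0.70, 0.32) * fov, size = 2.2, transmittance = 0.1),
    list(shape = "disk", centre = c(0.72, 0.68) * fov, size = 1.8, transmittance = 0.2))
  list(spec = scene_spec(dim = c(hr_dim, hr_dim), pitch = pitch_hr,
                         objects = objs, z = z, wavelength = wavelength),
       p_a = p_a, p_b = p_b)
}

#' Map scene coordinates to frame / fused-image pixel coordinates
#'
#' `scene_to_lr()` gives the position of a scene point (micrometres) in an
#' LR frame acquired at alignment shift `shift` (LR pixels; frame pixel
#' centres sit at the box-average of `factor` HR pixels).
#' `scene_to_hr()` gives its position in the fused HR image, whose geometry
#' is that of the reference frame.
#'
#' @param p scene position `c(row_um, col_um)`.
#' @param pitch_hr HR (scene) pixel pitch in micrometres.
#' @param factor upsampling factor.
#' @param shift the frame's alignment shift (LR px; for the fused image,
#'   the reference frame's shift).
#' @return `c(row, col)` pixel coordinates.
#' @export
scene_to_lr <- function(p, pitch_hr, factor, shift = c(0, 0)) {
  (p / pitch_hr - (factor + 1) / 2) / factor + 1 - shift
}

#' @rdname scene_to_lr
#' @export
scene_to_hr <- function(p, pitch_hr, factor, shift = c(0, 0)) {
  p / pitch_hr - factor * shift
}
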