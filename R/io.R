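# Image input/output: 8/16-bit TIFF/PNG holograms in, 32-bit float TIFF
# planes and 8-bit PNG previews out.

#' Read a single-channel hologram image
#'
#' Reads an 8- or 16-bit single-channel TIFF or PNG (multi-channel images
#' are reduced to their first channel) and returns intensities on [0, 1].
#'
#' @param path image file, extension `.tif`, `.tiff` or `.png`.
#' @return numeric matrix in [0, 1].
#' @export
read_hologram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop(sprintf("unsupported image extension '%s'", ext)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a raster as 32-bit float TIFF
#'
#' Values must lie in [0, 1] (the TIFF writer's payload range); anything
#' outside is clipped with a warning. Callers with wider dynamic range
#' should divide by a recorded scale first (see [cmd_superresolve()]).
#'
#' @param image numeric matrix with values in [0, 1].
#' @param path output `.tif` path.
#' @return invisibly, `path`.
#' @export
write_float_tiff <- function(image, path) {
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    warning("values outside [0, 1] clipped when writing float TIFF")
    image <- pmin(pmax(image, 0), 1)
  }
  tiff::writeTIFF(image, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a raster (or RGB array) as an 8-bit PNG preview
#'
#' Single-channel inputs are min-max normalized; 3-channel arrays are
#' clipped to [0, 1].
#'
#' @param image numeric matrix or nrow x ncol x 3 array.
#' @param path output `.png` path.
#' @return invisibly, `path`.
#' @export
write_png8 <- function(image, path) {
  if (length(dim(image)) == 2) image <- norm01(image)
  else image <- pmin(pmax(image, 0), 1)
  png::writePNG(image, path)
  invisible(path)
}

#' Write all planes of a reconstruction to disk
#'
#' Real, imaginary, amplitude and phase planes go out as 32-bit float TIFFs
#' (one file per plane), each min-max normalized to the writer's [0, 1]
#' payload range; the original range of every plane is recorded in a
#' `<prefix>_scaling.txt` sidecar (`plane min max` per line) so values are
#' exactly recoverable. The RGB composition goes out as an 8-bit PNG.
#'
#' @param planes a [reconstructed_planes()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, e.g. `"z00800"`.
#' @return invisibly, character vector of written paths.
#' @export
write_planes <- function(planes, dir, prefix) {
  stopifnot(inherits(planes, "reconstructed_planes"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  scaling <- character(0)
  for (nm in c("real_part", "imag_part", "amplitude", "phase")) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    v <- planes[[nm]]
    lo <- min(v); hi <- max(v)
    write_float_tiff(if (hi > lo) (v - lo) / (hi - lo) else v * 0, p)
    scaling <- c(scaling, sprintf("%s %.10g %.10g", nm, lo, hi))
    paths <- c(paths, p)
  }
  writeLines(scaling, file.path(dir, sprintf("%s_scaling.txt", prefix)))
  p <- file.path(dir, sprintf("%s_composition.png", prefix))
  write_png8(compose_rgb(planes), p)
  invisible(c(paths, p))
}

#' Export a line profile as CSV
#'
#' Two columns: `position_px`, `intensity`.
#'
#' @param profile a [line_profile()] result.
#' @param path output `.csv` path.
#' @return invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "profile_measurement"))
  utils::write.csv(data.frame(position_px = profile$positions,
                              intensity = profile$intensities),
                   path, row.names = FALSE)
  invisible(path)
}
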