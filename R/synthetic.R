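# Synthetic acquisition simulator: planar complex transmittance scenes,
# forward diffraction to the detector, per-frame sub-pixel shifts on an
# irregular displacement grid, detector-pitch downsampling, quantization
# and shot/read noise — with full ground truth.

#' Scene specification for the synthetic generator
#'
#' Describes a planar complex-transmittance scene on the HR grid (pitch =
#' detector pitch / upsampling factor). Objects are listed as
#' `list(shape = "disk" | "ellipse" | "sperm", centre = c(row_um, col_um),
#' size = ..., transmittance = a in [0,1], phase = radians)`; sizes are in
#' micrometres (`size` is the disk radius, `c(semi_r, semi_c)` for
#' ellipses, and the head semi-axes for sperm-like objects, which add a
#' thin wavy tail). Overlapping objects multiply their transmittances.
#'
#' @param dim HR canvas `c(nrow, ncol)` in pixels.
#' @param pitch HR pixel pitch in micrometres (default 1.67 / 4).
#' @param objects list of object descriptors (see above).
#' @param z scene-to-detector distance in micrometres (default 800).
#' @param wavelength illumination wavelength in micrometres (default 0.385).
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(dim = c(256, 256), pitch = 1.67 / 4, objects = list(),
                       z = 800, wavelength = 0.385) {
  stopifnot(length(dim) == 2, all(dim >= 2), pitch > 0, z > 0, wavelength > 0)
  for (ob in objects) {
    if (!is.list(ob) || is.null(ob$shape) || is.null(ob$centre))
      stop("each object needs at least `shape` and `centre`")
    tr <- ob$transmittance %||% 0
    if (tr < 0 || tr > 1) stop("`transmittance` must lie in [0, 1]")
  }
  structure(list(dim = as.integer(dim), pitch = pitch, objects = objects,
                 z = z, wavelength = wavelength),
            class = "scene_spec")
}

# Soft-edged (1 px anti-aliased) masks for one object on the grid. Returns a
# list of parts, each `list(mask, t)` with mask in [0,1] and t the complex
# transmittance of that part; sperm-like objects contribute a head part and
# a tail part with independent optical properties (dense absorbing head,
# thin phase-shifting tail).
object_parts <- function(ob, dim, pitch) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2]) * pitch
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE) * pitch
  edge <- pitch  # 1-px anti-aliasing band
  soft <- function(d) pmin(pmax(0.5 - d / edge, 0), 1)  # d: signed distance
  ctr <- ob$centre
  tval <- (ob$transmittance %||% 0) * exp(1i * (ob$phase %||% 0))
  if (ob$shape == "disk") {
    d <- sqrt((r - ctr[1])^2 + (c - ctr[2])^2) - ob$size[1]
    return(list(list(mask = soft(d), t = tval)))
  }
  if (ob$shape == "ellipse" || ob$shape == "sperm") {
    ax <- if (length(ob$size) >= 2) ob$size[1:2] else rep(ob$size[1], 2)
    # approximate signed distance for an ellipse
    q <- sqrt(((r - ctr[1]) / ax[1])^2 + ((c - ctr[2]) / ax[2])^2)
    d <- (q - 1) * min(ax)
    parts <- list(list(mask = soft(d), t = tval))
    if (ob$shape == "sperm") {
      # thin wavy polyline tail leaving the head along +col
      len <- ob$tail_length %||% (8 * max(ax))
      wd <- ob$tail_width %||% 0.5
      amp <- ob$tail_amplitude %||% (1.5 * max(ax))
      nseg <- 16
      t <- seq(0, 1, length.out = nseg + 1)
      pr <- ctr[1] + amp * sin(3 * pi * t)
      pc <- ctr[2] + ax[2] + len * t
      dmin <- matrix(Inf, dim[1], dim[2])
      for (s in seq_len(nseg)) {
        a <- c(pr[s], pc[s]); b <- c(pr[s + 1], pc[s + 1])
        ab <- b - a; ab2 <- sum(ab^2)
        tt <- pmin(pmax(((r - a[1]) * ab[1] + (c - a[2]) * ab[2]) / ab2, 0), 1)
        dmin <- pmin(dmin, sqrt((r - a[1] - tt * ab[1])^2 +
                                (c - a[2] - tt * ab[2])^2))
      }
      t_tail <- (ob$tail_transmittance %||% 0.75) *
        exp(1i * (ob$tail_phase %||% 1.2))
      parts <- c(parts, list(list(mask = soft(dmin - wd / 2), t = t_tail)))
    }
    return(parts)
  }
  stop(sprintf("unknown object shape '%s'", ob$shape))
}

#' Render a scene specification into a complex transmittance field
#'
#' Background transmittance is 1 (clear); each object multiplies in a
#' soft-edged factor interpolating between 1 and its complex transmittance
#' `a * exp(i phase)`. Deterministic for a fixed spec and seed.
#'
#' @param spec a [scene_spec()].
#' @param seed RNG seed (reserved for randomized object generators;
#'   rendering itself is deterministic).
#' @return a [complex_field()] at the scene pitch and wavelength.
#' @export
make_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  t <- matrix(1 + 0i, spec$dim[1], spec$dim[2])
  with_seed(seed, {
    for (ob in spec$objects) {
      for (part in object_parts(ob, spec$dim, spec$pitch))
        t <- t * (1 - part$mask * (1 - part$t))
    }
  })
  complex_field(t, spec$pitch, spec$wavelength)
}

#' Forward-simulate the detector-plane hologram of a scene
#'
#' Propagates the complex transmittance (illuminated by a unit plane wave)
#' over the scene-to-detector distance with the angular-spectrum method and
#' records the intensity, normalized so the background level is 1.
#'
#' @param scene a [complex_field()] transmittance from [make_scene()].
#' @param z scene-to-detector distance in micrometres (> 0).
#' @param pad passed to [propagate()].
#' @return numeric intensity matrix (HR grid).
#' @export
simulate_hologram <- function(scene, z, pad = TRUE) {
  if (z <= 0) stop("`z` must be positive")
  U <- propagate(scene, z, pad = pad)
  I <- Mod(U$values)^2
  I / stats::median(I)
}

#' Irregular displacement grid
#'
#' An n x n lattice of shifts centred on zero with lattice constant `step`,
#' plus i.i.d. uniform jitter in `[-jitter, jitter]` per axis — the
#' irregular light-source displacement matrix the acquisition emulates.
#' Deterministic under `seed`.
#'
#' @param n lattice side (default 7 -> 49 positions).
#' @param step lattice constant in LR pixels (default 0.5).
#' @param jitter uniform jitter half-width in LR pixels (default 0.3).
#' @param seed RNG seed.
#' @return n^2 x 2 matrix of `(dr, dc)` shifts in LR pixels, row-major over
#'   the lattice.
#' @export
grid_shifts <- function(n = 7, step = 0.5, jitter = 0.3, seed = 1L) {
  stopifnot(n >= 1, step > 0, jitter >= 0)
  base <- (seq_len(n) - (n + 1) / 2) * step
  g <- expand.grid(dr = base, dc = base)
  with_seed(seed, {
    j <- matrix(stats::runif(2 * n^2, -jitter, jitter), n^2, 2)
    cbind(dr = g$dr, dc = g$dc) + j
  })
}

# Sub-pixel translation of an image by (dr, dc) pixels via the Fourier
# shift theorem, with 2x replicate guard padding against wrap-around.
fourier_shift <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- nr %/% 2; pc <- nc %/% 2
  P <- pad_replicate(img, max(pr, pc))
  P <- P[seq_len(nr + 2 * pr), seq_len(nc + 2 * pc), drop = FALSE]
  fr <- fft_freq(nrow(P)); fc <- fft_freq(ncol(P))
  ph <- exp(-2i * pi * (outer(fr * dr, fc * dc, `+`)))
  S <- Re(stats::fft(stats::fft(P) * ph, inverse = TRUE)) / length(P)
  S[(pr + 1):(pr + nr), (pc + 1):(pc + nc)]
}

#' Acquisition specification for the LR stack simulator
#'
#' @param factor integer HR-to-LR downsampling factor (default 4).
#' @param n displacement-lattice side (default 7: 49 frames).
#' @param step,jitter lattice constant and jitter (LR px; defaults 0.5, 0.3).
#' @param dn_scale digital number corresponding to unit (background)
#'   intensity (default 180 DN on the 8-bit range).
#' @param read_sigma Gaussian read noise, DN (default 1).
#' @param poisson_scale photons per DN for shot noise; 0 disables (default 4).
#' @param bit_depth quantization depth in bits; NA keeps noiseless float
#'   frames (default 8).
#' @param seed RNG seed.
#' @return list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(factor = 4L, n = 7L, step = 0.5, jitter = 0.3,
                             dn_scale = 180, read_sigma = 1,
                             poisson_scale = 4, bit_depth = 8L, seed = 1L) {
  stopifnot(factor >= 1, n >= 1, jitter >= 0, dn_scale > 0,
            read_sigma >= 0, poisson_scale >= 0)
  structure(list(factor = as.integer(factor), n = as.integer(n), step = step,
                 jitter = jitter, dn_scale = dn_scale,
                 read_sigma = read_sigma, poisson_scale = poisson_scale,
                 bit_depth = bit_depth, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Simulate an LR frame stack from an HR hologram
#'
#' For each position of the irregular displacement grid, the HR hologram is
#' translated by the sub-pixel shift (Fourier shift theorem with guard
#' padding), box-averaged down to the detector pitch, scaled to digital
#' numbers, degraded with Poisson shot noise and Gaussian read noise, and
#' clipped/quantized to the sensor bit depth. Frames are returned in linear
#' intensity units (background about 1) together with the ground-truth
#' alignment shifts.
#'
#' The recorded shift of frame i is the translation that maps frame-i
#' coordinates onto reference-scene coordinates (LR pixels): frame content
#' equals the hologram translated by minus that shift.
#'
#' @param hologram_hr numeric HR intensity matrix, dimensions divisible by
#'   `acq$factor`.
#' @param acq an [acquisition_spec()].
#' @return an [lr_stack()] with `shifts` set (n^2 x 2, LR pixels).
#' @export
simulate_lr_stack <- function(hologram_hr, acq = acquisition_spec()) {
  stopifnot(inherits(acq, "acquisition_spec"))
  f <- acq$factor
  nr <- nrow(hologram_hr); nc <- ncol(hologram_hr)
  if (nr %% f != 0 || nc %% f != 0)
    stop("hologram dimensions must be divisible by the downsampling factor")
  shifts <- grid_shifts(acq$n, acq$step, acq$jitter, acq$seed)
  guard <- min(nr, nc) %/% 2 / f
  if (max(abs(shifts)) > guard)
    stop("shift exceeds the guard margin of the hologram")
  quant <- is.finite(acq$bit_depth %||% NA)
  dn_max <- if (quant) 2^acq$bit_depth - 1 else Inf
  frames <- vector("list", nrow(shifts))
  with_seed(acq$seed + 1L, {
    for (i in seq_len(nrow(shifts))) {
      # content = hologram translated by -shift (in HR pixels)
      sh <- fourier_shift(hologram_hr, -shifts[i, 1] * f, -shifts[i, 2] * f)
      lr <- box_downsample(sh, f)
      dn <- lr * acq$dn_scale
      if (acq$poisson_scale > 0)
        dn <- stats::rpois(length(dn), pmax(dn, 0) * acq$poisson_scale) /
          acq$poisson_scale
      if (acq$read_sigma > 0)
        dn <- dn + stats::rnorm(length(dn), 0, acq$read_sigma)
      if (quant) dn <- round(pmin(pmax(dn, 0), dn_max))
      frames[[i]] <- matrix(dn / acq$dn_scale, nr %/% f, nc %/% f)
    }
  })
  lr_stack(frames, pitch = 1.67, shifts = shifts)
}

#' Write / read an LR stack with its plain-text manifest
#'
#' Frames are written as numbered single-channel TIFFs (8-bit when the
#' stack was quantized to [0, 255/dn_scale], 32-bit float otherwise) and a
#' `manifest.txt` records, per frame, the file name and true shifts, plus
#' header lines with the seed, pitch and intensity scaling.
#'
#' @param stack an [lr_stack()].
#' @param dir output directory (created if missing).
#' @param dn_scale digital-number scale used to encode intensities.
#' @param seed seed to record in the manifest.
#' @return `write_lr_stack`: invisibly, the manifest path;
#'   `read_lr_stack`: the reconstructed [lr_stack()].
#' @export
write_lr_stack <- function(stack, dir, dn_scale = 180, seed = NA_integer_) {
  stopifnot(inherits(stack, "lr_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- length(stack$frames)
  files <- sprintf("frame_%03d.tif", seq_len(m))
  # 8-bit encoding only when the frames already are integer digital
  # numbers on the 8-bit range; anything else goes out as scaled float
  eight_bit <- all(vapply(stack$frames, function(f) {
    dn <- f * dn_scale
    max(dn) <= 255 + 1e-9 && max(abs(dn - round(dn))) < 1e-9
  }, logical(1)))
  # TIFF payloads must lie in [0, 1]; float frames are normalized by a
  # recorded scale
  float_scale <- max(vapply(stack$frames, max, numeric(1)), 1e-12)
  for (i in seq_len(m)) {
    if (eight_bit) {
      # nudge above the level boundary so the writer's truncation cannot
      # drop a digital number by one
      dn <- pmin(pmax(round(stack$frames[[i]] * dn_scale), 0), 255)
      tiff::writeTIFF(pmin(dn / 255 + 1e-6, 1), file.path(dir, files[i]),
                      bits.per.sample = 8L)
    } else {
      tiff::writeTIFF(pmin(pmax(stack$frames[[i]] / float_scale, 0), 1),
                      file.path(dir, files[i]), bits.per.sample = 32L)
    }
  }
  sh <- stack$shifts %||% matrix(NA_real_, m, 2)
  man <- file.path(dir, "manifest.txt")
  hdr <- c(sprintf("# pitch: %.10g", stack$pitch),
           sprintf("# dn_scale: %.10g", dn_scale),
           sprintf("# float_scale: %.10g", float_scale),
           sprintf("# seed: %s", seed),
           sprintf("# encoding: %s", if (eight_bit) "uint8" else "float32"),
           "# file dr dc")
  rows <- sprintf("%s %.10g %.10g", files, sh[, 1], sh[, 2])
  writeLines(c(hdr, rows), man)
  invisible(man)
}

#' @rdname write_lr_stack
#' @param manifest path to a manifest written by [write_lr_stack()].
#' @export
read_lr_stack <- function(manifest) {
  lines <- readLines(manifest)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), hdr, value = TRUE))
  pitch <- as.numeric(getv("pitch"))
  dn_scale <- as.numeric(getv("dn_scale"))
  fs <- getv("float_scale")
  float_scale <- if (length(fs)) as.numeric(fs) else 1
  enc <- getv("encoding")
  body <- lines[!grepl("^#", lines)]
  tok <- strsplit(trimws(body), "\\s+")
  dir <- dirname(manifest)
  frames <- lapply(tok, function(t) {
    img <- tiff::readTIFF(file.path(dir, t[1]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (enc == "uint8") img * 255 / dn_scale else img * float_scale
  })
  sh <- do.call(rbind, lapply(tok, function(t) as.numeric(t[2:3])))
  if (all(is.na(sh))) sh <- NULL
  lr_stack(frames, pitch = pitch, shifts = sh)
}
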