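# Independent oracles and small fixture builders shared across test files.

# Direct Rayleigh-Sommerfeld diffraction sum (first RS solution, point-to-
# point double loop) — the brute-force oracle for angular-spectrum
# propagation. Deliberately independent of the package's FFT path.
rs_propagate <- function(U, pitch, lambda, z) {
  n <- nrow(U); k <- 2 * pi / lambda
  xs <- (seq_len(n) - (n + 1) / 2) * pitch
  out <- matrix(0 + 0i, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      dx <- xs[a] - xs; dy <- xs[b] - xs
      R <- sqrt(outer(dx^2, dy^2, `+`) + z^2)
      kern <- (1 / (2 * pi)) * (z / R) * (1 / R - 1i * k) * exp(1i * k * R) / R
      out[a, b] <- sum(U * kern) * pitch^2
    }
  }
  out
}

# Gaussian-blob complex field on an n x n grid (band-limited, centred);
# the regime in which both the ASM and the discrete RS sum are valid.
blob_field <- function(n, pitch, lambda, sigma_px = 1.5) {
  ctr <- (n + 1) / 2
  U <- exp(-((row(matrix(0, n, n)) - ctr)^2 +
             (col(matrix(0, n, n)) - ctr)^2) / (2 * sigma_px^2)) + 0i
  complex_field(U, pitch, lambda)
}

rel_rms <- function(a, b) sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))

# Noise-free / noisy LR stacks from the standard cell scene. The default
# propagation distance stays inside the grid's aliasing-free limit.
make_cell_stack <- function(lr_dim = 64, factor = 4, z = NULL, n = 7,
                            step = 0.5, jitter = 0.3, read_sigma = 1,
                            poisson_scale = 4, bit_depth = 8, seed = 11,
                            scene_seed = 3) {
  if (is.null(z))
    z <- round(0.85 * 2 * lr_dim * factor * (1.67 / factor)^2 / 0.385)
  sp <- fixture_cell_scene(lr_dim = lr_dim, factor = factor, z = z,
                           seed = scene_seed)
  holo <- simulate_hologram(make_scene(sp), z)
  acq <- acquisition_spec(factor = factor, n = n, step = step,
                          jitter = jitter, read_sigma = read_sigma,
                          poisson_scale = poisson_scale,
                          bit_depth = bit_depth, seed = seed)
  list(stack = simulate_lr_stack(holo, acq), holo = holo, spec = sp)
}

# keypoints/match_set builders for transform-estimation tests that bypass
# the detector.
as_keypoints <- function(p) {
  structure(list(keypoints = data.frame(row = p[, 1], col = p[, 2],
                                        scale = 1, orientation = 0,
                                        response = 1),
                 descriptors = matrix(0, nrow(p), 4)),
            class = "keypoints")
}

as_matches <- function(n) {
  structure(data.frame(ref_index = seq_len(n), cand_index = seq_len(n),
                       distance = 0),
            class = c("match_set", "data.frame"))
}
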