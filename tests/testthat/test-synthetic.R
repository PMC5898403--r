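# Acquisition simulator: scenes, forward holograms, displacement grids,
# LR stack generation, manifests.

test_that("scene rendering honours geometry, background and determinism", {
  # empty object list -> all-ones transmittance
  sp0 <- scene_spec(dim = c(64, 64), pitch = 0.5, z = 100)
  expect_true(all(make_scene(sp0)$values == 1 + 0i))
  # centred opaque disk: occluded-pixel fraction matches pi r^2 / area
  r_um <- 10
  sp <- scene_spec(dim = c(160, 160), pitch = 0.5, z = 100,
                   objects = list(list(shape = "disk", centre = c(40, 40),
                                       size = r_um, transmittance = 0)))
  t <- make_scene(sp)$values
  frac <- mean(Mod(t) < 0.5)
  expect_equal(frac, pi * (r_um / 0.5)^2 / (160 * 160), tolerance = 0.02)
  # bitwise determinism
  expect_identical(make_scene(sp, seed = 4)$values, make_scene(sp, seed = 4)$values)
  expect_error(scene_spec(objects = list(list(shape = "disk", centre = c(1, 1),
                                              transmittance = 1.5))),
               "transmittance")
})

test_that("an empty scene produces a uniform unit hologram", {
  sp <- scene_spec(dim = c(64, 64), pitch = 1.67, z = 150)
  h <- simulate_hologram(make_scene(sp), 150)
  expect_true(all(abs(h - 1) < 1e-9))
  expect_error(simulate_hologram(make_scene(sp), -5), "positive")
})

test_that("a small disk yields countable concentric fringes", {
  sp <- scene_spec(dim = c(192, 192), pitch = 1.67, z = 400,
                   objects = list(list(shape = "disk", centre = c(160, 160),
                                       size = 4, transmittance = 0)))
  h <- simulate_hologram(make_scene(sp), 400)
  pr <- line_profile(h, c(96, 96), c(96, 190), 240)
  expect_gte(count_cycles(pr, 0.05), 3)
})

test_that("the simulated hologram matches the diffraction-sum oracle", {
  sp <- scene_spec(dim = c(32, 32), pitch = 2, z = 200, wavelength = 1,
                   objects = list(list(shape = "disk", centre = c(32, 32),
                                       size = 5, transmittance = 0.2)))
  scn <- make_scene(sp)
  I_asm <- simulate_hologram(scn, 200)
  scattered <- scn$values - 1
  rs <- rs_propagate(scattered, 2, 1, 200) + exp(2i * pi * 200 / 1)
  I_rs <- Mod(rs)^2
  I_rs <- I_rs / stats::median(I_rs)
  ci <- 11:23
  expect_lt(sqrt(mean((I_asm[ci, ci] - I_rs[ci, ci])^2)) /
              sqrt(mean(I_rs[ci, ci]^2)), 0.01)
})

test_that("displacement grids are centred lattices with bounded jitter", {
  # n = 1: single shift within the jitter box
  s1 <- grid_shifts(1, 0.5, 0.3, seed = 2)
  expect_identical(dim(s1), c(1L, 2L))
  expect_true(all(abs(s1) <= 0.3))
  # n = 7, no jitter: the exact 49-point lattice
  s0 <- grid_shifts(7, 0.5, 0, seed = 1)
  base <- (1:7 - 4) * 0.5
  expect_identical(nrow(s0), 49L)
  expect_equal(sort(unique(s0[, 1])), base, tolerance = 1e-12)
  expect_equal(colMeans(s0), c(dr = 0, dc = 0), tolerance = 1e-12)
  # jitter never exceeds its half-width
  sj <- grid_shifts(7, 0.5, 0.3, seed = 3)
  lat <- as.matrix(expand.grid(dr = base, dc = base))
  expect_true(max(abs(sj - lat)) <= 0.3)
  # deterministic under seed
  expect_identical(sj, grid_shifts(7, 0.5, 0.3, seed = 3))
})

test_that("LR stack generation respects shifts, averaging and quantization", {
  fx <- make_cell_stack(lr_dim = 48, n = 1, jitter = 0)
  holo <- fx$holo
  # zero shift, no noise, factor 1: frames equal the quantized hologram
  acq1 <- acquisition_spec(factor = 1, n = 1, jitter = 0, read_sigma = 0,
                           poisson_scale = 0, bit_depth = 8, seed = 1)
  st1 <- simulate_lr_stack(holo, acq1)
  expect_equal(st1$frames[[1]], pmin(round(holo * 180), 255) / 180,
               tolerance = 1e-12)
  # factor 2, no noise: box-average conserves the mean
  acq2 <- acquisition_spec(factor = 2, n = 1, jitter = 0, read_sigma = 0,
                           poisson_scale = 0, bit_depth = 8, seed = 1)
  st2 <- simulate_lr_stack(holo, acq2)
  expect_lt(abs(mean(st2$frames[[1]]) - mean(holo)), 1 / 180)
  # 7x7 grid with jitter: 49 frames, recorded shifts near lattice points
  acq3 <- acquisition_spec(factor = 4, n = 7, step = 0.5, jitter = 0.3, seed = 4)
  st3 <- simulate_lr_stack(holo[1:192, 1:192], acq3)
  expect_identical(length(st3$frames), 49L)
  lat <- as.matrix(expand.grid(dr = (1:7 - 4) * 0.5, dc = (1:7 - 4) * 0.5))
  expect_true(max(abs(st3$shifts - lat)) <= 0.3)
  # oversized shifts hit the guard margin
  acq4 <- acquisition_spec(factor = 4, n = 3, step = 40, jitter = 0, seed = 1)
  expect_error(simulate_lr_stack(holo[1:192, 1:192], acq4), "guard")
  expect_error(simulate_lr_stack(holo[1:50, 1:50],
                                 acquisition_spec(factor = 4)), "divisible")
})

test_that("shifted frames are consistent with their recorded ground truth", {
  # a frame with shift s must equal the reference scene translated by -s:
  # check against an independently generated stack whose lattice is offset
  fx <- make_cell_stack(lr_dim = 48, n = 1, jitter = 0, read_sigma = 0,
                        poisson_scale = 0, bit_depth = NA)
  acq <- acquisition_spec(factor = 4, n = 1, step = 1, jitter = 0.4,
                          read_sigma = 0, poisson_scale = 0, bit_depth = NA,
                          seed = 9)
  st <- simulate_lr_stack(fx$holo, acq)
  s <- st$shifts[1, ]
  # sample the unshifted LR rendering at positions displaced by -s
  lr0 <- holopsr:::box_downsample(fx$holo, 4)
  g <- expand.grid(r = 1:48, c = 1:48)
  pred <- matrix(holopsr:::bicubic_sample(lr0, g$r + s[1], g$c + s[2]), 48, 48)
  core <- 5:44
  expect_lt(sqrt(mean((pred[core, core] - st$frames[[1]][core, core])^2)),
            0.02 * diff(range(lr0)))
})

test_that("doubling the photon budget halves the relative shot-noise variance", {
  fx <- make_cell_stack(lr_dim = 64, n = 1, jitter = 0)
  mk <- function(ps, seed) {
    acq <- acquisition_spec(factor = 4, n = 1, jitter = 0, read_sigma = 0,
                            poisson_scale = ps, bit_depth = NA, seed = seed)
    simulate_lr_stack(fx$holo, acq)$frames[[1]]
  }
  clean <- {
    acq <- acquisition_spec(factor = 4, n = 1, jitter = 0, read_sigma = 0,
                            poisson_scale = 0, bit_depth = NA, seed = 1)
    simulate_lr_stack(fx$holo, acq)$frames[[1]]
  }
  v1 <- mean(vapply(1:6, function(s) stats::var(as.vector(mk(4, s) - clean)),
                    numeric(1)))
  v2 <- mean(vapply(1:6, function(s) stats::var(as.vector(mk(8, s) - clean)),
                    numeric(1)))
  expect_equal(v1 / v2, 2, tolerance = 0.1)
})

test_that("LR stacks round-trip through TIFFs and plain-text manifests", {
  fx <- make_cell_stack(lr_dim = 32, n = 2, step = 0.6, jitter = 0.2, seed = 6)
  dir <- file.path(tempdir(), "stack_rt")
  man <- write_lr_stack(fx$stack, dir, seed = 6)
  expect_true(file.exists(man))
  back <- read_lr_stack(man)
  expect_identical(length(back$frames), length(fx$stack$frames))
  expect_equal(back$shifts, fx$stack$shifts, ignore_attr = TRUE,
               tolerance = 1e-8)
  for (i in seq_along(back$frames))
    expect_equal(back$frames[[i]], fx$stack$frames[[i]], tolerance = 1e-6)
  # float stacks (unquantized) survive too
  fx2 <- make_cell_stack(lr_dim = 32, n = 1, jitter = 0.2, read_sigma = 0,
                         poisson_scale = 0, bit_depth = NA)
  man2 <- write_lr_stack(fx2$stack, file.path(tempdir(), "stack_f"), seed = 1)
  back2 <- read_lr_stack(man2)
  expect_equal(back2$frames[[1]], fx2$stack$frames[[1]], tolerance = 1e-6)
})

test_that("end-to-end ground-truth closure: simulate then recover the shifts", {
  fx <- make_cell_stack(lr_dim = 48, n = 3, step = 0.5, jitter = 0.3, z = 150,
                        read_sigma = 0, poisson_scale = 0, bit_depth = NA,
                        seed = 21)
  tfs <- suppressWarnings(prealign_stack(fx$stack, reference = 5,
                                         model = "translation",
                                         ratio = 0.9, max_shift = 5))
  res <- super_resolve(fx$stack, tfs, eparams = energy_params(beta = 0),
                       factor = 2, sweeps = 3, reference = 5)
  gt <- sweep(fx$stack$shifts, 2, fx$stack$shifts[5, ])
  expect_lt(sqrt(mean((total_alignment(res) - gt)^2)), 0.1)
})
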