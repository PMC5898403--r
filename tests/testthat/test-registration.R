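# Feature detection, matching, geometric filtering, robust transform
# estimation, warping and stack pre-alignment.

blob_image <- function(n = 96, k = 12, seed = 5, sigma = 2.5) {
  set.seed(seed)
  img <- matrix(0, n, n)
  pos <- cbind(runif(k, 12, n - 12), runif(k, 12, n - 12))
  amp <- runif(k, 0.5, 1)
  for (i in seq_len(k))
    img <- img + amp[i] * exp(-((row(img) - pos[i, 1])^2 +
                                (col(img) - pos[i, 2])^2) / (2 * sigma^2))
  img
}

test_that("feature detection is empty on constants and populous on structured images", {
  empty <- detect_features(matrix(1, 64, 64))
  expect_identical(nrow(empty$keypoints), 0L)
  # synthetic fringe image with dozens of contrast extrema
  fr <- outer(seq_len(96), seq_len(96), function(r, c)
    sin(r / 3) * cos(c / 3.5))
  kp <- detect_features(fr)
  expect_gte(nrow(kp$keypoints), 10)
  # sorted by response, descending
  expect_true(all(diff(kp$keypoints$response) <= 1e-12))
  # deterministic
  kp2 <- detect_features(fr)
  expect_identical(kp$keypoints, kp2$keypoints)
  expect_error(detect_features(matrix(0, 16, 16)), "32x32")
})

test_that("keypoints of an integer-translated copy move by the translation", {
  img <- blob_image()
  dr <- 3L; dc <- -2L
  shifted <- matrix(0, 96, 96)
  shifted[(1 + dr):96, 1:(96 + dc)] <- img[1:(96 - dr), (1 - dc):96]
  ka <- detect_features(img); kb <- detect_features(shifted)
  m <- match_features(ka, kb)
  expect_gt(nrow(m), 5)
  d <- as.matrix(kb$keypoints[m$cand_index, c("row", "col")]) -
       as.matrix(ka$keypoints[m$ref_index, c("row", "col")])
  interior <- ka$keypoints$row[m$ref_index] > 15 &
              ka$keypoints$row[m$ref_index] < 78
  expect_true(all(abs(d[interior, 1] - dr) < 0.5))
  expect_true(all(abs(d[interior, 2] - dc) < 0.5))
})

test_that("descriptor matching recovers identity and permutations, rejects noise", {
  img <- blob_image()
  kp <- detect_features(img)
  m <- match_features(kp, kp)
  expect_identical(m$ref_index, m$cand_index)
  expect_true(all(m$distance < 1e-5))  # distance-matrix round-off scale
  # permuted candidate list: exhaustive-NN oracle says match j -> perm[j]
  set.seed(1)
  perm <- sample(nrow(kp$keypoints))
  kperm <- kp
  kperm$keypoints <- kp$keypoints[perm, ]
  kperm$descriptors <- kp$descriptors[perm, , drop = FALSE]
  mp <- match_features(kp, kperm)
  expect_true(all(perm[mp$cand_index] == mp$ref_index))
  # independent random descriptors: almost nothing survives the ratio test
  set.seed(2)
  krand <- kp
  krand$descriptors <- matrix(rnorm(length(kp$descriptors)),
                              nrow(kp$descriptors))
  mr <- match_features(kp, krand)
  expect_lte(nrow(mr), ceiling(0.05 * nrow(kp$keypoints)))
  # empty input
  e <- detect_features(matrix(1, 64, 64))
  expect_identical(nrow(match_features(e, kp)), 0L)
})

test_that("geometric filtering keeps consistent displacements and drops outliers", {
  mk <- function(p) as_keypoints(p)
  base <- cbind(runif(10, 20, 80), runif(10, 20, 80))
  # all displacements identical -> all retained
  m <- filter_matches(as_matches(10), mk(base + 2.5), mk(base))
  expect_identical(nrow(m), 10L)
  # 9 consistent + 1 opposite-direction -> exactly the outlier removed
  ref <- base + matrix(c(rep(2, 9), -2, rep(3, 9), -3), 10, 2)
  m2 <- filter_matches(as_matches(10), mk(ref), mk(base))
  expect_identical(nrow(m2), 9L)
  expect_false(10L %in% m2$ref_index)
  # empty set passes through
  m0 <- match_features(detect_features(matrix(1, 64, 64)),
                       detect_features(matrix(1, 64, 64)))
  expect_identical(nrow(filter_matches(m0, mk(base), mk(base))), 0L)
  # displacement prior discards implausibly long moves
  far <- base; far[4, ] <- far[4, ] + 40
  m3 <- filter_matches(as_matches(10), mk(far + 1), mk(base), max_shift = 5)
  expect_false(4L %in% m3$ref_index)
})

test_that("transform estimation is exact on clean and 30%-contaminated correspondences", {
  set.seed(9)
  H <- matrix(c(1.02, 0.01, 2.3, -0.015, 0.99, -1.7, 1e-5, -2e-5, 1),
              3, 3, byrow = TRUE)
  n <- 40
  src <- cbind(runif(n, 10, 90), runif(n, 10, 90))
  X <- cbind(src, 1) %*% t(H)
  dst <- X[, 1:2] / X[, 3]
  tf <- estimate_transform(as_matches(n), as_keypoints(dst), as_keypoints(src),
                           model = "homography", seed = 1)
  expect_lt(max(abs(tf$matrix - H)), 1e-6)
  # identity correspondences
  ti <- estimate_transform(as_matches(n), as_keypoints(src), as_keypoints(src),
                           model = "homography", seed = 1)
  expect_lt(max(abs(ti$matrix - diag(3))), 1e-6)
  # 30% gross outliers: still exact, translation within 0.1 px
  dst2 <- dst
  out <- sample(n, 12)
  dst2[out, ] <- dst2[out, ] + matrix(runif(24, 5, 30), 12, 2)
  tr <- estimate_transform(as_matches(n), as_keypoints(dst2), as_keypoints(src),
                           model = "homography", seed = 3)
  expect_lt(max(abs(tr$matrix - H)), 1e-6)
  expect_lt(max(abs(tr$matrix[1:2, 3] - H[1:2, 3])), 0.1)
  expect_identical(tr$inliers, 28L)
  # reproducibility under a fixed seed
  tr2 <- estimate_transform(as_matches(n), as_keypoints(dst2), as_keypoints(src),
                            model = "homography", seed = 3)
  expect_identical(tr$matrix, tr2$matrix)
  expect_error(estimate_transform(as_matches(3), as_keypoints(dst[1:3, ]),
                                  as_keypoints(src[1:3, ]), model = "homography"),
               "degenerate")
})

test_that("warping honours identity, integer shifts and inverse round trips", {
  img <- blob_image(n = 64, k = 8)
  w <- warp(img, pt_identity())
  expect_equal(w, img, ignore_attr = TRUE, tolerance = 1e-12)
  # integer translation equals the index-shift oracle on the interior
  t23 <- pt_translation(2, 3)
  w2 <- warp(img, t23)
  oracle <- matrix(0, 64, 64)
  oracle[3:64, 4:64] <- img[1:62, 1:61]
  expect_equal(w2[5:60, 5:60], oracle[5:60, 5:60], tolerance = 1e-8)
  # T then T^-1 returns the interior within interpolation tolerance
  M <- diag(3); M[1, 3] <- 1.3; M[2, 3] <- -0.7; M[1, 2] <- 0.02
  tf <- planar_transform(M)
  inv <- planar_transform(solve(M))
  rt <- warp(warp(img, tf), inv)
  rng <- diff(range(img))
  expect_lt(sqrt(mean((rt[8:56, 8:56] - img[8:56, 8:56])^2)) / rng, 1e-2)
  expect_error(planar_transform(matrix(0, 3, 3)), "singular")
})

test_that("stack pre-alignment recovers known shifts and falls back gracefully", {
  # identical frames -> identity transforms
  img <- blob_image(n = 64, k = 8)
  st <- lr_stack(list(img, img, img))
  tfs <- prealign_stack(st, model = "translation")
  for (tf in tfs) expect_lt(max(abs(tf$matrix - diag(3))), 1e-6)
  # known sub-pixel shifts on hologram frames, 3x3 grid
  fx <- make_cell_stack(lr_dim = 64, n = 3, step = 1, jitter = 0.3,
                        read_sigma = 0, poisson_scale = 0, bit_depth = 8)
  tfs <- prealign_stack(fx$stack, reference = 5, model = "translation")
  gt <- sweep(fx$stack$shifts, 2, fx$stack$shifts[5, ])
  est <- t(vapply(tfs, function(t) t$matrix[1:2, 3], numeric(2)))
  expect_lt(sqrt(mean((est - gt)^2)), 0.5)
  expect_identical(length(tfs), 9L)
  # featureless frames fall back to identity with a warning
  flat <- lr_stack(list(matrix(1, 64, 64), matrix(1, 64, 64)))
  expect_warning(tf0 <- prealign_stack(flat, model = "translation"),
                 "identity")
  expect_lt(max(abs(tf0[[2]]$matrix - diag(3))), 1e-12)
})

test_that("pairwise alignment composes consistently (A->B->C vs A->C)", {
  fx <- make_cell_stack(lr_dim = 64, n = 2, step = 1.2, jitter = 0.2,
                        read_sigma = 0, poisson_scale = 0, bit_depth = 8)
  st <- fx$stack
  ka <- detect_features(st$frames[[1]])
  kb <- detect_features(st$frames[[2]])
  kc <- detect_features(st$frames[[3]])
  est <- function(kr, kc2) {
    m <- filter_matches(match_features(kr, kc2), kr, kc2)
    estimate_transform(m, kr, kc2, model = "translation", seed = 1)
  }
  ab <- est(kb, ka)$matrix   # A -> B frame coords mapping: cand A onto ref B
  bc <- est(kc, kb)$matrix
  ac <- est(kc, ka)$matrix
  comp <- bc %*% ab
  expect_lt(max(abs(comp[1:2, 3] - ac[1:2, 3])), 0.2)
})

test_that("transform sidecar files round-trip exactly", {
  tfs <- list(pt_identity(), pt_translation(1.25, -0.5),
              planar_transform(matrix(c(1.01, 0, 2, 0.01, 0.99, -1,
                                        1e-5, 0, 1), 3, 3, byrow = TRUE)))
  path <- tempfile(fileext = ".txt")
  write_transforms(tfs, path)
  back <- read_transforms(path)
  for (i in seq_along(tfs))
    expect_equal(back[[i]]$matrix, tfs[[i]]$matrix, tolerance = 1e-12)
})
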