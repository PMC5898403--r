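# Feature-based pre-alignment of LR frames onto a reference frame:
# keypoint detection, descriptor matching, geometric outlier rejection,
# robust transform estimation, warping.

#' Feature-detection options
#'
#' @param n_scales number of scale-space levels.
#' @param sigma0 base Gaussian scale (pixels).
#' @param scale_step multiplicative scale step between levels.
#' @param threshold_rel keep responses above this fraction of the global
#'   maximum determinant-of-Hessian response.
#' @param max_keypoints cap on returned keypoints (strongest first).
#' @param patch descriptor grid size (patch x patch samples).
#' @param orientation estimate a dominant gradient orientation and rotate
#'   the descriptor grid (default FALSE: upright descriptors; hologram
#'   stacks are not rotated between frames).
#' @return list of options for [detect_features()].
#' @export
feature_options <- function(n_scales = 4, sigma0 = 1.6, scale_step = sqrt(2),
                            threshold_rel = 0.02, max_keypoints = 500,
                            patch = 8, orientation = FALSE) {
  list(n_scales = n_scales, sigma0 = sigma0, scale_step = scale_step,
       threshold_rel = threshold_rel, max_keypoints = max_keypoints,
       patch = patch, orientation = orientation)
}

#' Detect scale-space blob keypoints with descriptors
#'
#' A determinant-of-Hessian blob detector: the image is smoothed at a small
#' bank of Gaussian scales, the scale-normalized determinant of the Hessian
#' is computed at each level, and its local spatial maxima above a relative
#' threshold become keypoints. Positions are refined to sub-pixel accuracy
#' by a 2-D quadratic fit of the response. Each keypoint carries a
#' descriptor: a `patch x patch` grid of intensities sampled at the
#' keypoint's scale from the smoothed image, normalized to zero mean and
#' unit variance. Detection is deterministic for fixed input and options.
#'
#' @param image numeric matrix, at least 32x32.
#' @param options a [feature_options()] list.
#' @return An object of class `keypoints`: list with `keypoints` (data.frame
#'   `row`, `col`, `scale`, `orientation`, `response`, sorted by descending
#'   response) and `descriptors` (matrix, one row per keypoint). A
#'   featureless image yields zero keypoints.
#' @export
detect_features <- function(image, options = feature_options()) {
  if (!is.matrix(image) || nrow(image) < 32 || ncol(image) < 32)
    stop("`image` must be at least 32x32")
  o <- options
  nr <- nrow(image); nc <- ncol(image)
  sigmas <- o$sigma0 * o$scale_step^(seq_len(o$n_scales) - 1)
  dxx <- matrix(c(1, -2, 1), 3, 1)  # column-direction (row index) 2nd diff
  levels <- lapply(sigmas, function(s) {
    L <- gaussian_blur(image, s)
    Lrr <- conv2_same(L, dxx)            # d2/drow2
    Lcc <- conv2_same(L, t(dxx))         # d2/dcol2
    Lrc <- conv2_same(L, matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1) / 4, 3, 3))
    resp <- s^4 * (Lrr * Lcc - Lrc^2)
    # zero-padded derivatives are meaningless on the frame border
    resp[c(1, 2, nr - 1, nr), ] <- 0
    resp[, c(1, 2, nc - 1, nc)] <- 0
    list(L = L, resp = resp)
  })
  rng <- diff(range(image))
  gmax <- max(vapply(levels, function(l) max(l$resp), numeric(1)))
  # floor against FFT round-off on (near-)featureless images: genuine blob
  # responses scale with the squared image contrast
  if (!is.finite(gmax) || rng == 0 || gmax <= 1e-12 * rng^2)
    return(structure(list(keypoints = data.frame(row = numeric(), col = numeric(),
                                                 scale = numeric(), orientation = numeric(),
                                                 response = numeric()),
                          descriptors = matrix(numeric(), 0, o$patch^2)),
                     class = "keypoints"))
  thr <- max(o$threshold_rel * gmax, 1e-12 * rng^2)
  kp <- list(); desc <- list()
  half <- (o$patch - 1) / 2
  for (li in seq_along(levels)) {
    s <- sigmas[li]
    R <- levels[[li]]$resp
    margin <- ceiling(half * s * sqrt(2)) + 2L
    if (nr - 2 * margin < 3 || nc - 2 * margin < 3) next
    ri <- (margin + 1):(nr - margin); ci <- (margin + 1):(nc - margin)
    C <- R[ri, ci]
    is_max <- C > thr &
      C > R[ri - 1, ci - 1] & C > R[ri - 1, ci] & C > R[ri - 1, ci + 1] &
      C > R[ri, ci - 1] & C > R[ri, ci + 1] &
      C > R[ri + 1, ci - 1] & C > R[ri + 1, ci] & C > R[ri + 1, ci + 1]
    idx <- which(is_max, arr.ind = TRUE)
    if (!nrow(idx)) next
    pr <- idx[, 1] + margin; pc <- idx[, 2] + margin
    # sub-pixel quadratic refinement of the response peak
    g_r <- (R[cbind(pr + 1, pc)] - R[cbind(pr - 1, pc)]) / 2
    g_c <- (R[cbind(pr, pc + 1)] - R[cbind(pr, pc - 1)]) / 2
    h_rr <- R[cbind(pr + 1, pc)] + R[cbind(pr - 1, pc)] - 2 * R[cbind(pr, pc)]
    h_cc <- R[cbind(pr, pc + 1)] + R[cbind(pr, pc - 1)] - 2 * R[cbind(pr, pc)]
    h_rc <- (R[cbind(pr + 1, pc + 1)] - R[cbind(pr + 1, pc - 1)] -
             R[cbind(pr - 1, pc + 1)] + R[cbind(pr - 1, pc - 1)]) / 4
    det <- h_rr * h_cc - h_rc^2
    dr <- ifelse(abs(det) > 1e-12, -(h_cc * g_r - h_rc * g_c) / det, 0)
    dc <- ifelse(abs(det) > 1e-12, -(-h_rc * g_r + h_rr * g_c) / det, 0)
    dr <- pmin(pmax(dr, -0.5), 0.5); dc <- pmin(pmax(dc, -0.5), 0.5)
    rows <- pr + dr; cols <- pc + dc
    L <- levels[[li]]$L
    ori <- rep(0, length(rows))
    if (isTRUE(o$orientation)) {
      gr <- (bilinear_sample(L, rows + 1, cols, 0) -
             bilinear_sample(L, rows - 1, cols, 0)) / 2
      gc <- (bilinear_sample(L, rows, cols + 1, 0) -
             bilinear_sample(L, rows, cols - 1, 0)) / 2
      ori <- atan2(as.numeric(gr), as.numeric(gc))
    }
    # descriptor: patch x patch grid at spacing s, rotated by orientation
    grid <- expand.grid(dr = (seq_len(o$patch) - 1 - half) * s,
                        dc = (seq_len(o$patch) - 1 - half) * s)
    D <- matrix(0, length(rows), o$patch^2)
    for (k in seq_along(rows)) {
      ca <- cos(ori[k]); sa <- sin(ori[k])
      sr <- rows[k] + ca * grid$dr + sa * grid$dc
      sc <- cols[k] - sa * grid$dr + ca * grid$dc
      D[k, ] <- as.numeric(bilinear_sample(L, sr, sc, 0))
    }
    mu <- rowMeans(D)
    sd_ <- sqrt(rowMeans((D - mu)^2))
    D <- (D - mu) / ifelse(sd_ > 1e-12, sd_, 1)
    D[sd_ <= 1e-12, ] <- 0
    kp[[length(kp) + 1]] <- data.frame(row = rows, col = cols, scale = s,
                                       orientation = ori,
                                       response = R[cbind(pr, pc)])
    desc[[length(desc) + 1]] <- D
  }
  if (!length(kp))
    return(structure(list(keypoints = data.frame(row = numeric(), col = numeric(),
                                                 scale = numeric(), orientation = numeric(),
                                                 response = numeric()),
                          descriptors = matrix(numeric(), 0, o$patch^2)),
                     class = "keypoints"))
  K <- do.call(rbind, kp)
  D <- do.call(rbind, desc)
  ord <- order(-K$response, K$row, K$col)
  if (length(ord) > o$max_keypoints) ord <- ord[seq_len(o$max_keypoints)]
  structure(list(keypoints = K[ord, , drop = FALSE],
                 descriptors = D[ord, , drop = FALSE]),
            class = "keypoints")
}

#' @export
print.keypoints <- function(x, ...) {
  cat(sprintf("<keypoints: %d detections>\n", nrow(x$keypoints)))
  invisible(x)
}

#' Match keypoint descriptors between two images
#'
#' Exact nearest-neighbour matching in descriptor space with a Lowe-style
#' ratio test: a reference keypoint is matched to its nearest candidate
#' descriptor only if the nearest distance is below `ratio` times the
#' second-nearest. Each candidate keypoint is used at most once (best
#' distance wins).
#'
#' @param ref,cand `keypoints` objects from [detect_features()].
#' @param ratio Lowe ratio threshold, default 0.75.
#' @return An object of class `match_set`: data.frame with columns
#'   `ref_index`, `cand_index`, `distance`. Empty inputs give an empty set.
#' @export
match_features <- function(ref, cand, ratio = 0.75) {
  empty <- structure(data.frame(ref_index = integer(), cand_index = integer(),
                                distance = numeric()), class = c("match_set", "data.frame"))
  if (!nrow(ref$keypoints) || !nrow(cand$keypoints)) return(empty)
  A <- ref$descriptors; B <- cand$descriptors
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2 <- pmax(d2, 0)
  out <- lapply(seq_len(nrow(A)), function(i) {
    di <- d2[i, ]
    j <- which.min(di)
    if (length(di) >= 2) {
      d2nd <- min(di[-j])
      if (sqrt(di[j]) > ratio * sqrt(d2nd)) return(NULL)
    }
    data.frame(ref_index = i, cand_index = j, distance = sqrt(di[j]))
  })
  m <- do.call(rbind, out)
  if (is.null(m) || !nrow(m)) return(empty)
  # enforce one-to-one on candidate side: keep best distance
  m <- m[order(m$distance), , drop = FALSE]
  m <- m[!duplicated(m$cand_index), , drop = FALSE]
  m <- m[order(m$ref_index), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, class = c("match_set", "data.frame"))
}

#' Reject geometrically inconsistent matches
#'
#' Computes the displacement vector of each match (reference position minus
#' candidate position) and retains only matches whose vector length and
#' angle lie within 3 median-absolute-deviations of the robust common
#' displacement. Angle filtering is skipped when the common displacement is
#' shorter than `len_floor` (near-identity alignment, where angles are
#' meaningless noise).
#'
#' @param matches a `match_set`.
#' @param ref_kp,cand_kp the `keypoints` objects the matches index into.
#' @param len_floor MAD floor for the length test (pixels), default 0.3.
#' @param ang_floor MAD floor for the angle test (radians), default 0.05.
#' @param max_shift prior bound on plausible displacement length (pixels);
#'   matches moving further are discarded before the robust fit. Useful for
#'   acquisitions whose protocol guarantees small frame-to-frame shifts,
#'   where self-similar diffraction rings of distinct objects would
#'   otherwise cross-match. Default `Inf` (no prior).
#' @return filtered `match_set`; empty (with a warning) when every match is
#'   rejected.
#' @export
filter_matches <- function(matches, ref_kp, cand_kp,
                           len_floor = 0.3, ang_floor = 0.05,
                           max_shift = Inf) {
  if (!nrow(matches)) return(matches)
  pr <- as.matrix(ref_kp$keypoints[matches$ref_index, c("row", "col")])
  pc <- as.matrix(cand_kp$keypoints[matches$cand_index, c("row", "col")])
  d <- pr - pc
  len <- sqrt(rowSums(d^2))
  if (is.finite(max_shift)) {
    ok <- len <= max_shift
    matches <- matches[ok, , drop = FALSE]
    if (!nrow(matches)) {
      warning("all matches rejected as geometric outliers")
      return(structure(matches, class = c("match_set", "data.frame")))
    }
    d <- d[ok, , drop = FALSE]; len <- len[ok]
  }
  med_d <- c(stats::median(d[, 1]), stats::median(d[, 2]))
  med_len <- stats::median(len)
  mad_len <- stats::median(abs(len - med_len))
  keep <- abs(len - med_len) <= 3 * max(mad_len, len_floor)
  if (sqrt(sum(med_d^2)) > 3 * len_floor) {
    ang <- atan2(d[, 1], d[, 2])
    ang0 <- atan2(med_d[1], med_d[2])
    dang <- atan2(sin(ang - ang0), cos(ang - ang0))
    mad_ang <- stats::median(abs(dang))
    keep <- keep & abs(dang) <= 3 * max(mad_ang, ang_floor)
  }
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("all matches rejected as geometric outliers")
  structure(out, class = c("match_set", "data.frame"))
}

# --- planar transforms -------------------------------------------------

#' Planar (projective) transform
#'
#' A 3x3 homography mapping frame coordinates `c(row, col)` to reference
#' coordinates, normalized so the bottom-right entry is 1.
#'
#' @param M 3x3 numeric matrix, invertible.
#' @param inliers optional inlier count from robust estimation.
#' @param model one of "homography", "affine", "translation", "identity".
#' @return object of class `planar_transform`.
#' @export
planar_transform <- function(M, inliers = NA_integer_, model = "homography") {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(3, 3)), all(is.finite(M)))
  if (abs(M[3, 3]) < 1e-12 || abs(det(M)) < 1e-12)
    stop("transform matrix is singular or not normalizable")
  M <- M / M[3, 3]
  structure(list(matrix = M, inliers = inliers, model = model),
            class = "planar_transform")
}

#' @rdname planar_transform
#' @export
pt_identity <- function() planar_transform(diag(3), model = "identity")

#' @rdname planar_transform
#' @param dr,dc translation components (row, col) in pixels.
#' @export
pt_translation <- function(dr, dc) {
  M <- diag(3); M[1, 3] <- dr; M[2, 3] <- dc
  planar_transform(M, model = "translation")
}

#' Apply a planar transform to points
#'
#' @param tform a `planar_transform`.
#' @param pts n x 2 matrix of `c(row, col)` points.
#' @return n x 2 matrix of mapped points.
#' @export
pt_apply <- function(tform, pts) {
  pts <- matrix(pts, ncol = 2)
  H <- tform$matrix
  X <- cbind(pts, 1) %*% t(H)
  X[, 1:2, drop = FALSE] / X[, 3]
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("<planar_transform (%s)%s>\n", x$model,
              if (is.na(x$inliers)) "" else sprintf(", %d inliers", x$inliers)))
  print(round(x$matrix, 6))
  invisible(x)
}

# Normalized DLT homography fit (Hartley normalization), exact for >= 4
# noiseless correspondences.
fit_homography_dlt <- function(src, dst) {
  normalise <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)) + 1e-300)
    Tm <- rbind(c(sc, 0, -sc * mu[1]), c(0, sc, -sc * mu[2]), c(0, 0, 1))
    list(T = Tm, p = cbind(p, 1) %*% t(Tm))
  }
  ns <- normalise(src); nd <- normalise(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, ]; y <- nd$p[i, ]
    A[2 * i - 1, ] <- c(-x, 0, 0, 0, y[1] * x)
    A[2 * i, ] <- c(0, 0, 0, -x, y[2] * x)
  }
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

fit_affine_ls <- function(src, dst) {
  X <- cbind(src, 1)
  beta <- qr.solve(X, dst)            # 3 x 2
  M <- diag(3)
  M[1, 1:3] <- beta[c(1, 2, 3), 1]
  M[2, 1:3] <- beta[c(1, 2, 3), 2]
  M
}

#' Robust transform estimation from filtered matches
#'
#' Estimates the planar transform mapping candidate-frame coordinates to
#' reference coordinates with RANSAC: minimal samples are drawn, a model is
#' fitted (normalized DLT for homographies, least squares for affine, the
#' sample displacement for translations), inliers are counted against the
#' reprojection threshold, and the best consensus model is refitted on all
#' its inliers. Fully reproducible for a fixed `seed`.
#'
#' @param matches a `match_set` (after [filter_matches()]).
#' @param ref_kp,cand_kp the `keypoints` objects the matches index into.
#' @param model "homography" (needs >= 4 matches), "affine" (>= 3) or
#'   "translation" (>= 1).
#' @param threshold RANSAC reprojection threshold in pixels (default 1.0).
#' @param max_iterations RANSAC iteration cap (default 2000; terminates
#'   early once the consensus makes further improvement overwhelmingly
#'   unlikely).
#' @param seed RNG seed for the sampler (default 1).
#' @return a [planar_transform()] with its inlier count.
#' @export
estimate_transform <- function(matches, ref_kp, cand_kp,
                               model = c("homography", "affine", "translation"),
                               threshold = 1.0, max_iterations = 2000,
                               seed = 1L) {
  model <- match.arg(model)
  need <- switch(model, homography = 4L, affine = 3L, translation = 1L)
  if (nrow(matches) < need)
    stop(sprintf("degenerate input: %d matches but %s needs >= %d",
                 nrow(matches), model, need))
  dst <- as.matrix(ref_kp$keypoints[matches$ref_index, c("row", "col")])
  src <- as.matrix(cand_kp$keypoints[matches$cand_index, c("row", "col")])
  n <- nrow(src)
  fit <- function(idx) {
    switch(model,
           homography = tryCatch(fit_homography_dlt(src[idx, , drop = FALSE],
                                                    dst[idx, , drop = FALSE]),
                                 error = function(e) NULL),
           affine = tryCatch(fit_affine_ls(src[idx, , drop = FALSE],
                                           dst[idx, , drop = FALSE]),
                             error = function(e) NULL),
           translation = {
             t0 <- colMeans(dst[idx, , drop = FALSE] - src[idx, , drop = FALSE])
             M <- diag(3); M[1:2, 3] <- t0; M
           })
  }
  errs <- function(M) {
    X <- cbind(src, 1) %*% t(M)
    mapped <- X[, 1:2, drop = FALSE] / X[, 3]
    sqrt(rowSums((mapped - dst)^2))
  }
  best <- NULL; best_n <- -1L; best_err <- Inf
  with_seed(seed, {
    it <- 0L; needed_it <- max_iterations
    while (it < min(max_iterations, needed_it)) {
      it <- it + 1L
      idx <- if (n == need) seq_len(n) else sample.int(n, need)
      M <- fit(idx)
      if (is.null(M) || any(!is.finite(M))) next
      e <- errs(M)
      inl <- e < threshold
      ni <- sum(inl)
      me <- mean(e[inl])
      if (ni > best_n || (ni == best_n && me < best_err)) {
        best <- inl; best_n <- ni; best_err <- me
        w <- max(ni / n, 1e-6)
        needed_it <- ceiling(log(1e-4) / log(max(1 - w^need, 1e-12)))
      }
      if (n == need) break
    }
  })
  if (is.null(best) || best_n < need)
    stop("RANSAC failed to find a consensus transform")
  M <- fit(which(best))
  planar_transform(M, inliers = best_n, model = model)
}

#' Warp an image by a planar transform
#'
#' Resamples an image onto the reference grid by inverse mapping: each
#' output pixel is looked up at `T^{-1}(row, col)` in the source image with
#' bicubic (default) or bilinear interpolation. Out-of-bounds samples are
#' set to `fill` and flagged in the `mask` attribute.
#'
#' @param image numeric matrix.
#' @param tform a [planar_transform()] mapping image coordinates to
#'   reference coordinates.
#' @param out_shape `c(nrow, ncol)` of the output (default: input shape).
#' @param fill fill value for unmapped pixels (default 0).
#' @param method "bicubic" (default) or "bilinear".
#' @return warped matrix with logical attribute `mask` (TRUE where valid).
#' @export
warp <- function(image, tform, out_shape = dim(image), fill = 0,
                 method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  Minv <- solve(tform$matrix)
  if (!all(is.finite(Minv))) stop("transform is not invertible")
  g <- expand.grid(row = seq_len(out_shape[1]), col = seq_len(out_shape[2]))
  X <- cbind(g$row, g$col, 1) %*% t(Minv)
  r <- X[, 1] / X[, 3]; c <- X[, 2] / X[, 3]
  v <- if (method == "bicubic") bicubic_sample(image, r, c, NA_real_)
       else bilinear_sample(image, r, c, NA_real_)
  mask <- matrix(attr(v, "valid"), out_shape[1], out_shape[2])
  v[is.na(v)] <- fill
  out <- matrix(as.numeric(v), out_shape[1], out_shape[2])
  attr(out, "mask") <- mask
  out
}

#' Pre-align a stack of LR frames onto a reference frame
#'
#' Runs the feature pipeline (detect, match, geometric filtering, robust
#' estimation) for every frame against the chosen reference frame. The
#' reference gets the identity transform; a frame whose estimation fails
#' falls back to the identity with a warning (the sub-pixel optimizer can
#' absorb the residual shift).
#'
#' @param stack an [lr_stack()] with at least 2 frames.
#' @param reference index of the reference frame (default 1).
#' @param model transform model passed to [estimate_transform()]; use
#'   "translation" for pure-shift acquisitions.
#' @param options [feature_options()] for detection.
#' @param ratio,threshold,seed passed through to matching and RANSAC.
#' @param max_shift displacement prior passed to [filter_matches()]
#'   (default `Inf`).
#' @param verbose log per-frame inlier counts via `message()`.
#' @return list of [planar_transform()], one per frame.
#' @export
prealign_stack <- function(stack, reference = 1,
                           model = c("homography", "affine", "translation"),
                           options = feature_options(), ratio = 0.75,
                           threshold = 1.0, seed = 1L, max_shift = Inf,
                           verbose = FALSE) {
  stopifnot(inherits(stack, "lr_stack"))
  model <- match.arg(model)
  m <- length(stack$frames)
  if (m < 2) stop("pre-alignment needs at least 2 frames")
  ref_kp <- detect_features(stack$frames[[reference]], options)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    if (i == reference) { out[[i]] <- pt_identity(); next }
    tf <- tryCatch({
      kp <- detect_features(stack$frames[[i]], options)
      mt <- match_features(ref_kp, kp, ratio = ratio)
      mt <- suppressWarnings(filter_matches(mt, ref_kp, kp,
                                            max_shift = max_shift))
      estimate_transform(mt, ref_kp, kp, model = model,
                         threshold = threshold, seed = seed + i)
    }, error = function(e) e)
    if (inherits(tf, "error")) {
      warning(sprintf("frame %d: %s; falling back to identity", i,
                      conditionMessage(tf)))
      out[[i]] <- pt_identity()
    } else {
      if (verbose) message(sprintf("frame %d: %d inliers", i, tf$inliers))
      out[[i]] <- tf
    }
  }
  out
}

#' Write / read planar transforms as a plain-text sidecar
#'
#' One line per frame: the frame label followed by the 9 row-major entries
#' of the 3x3 matrix.
#'
#' @param transforms list of [planar_transform()].
#' @param path output text file.
#' @param labels frame labels (default `frame_001`, ...).
#' @return `write_transforms`: invisibly, `path`. `read_transforms`: list of
#'   transforms with `names` set to the labels.
#' @export
write_transforms <- function(transforms, path,
                             labels = sprintf("frame_%03d", seq_along(transforms))) {
  lines <- vapply(seq_along(transforms), function(i) {
    paste(c(labels[i], format(as.vector(t(transforms[[i]]$matrix)),
                              digits = 17)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    M <- matrix(as.numeric(tok[-1]), 3, 3, byrow = TRUE)
    planar_transform(M)
  })
  names(out) <- vapply(lines, function(ln) strsplit(trimws(ln), "\\s+")[[1]][1],
                       character(1))
  out
}
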