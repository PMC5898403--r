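# Multi-frame pixel super-resolution: shift-and-add fusion onto the HR
# grid, the variational energy (fidelity + sharpness), the continuous ant
# colony optimizer, and the top-level super_resolve() driver.

#' Energy parameters
#'
#' Weights of the two penalizer terms of the super-resolution energy
#' `E(I, L) = alpha * sum_i MSE(L_i, I) + sign * beta * LAPM(I) / npix`:
#' a data-fidelity term tying the fused HR hologram to every observed LR
#' frame, and a sharpness term scoring holographic propagation quality via
#' the sum-modified Laplacian. With the default `sharpness_sign = -1`,
#' minimizing E rewards sharpness.
#'
#' @param alpha fidelity weight, >= 0 (default 1).
#' @param beta sharpness weight, >= 0 (default 0.1; the per-pixel LAPM
#'   normalization puts both terms on comparable scales for typical
#'   unit-background holograms).
#' @param sharpness_sign -1 (default, sharper is better) or +1.
#' @param sampling how the HR image is compared against each LR frame:
#'   "point" (default) samples the fused HR bilinearly at each LR pixel's
#'   mapped position; "box" first box-filters the HR by the upsampling
#'   factor.
#' @return list of class `energy_params`.
#' @export
energy_params <- function(alpha = 1, beta = 0.1, sharpness_sign = -1,
                          sampling = c("point", "box")) {
  if (alpha < 0 || beta < 0) stop("weights must be non-negative")
  if (alpha == 0 && beta == 0) stop("alpha and beta must not both be zero")
  structure(list(alpha = alpha, beta = beta,
                 sharpness_sign = sharpness_sign,
                 sampling = match.arg(sampling)),
            class = "energy_params")
}

#' Continuous ant colony optimizer parameters
#'
#' @param archive_size solution archive size k (>= 2, default 30).
#' @param locality q, spread of the rank weights (default 0.1; small values
#'   concentrate sampling around the best archive members).
#' @param speed xi, convergence speed / deviation multiplier (default 0.85).
#' @param ants solutions constructed per iteration (default 2).
#' @param iterations iteration count (default 500).
#' @param seed RNG seed (default 1).
#' @return list of class `acor_params`.
#' @export
acor_params <- function(archive_size = 30, locality = 0.1, speed = 0.85,
                        ants = 2, iterations = 500, seed = 1L) {
  if (archive_size < 2) stop("`archive_size` must be >= 2")
  if (locality <= 0) stop("`locality` must be positive")
  if (speed <= 0) stop("`speed` must be positive")
  if (iterations < 1 || ants < 1) stop("evaluation budget must be positive")
  structure(list(archive_size = as.integer(archive_size), locality = locality,
                 speed = speed, ants = as.integer(ants),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "acor_params")
}

# Mapped HR-grid coordinates of every pixel of one LR frame: the frame's
# pixel centres are sent through its planar transform (frame -> reference LR
# coordinates), shifted by the sub-pixel offset, and scaled onto the HR grid
# where LR pixel centre u maps to factor * (u - 1) + (factor + 1) / 2.
frame_hr_coords <- function(lr_dim, tform, offset, factor) {
  g <- expand.grid(row = seq_len(lr_dim[1]), col = seq_len(lr_dim[2]))
  if (is.null(tform) || identical(tform$model, "identity")) {
    ref <- cbind(g$row, g$col)
  } else {
    ref <- pt_apply(tform, cbind(g$row, g$col))
  }
  ref <- ref + matrix(offset, nrow(ref), 2, byrow = TRUE)
  factor * (ref - 1) + (factor + 1) / 2
}

# Bilinear splat of one frame onto HR accumulators; returns the sparse
# contribution (flat indices, weights, weighted values).
frame_contribution <- function(frame, hr_coords, hr_dim) {
  r <- hr_coords[, 1]; c <- hr_coords[, 2]
  v <- as.numeric(frame)
  keep <- r >= 1 & r <= hr_dim[1] & c >= 1 & c <= hr_dim[2]
  r <- r[keep]; c <- c[keep]; v <- v[keep]
  r0 <- pmin(pmax(floor(r), 1), hr_dim[1] - 1L)
  c0 <- pmin(pmax(floor(c), 1), hr_dim[2] - 1L)
  fr <- r - r0; fc <- c - c0
  nr <- hr_dim[1]
  i00 <- (c0 - 1) * nr + r0
  idx <- c(i00, i00 + 1, i00 + nr, i00 + nr + 1)
  w <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
  list(idx = idx, w = w, wv = w * rep(v, 4))
}

add_contribution <- function(num, den, contrib, sign = 1) {
  ii <- unique(contrib$idx)  # first-appearance order, as rowsum(reorder=FALSE)
  s <- rowsum(cbind(contrib$wv, contrib$w), contrib$idx, reorder = FALSE)
  num[ii] <- num[ii] + sign * s[, 1]
  den[ii] <- den[ii] + sign * s[, 2]
  list(num = num, den = den)
}

#' Fuse LR frames into a high-resolution image (shift-and-add)
#'
#' Each LR pixel is mapped through its frame's planar transform plus
#' sub-pixel offset onto the HR grid (`factor` times finer) and splatted
#' with bilinear weights; the HR image is the weighted mean at each cell.
#' Cells receiving no weight are filled by iterated neighbourhood
#' interpolation, so the output has no undefined values.
#'
#' @param stack an [lr_stack()].
#' @param transforms list of [planar_transform()] per frame, or NULL for
#'   identities.
#' @param offsets m x 2 matrix of per-frame `(dr, dc)` corrections in LR
#'   pixels, or NULL for zeros.
#' @param factor integer upsampling factor >= 1.
#' @return numeric matrix of dimension `factor * dim(frame)` with attribute
#'   `coverage` (logical matrix: TRUE where observed, FALSE where
#'   interpolated).
#' @export
fuse <- function(stack, transforms = NULL, offsets = NULL, factor = 4L) {
  stopifnot(inherits(stack, "lr_stack"))
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be >= 1")
  m <- length(stack$frames)
  lr_dim <- dim(stack$frames[[1]])
  hr_dim <- lr_dim * factor
  if (is.null(offsets)) offsets <- matrix(0, m, 2)
  num <- numeric(prod(hr_dim)); den <- numeric(prod(hr_dim))
  for (i in seq_len(m)) {
    tf <- if (is.null(transforms)) NULL else transforms[[i]]
    hc <- frame_hr_coords(lr_dim, tf, offsets[i, ], factor)
    acc <- add_contribution(num, den, frame_contribution(stack$frames[[i]], hc, hr_dim))
    num <- acc$num; den <- acc$den
  }
  covered <- den > 1e-9
  vals <- numeric(prod(hr_dim))
  vals[covered] <- num[covered] / den[covered]
  I <- matrix(vals, hr_dim[1], hr_dim[2])
  I <- fill_holes(I, matrix(covered, hr_dim[1], hr_dim[2]))
  attr(I, "coverage") <- matrix(covered, hr_dim[1], hr_dim[2])
  I
}

# Fidelity residual of one frame against an HR estimate: mean squared
# difference between the frame and the HR image sampled (point or box) at
# the frame's mapped positions. Invalid samples (outside the HR grid or on
# uncovered cells) are excluded.
frame_fidelity <- function(frame, hr, hr_coords, factor, sampling = "point",
                           hr_box = NULL) {
  img <- if (sampling == "box") hr_box %||% hr_box_filter(hr, factor) else hr
  s <- bilinear_sample(img, hr_coords[, 1], hr_coords[, 2])
  ok <- attr(s, "valid")
  if (!any(ok)) return(NA_real_)
  mean((as.numeric(frame)[ok] - s[ok])^2)
}

# "Same"-size box filter of the HR image over factor x factor windows
# (separable moving average), used by the "box" fidelity sampling mode.
hr_box_filter <- function(hr, factor) {
  if (factor == 1) return(hr)
  k <- matrix(1 / factor, factor, 1)
  if (factor %% 2 == 0) k <- rbind(k, 0)  # odd-size kernel for conv2_same
  conv2_same(conv2_same(hr, k), t(k))
}

#' Super-resolution energy of a candidate offset configuration
#'
#' Fuses the stack at the given offsets and evaluates
#' `E = alpha * sum_i MSE_i + sign * beta * LAPM(I) / npix`, where `MSE_i`
#' compares frame i with the fused HR image re-sampled on that frame's
#' grid. This is the objective the sub-pixel optimizer minimizes.
#'
#' @param offsets m x 2 matrix of per-frame offsets (reference row zero).
#' @param stack an [lr_stack()].
#' @param transforms per-frame transforms or NULL.
#' @param eparams an [energy_params()].
#' @param factor upsampling factor.
#' @param hr optionally, a pre-computed fused image for these offsets.
#' @return finite scalar energy with attribute `terms`
#'   (`c(fidelity, sharpness)`).
#' @export
sr_energy <- function(offsets, stack, transforms = NULL,
                      eparams = energy_params(), factor = 4L, hr = NULL) {
  stopifnot(inherits(stack, "lr_stack"))
  m <- length(stack$frames)
  offsets <- matrix(offsets, ncol = 2)
  if (nrow(offsets) != m) stop("`offsets` must have one row per frame")
  if (is.null(hr)) hr <- fuse(stack, transforms, offsets, factor)
  lr_dim <- dim(stack$frames[[1]])
  hr_box <- if (eparams$sampling == "box") hr_box_filter(hr, factor) else NULL
  fid <- 0
  if (eparams$alpha > 0) {
    for (i in seq_len(m)) {
      tf <- if (is.null(transforms)) NULL else transforms[[i]]
      hc <- frame_hr_coords(lr_dim, tf, offsets[i, ], factor)
      fi <- frame_fidelity(stack$frames[[i]], hr, hc, factor,
                           sampling = eparams$sampling, hr_box = hr_box)
      if (!is.finite(fi))
        stop(sprintf("non-finite fidelity residual for frame %d", i))
      fid <- fid + fi
    }
    fid <- eparams$alpha * fid
  }
  sharp <- 0
  if (eparams$beta > 0)
    sharp <- eparams$sharpness_sign * eparams$beta * lapm(hr) / length(hr)
  E <- fid + sharp
  if (!is.finite(E)) stop("non-finite energy")
  attr(E, "terms") <- c(fidelity = fid, sharpness = sharp)
  E
}

#' Continuous ant colony optimization (solution-archive ACO)
#'
#' Minimizes a continuous objective over a box by the solution-archive
#' algorithm: an archive of k solutions is kept sorted by objective value;
#' each iteration every ant picks a guide solution with rank-based Gaussian
#' weights (`locality` q) and samples each coordinate from a normal centred
#' on the guide with deviation `speed * mean |archive - guide|`; the
#' combined pool is truncated back to the k best. Fully reproducible under
#' a fixed seed.
#'
#' @param objective function of a numeric vector, finite on the box.
#' @param lower,upper numeric bounds (finite, `lower < upper`).
#' @param params an [acor_params()].
#' @param init optional matrix of initial solutions (rows) to seed the
#'   archive, e.g. a pre-alignment guess.
#' @return list with `par` (best point), `value` (best objective), `trace`
#'   (best-so-far value per iteration, non-increasing) and `evaluations`.
#' @examples
#' res <- acor_minimize(function(x) sum(x^2), rep(-5, 4), rep(5, 4),
#'                      acor_params(iterations = 100, seed = 7))
#' res$value
#' @export
acor_minimize <- function(objective, lower, upper, params = acor_params(),
                          init = NULL) {
  stopifnot(inherits(params, "acor_params"))
  n <- length(lower)
  if (length(upper) != n || any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper")
  k <- params$archive_size
  q <- params$locality; xi <- params$speed
  evals <- 0L
  with_seed(params$seed, {
    A <- matrix(stats::runif(k * n, rep(lower, each = k), rep(upper, each = k)),
                k, n)
    if (!is.null(init)) {
      init <- matrix(init, ncol = n)
      ni <- min(nrow(init), k)
      A[seq_len(ni), ] <- pmin(pmax(init[seq_len(ni), , drop = FALSE],
                                    rep(lower, each = ni)),
                               rep(upper, each = ni))
    }
    f <- apply(A, 1, objective)
    evals <- evals + k
    ord <- order(f)
    A <- A[ord, , drop = FALSE]; f <- f[ord]
    w <- exp(-(seq_len(k) - 1)^2 / (2 * q^2 * k^2))
    w <- w / sum(w)
    trace <- numeric(params$iterations)
    for (it in seq_len(params$iterations)) {
      newA <- matrix(0, params$ants, n)
      for (a in seq_len(params$ants)) {
        j <- sample.int(k, 1, prob = w)
        sd_j <- xi * colSums(abs(A - matrix(A[j, ], k, n, byrow = TRUE))) / (k - 1)
        x <- stats::rnorm(n, A[j, ], pmax(sd_j, 1e-12))
        newA[a, ] <- pmin(pmax(x, lower), upper)
      }
      newf <- apply(newA, 1, objective)
      evals <- evals + params$ants
      A <- rbind(A, newA); f <- c(f, newf)
      ord <- order(f)[seq_len(k)]
      A <- A[ord, , drop = FALSE]; f <- f[ord]
      trace[it] <- f[1]
    }
    list(par = A[1, ], value = f[1], trace = cummin(trace), evaluations = evals)
  })
}

#' Super-resolve an LR hologram stack
#'
#' Refines per-frame sub-pixel offsets (corrections added on top of the
#' feature pre-alignment transforms; the reference frame is pinned at zero)
#' by minimizing the super-resolution energy with the continuous ant colony
#' optimizer, then fuses the stack at the best offsets.
#'
#' Two search strategies are available. `"sweep"` (default) performs cyclic
#' block-coordinate refinement: each frame's 2-D offset is optimized by
#' ACO against the leave-one-out fused estimate of all other frames, over
#' several sweeps; the full energy is tracked after every block and the
#' best-energy configuration is returned. `"joint"` runs a single ACO over
#' all `2(m-1)` variables at once (practical only for small m).
#'
#' @param stack an [lr_stack()], m >= 2 for meaningful super-resolution
#'   (a single frame is upsampled with a warning).
#' @param transforms pre-alignment transforms from [prealign_stack()], or
#'   NULL for identities.
#' @param eparams an [energy_params()].
#' @param aparams an [acor_params()]; in `"sweep"` mode it parameterizes
#'   each per-frame 2-D search (default: archive 10, 30 iterations).
#' @param factor integer upsampling factor (default 4).
#' @param strategy "sweep" or "joint".
#' @param sweeps number of block-coordinate sweeps (default 3).
#' @param bound offset search half-width in LR pixels around the
#'   pre-alignment (default 2).
#' @param reference reference frame index whose offset stays zero
#'   (default 1).
#' @return object of class `hr_result`: list with `hr` (fused HR matrix),
#'   `offsets` (m x 2), `energy`, `trace` (non-increasing best-so-far),
#'   `transforms`, `factor`, `strategy`, `evaluations`.
#' @export
super_resolve <- function(stack, transforms = NULL,
                          eparams = energy_params(),
                          aparams = acor_params(archive_size = 10,
                                                iterations = 30),
                          factor = 4L, strategy = c("sweep", "joint"),
                          sweeps = 3L, bound = 2, reference = 1L) {
  stopifnot(inherits(stack, "lr_stack"))
  strategy <- match.arg(strategy)
  factor <- as.integer(factor)
  m <- length(stack$frames)
  lr_dim <- dim(stack$frames[[1]])
  if (m < 2) {
    warning("single-frame stack: returning interpolated upsampling, no SR")
    g <- expand.grid(r = (seq_len(lr_dim[1] * factor) - (factor + 1) / 2) / factor + 1,
                     c = (seq_len(lr_dim[2] * factor) - (factor + 1) / 2) / factor + 1)
    hr <- matrix(bicubic_sample(stack$frames[[1]], g$r, g$c, 0),
                 lr_dim[1] * factor, lr_dim[2] * factor)
    return(structure(list(hr = hr, offsets = matrix(0, 1, 2),
                          energy = NA_real_, trace = numeric(0),
                          transforms = transforms, factor = factor,
                          strategy = strategy, evaluations = 0L),
                     class = "hr_result"))
  }
  if (is.null(transforms)) transforms <- replicate(m, pt_identity(), simplify = FALSE)
  offsets <- matrix(0, m, 2)
  hr_dim <- lr_dim * factor

  if (strategy == "joint") {
    free <- setdiff(seq_len(m), reference)
    obj <- function(x) {
      off <- matrix(0, m, 2)
      off[free, ] <- matrix(x, ncol = 2)
      as.numeric(sr_energy(off, stack, transforms, eparams, factor))
    }
    nvar <- 2 * (m - 1)
    res <- acor_minimize(obj, rep(-bound, nvar), rep(bound, nvar),
                         params = aparams, init = rep(0, nvar))
    offsets[free, ] <- matrix(res$par, ncol = 2)
    hr <- fuse(stack, transforms, offsets, factor)
    E <- sr_energy(offsets, stack, transforms, eparams, factor, hr = hr)
    return(structure(list(hr = hr, offsets = offsets, energy = as.numeric(E),
                          trace = res$trace, transforms = transforms,
                          factor = factor, strategy = strategy,
                          evaluations = res$evaluations),
                     class = "hr_result"))
  }

  # -- sweep (block-coordinate) strategy --------------------------------
  coords <- lapply(seq_len(m), function(i)
    frame_hr_coords(lr_dim, transforms[[i]], offsets[i, ], factor))
  contribs <- lapply(seq_len(m), function(i)
    frame_contribution(stack$frames[[i]], coords[[i]], hr_dim))
  num <- numeric(prod(hr_dim)); den <- numeric(prod(hr_dim))
  for (i in seq_len(m)) {
    acc <- add_contribution(num, den, contribs[[i]])
    num <- acc$num; den <- acc$den
  }
  base_coords <- lapply(seq_len(m), function(i)
    frame_hr_coords(lr_dim, transforms[[i]], c(0, 0), factor))
  # full energy from the maintained accumulators (point-sampling fast path)
  full_energy <- function(off, num, den) {
    if (eparams$sampling != "point")
      return(as.numeric(sr_energy(off, stack, transforms, eparams, factor)))
    covered <- den > 1e-9
    vals <- numeric(prod(hr_dim)); vals[covered] <- num[covered] / den[covered]
    I <- fill_holes(matrix(vals, hr_dim[1], hr_dim[2]),
                    matrix(covered, hr_dim[1], hr_dim[2]))
    fid <- 0
    if (eparams$alpha > 0) {
      for (i in seq_len(m)) {
        s <- bilinear_sample(I, base_coords[[i]][, 1] + factor * off[i, 1],
                             base_coords[[i]][, 2] + factor * off[i, 2])
        ok <- attr(s, "valid")
        fid <- fid + mean((as.numeric(stack$frames[[i]])[ok] - s[ok])^2)
      }
      fid <- eparams$alpha * fid
    }
    sharp <- if (eparams$beta > 0)
      eparams$sharpness_sign * eparams$beta * lapm(I) / length(I) else 0
    fid + sharp
  }
  trace <- c()
  best_E <- full_energy(offsets, num, den)
  best_off <- offsets
  evals <- 0L
  for (sw in seq_len(sweeps)) {
    for (i in setdiff(seq_len(m), reference)) {
      acc <- add_contribution(num, den, contribs[[i]], sign = -1)
      num_i <- acc$num; den_i <- acc$den
      covered <- den_i > 1e-9
      vals <- numeric(prod(hr_dim)); vals[covered] <- num_i[covered] / den_i[covered]
      I_minus <- matrix(vals, hr_dim[1], hr_dim[2])
      I_minus[!covered] <- NA_real_
      fi <- as.numeric(stack$frames[[i]])
      bc <- base_coords[[i]]
      obj <- function(o) {
        s <- bilinear_sample(I_minus, bc[, 1] + factor * o[1],
                             bc[, 2] + factor * o[2])
        ok <- attr(s, "valid") & !is.na(s)
        if (sum(ok) < length(fi) / 2) return(1e6)
        mean((fi[ok] - s[ok])^2)
      }
      res <- acor_minimize(obj, c(-bound, -bound), c(bound, bound),
                           params = acor_params(
                             archive_size = aparams$archive_size,
                             locality = aparams$locality,
                             speed = aparams$speed, ants = aparams$ants,
                             iterations = aparams$iterations,
                             seed = aparams$seed + 1009L * sw + i),
                           init = rbind(offsets[i, ]))
      evals <- evals + res$evaluations
      offsets[i, ] <- res$par
      coords[[i]] <- frame_hr_coords(lr_dim, transforms[[i]], offsets[i, ], factor)
      contribs[[i]] <- frame_contribution(stack$frames[[i]], coords[[i]], hr_dim)
      acc <- add_contribution(num_i, den_i, contribs[[i]])
      num <- acc$num; den <- acc$den
      E <- full_energy(offsets, num, den)
      if (E < best_E) { best_E <- E; best_off <- offsets }
      trace <- c(trace, min(E, best_E))
    }
  }
  offsets <- best_off
  hr <- fuse(stack, transforms, offsets, factor)
  E <- sr_energy(offsets, stack, transforms, eparams, factor, hr = hr)
  structure(list(hr = hr, offsets = offsets, energy = as.numeric(E),
                 trace = cummin(trace), transforms = transforms,
                 factor = factor, strategy = strategy, evaluations = evals),
            class = "hr_result")
}

#' @export
print.hr_result <- function(x, ...) {
  cat(sprintf("<hr_result: %d x %d HR image, factor %d, energy %.6g, %s strategy>\n",
              nrow(x$hr), ncol(x$hr), x$factor, x$energy, x$strategy))
  invisible(x)
}
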