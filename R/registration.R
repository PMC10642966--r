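# Dimension-generic diffeomorphic registration: stationary-velocity greedy
# demons on multi-channel images, transform algebra (exponentiation,
# composition, inversion, Jacobians), and iterative groupwise template
# building. The same engine drives the 2D unfolded and the 3D volumetric
# control registrations.

#' Registration parameters
#'
#' @param levels number of pyramid levels (coarse-to-fine, downsampling
#'   factors 2^(levels-1) ... 1).
#' @param iterations per-level iteration caps, coarse to fine.
#' @param step_size gradient step scaling for the demons update.
#' @param fluid_sigma Gaussian smoothing (px) of each update field.
#' @param elastic_sigma Gaussian smoothing (px) of the accumulated velocity.
#' @param conv_window stop a level when the best similarity has not improved
#'   for this many iterations.
#' @return a `RegParams` list.
#' @export
regParams <- function(levels = 3L, iterations = c(100L, 100L, 50L),
                      step_size = 1.0, fluid_sigma = 2.0,
                      elastic_sigma = 1.0, conv_window = 10L) {
  stopifnot(levels >= 1, length(iterations) == levels,
            fluid_sigma >= 0, elastic_sigma >= 0)
  structure(list(levels = as.integer(levels),
                 iterations = as.integer(iterations),
                 step_size = step_size, fluid_sigma = fluid_sigma,
                 elastic_sigma = elastic_sigma,
                 conv_window = as.integer(conv_window)),
            class = "RegParams")
}

# ---------------------------------------------------------------------------
# displacement-field primitives (dimension-generic, components in px)

gridPoints <- function(shape) {
  nd <- length(shape)
  if (nd == 2) {
    cbind(rep(seq_len(shape[1]) - 1, shape[2]),
          rep(seq_len(shape[2]) - 1, each = shape[1]))
  } else {
    g <- expand.grid(x = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
                     z = seq_len(shape[3]) - 1)
    as.matrix(g)
  }
}

# warp points x + u(x); u given as list of component arrays
warpPoints <- function(disp, shape, pts = gridPoints(shape)) {
  pts + vapply(disp, function(u) as.numeric(u), numeric(prod(shape)))
}

# sample a displacement field at arbitrary points (linear, clamped)
sampleDisp <- function(disp, shape, pts) {
  vapply(disp, function(u) cpp_interp_linear(as.numeric(u), shape, pts),
         numeric(nrow(pts)))
}

# compose displacements: result u_c of T_b(T_a(x)): u_c = u_a + u_b(x + u_a)
composeDisp <- function(ua, ub, shape) {
  uc <- cpp_compose_disp(lapply(ua, as.numeric), lapply(ub, as.numeric),
                         shape)
  lapply(uc, array, dim = shape)
}

# exponentiate a stationary velocity field by scaling and squaring;
# `target` is the max per-step displacement (px): emitted transforms use a
# fine step, the inner demons loop a coarser (cheaper) one
expVelocity <- function(vel, shape, target = 0.25) {
  u <- cpp_exp_velocity(lapply(vel, as.numeric), shape, target)
  lapply(u, array, dim = shape)
}

makeDiffeo <- function(vel = NULL, disp = NULL, shape, spacing) {
  shape <- as.integer(shape)
  if (is.null(disp)) {
    disp <- expVelocity(vel, shape)
    new("DiffeoTransform", velocity = vel, disp = disp, shape = shape,
        spacing = spacing, kind = "svf")
  } else {
    new("DiffeoTransform", velocity = list(), disp = disp, shape = shape,
        spacing = spacing, kind = "disp")
  }
}

#' Identity transform on a grid
#' @param shape grid shape (2D or 3D).
#' @param spacing physical pixel spacing (mm).
#' @return a [DiffeoTransform-class].
#' @export
identityTransform <- function(shape, spacing = gridSpacing(shape)) {
  shape <- as.integer(shape)
  zero <- lapply(seq_along(shape), function(i) array(0, shape))
  new("DiffeoTransform", velocity = zero, disp = zero, shape = shape,
      spacing = spacing, kind = "svf")
}

#' Compose two transforms
#'
#' `composeTransforms(a, b)` returns the transform that applies `a`'s
#' coordinate map first and `b`'s second: T(x) = T_b(T_a(x)). Both transforms
#' must live on the same grid.
#'
#' @param a,b [DiffeoTransform-class] objects on a common domain.
#' @return a displacement-parameterized [DiffeoTransform-class].
#' @export
composeTransforms <- function(a, b) {
  if (!identical(a@shape, b@shape))
    stop("domain mismatch: ", paste(a@shape, collapse = "x"), " vs ",
         paste(b@shape, collapse = "x"))
  makeDiffeo(disp = composeDisp(a@disp, b@disp, a@shape), shape = a@shape,
             spacing = a@spacing)
}

#' Invert a transform
#'
#' Stationary-velocity transforms are inverted exactly by negating the
#' velocity; displacement-parameterized transforms by 20 fixed-point
#' iterations of u_inv(x) = -u(x + u_inv(x)).
#'
#' @param t a [DiffeoTransform-class].
#' @return the inverse [DiffeoTransform-class].
#' @export
invertTransform <- function(t) {
  if (t@kind == "svf" && length(t@velocity))
    return(makeDiffeo(vel = lapply(t@velocity, function(v) -v),
                      shape = t@shape, spacing = t@spacing))
  shape <- t@shape
  uinv <- cpp_invert_disp(lapply(t@disp, as.numeric), shape, 20L)
  makeDiffeo(disp = lapply(uinv, array, dim = shape), shape = shape,
             spacing = t@spacing)
}

#' Apply a transform to an image
#'
#' Resamples `image` through the transform (pull-back): out(x) =
#' image(x + u(x)). Out-of-domain lookups clamp to the rectangle (no wrap).
#' Label images must use nearest-neighbour interpolation; requesting linear
#' interpolation for an integer matrix is an error.
#'
#' @param image a numeric matrix/array on the transform's grid, or an
#'   [UnfoldedMap-class].
#' @param t a [DiffeoTransform-class].
#' @param interp "linear" or "nearest".
#' @return the warped image, same type as the input.
#' @export
applyTransform <- function(image, t, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  um <- NULL
  if (is(image, "UnfoldedMap")) {
    um <- image
    image <- image@values
  }
  if (!identical(as.integer(dim(image)), t@shape))
    stop("image shape does not match transform domain")
  if (is.integer(image) && interp == "linear")
    stop("linear interpolation requested for an integer label image; ",
         "use interp = 'nearest'")
  out <- cpp_warp(as.numeric(image), t@shape, lapply(t@disp, as.numeric),
                  if (interp == "linear") 1L else 0L)
  out <- array(out, dim(image))
  if (is.integer(image)) out <- array(as.integer(round(out)), dim(image))
  if (!is.null(um)) {
    um@values <- matrix(out, nrow(um@values), ncol(um@values))
    return(um)
  }
  out
}

#' Jacobian determinant of a transform
#'
#' Central-difference Jacobian of the forward map x + u(x). Values near 1
#' indicate little local area/volume change; positivity everywhere certifies
#' the transform preserves topology.
#'
#' @param t a [DiffeoTransform-class].
#' @return an [UnfoldedMap-class] (2D) or array (3D) of determinants.
#' @export
jacobianDeterminant <- function(t) {
  shape <- t@shape
  nd <- length(shape)
  J <- vector("list", nd * nd)
  for (i in seq_len(nd)) {
    u <- t@disp[[i]]
    for (j in seq_len(nd)) {
      up <- shiftArray(u, j, 1)
      dn <- shiftArray(u, j, -1)
      # one-sided differences at the edges (shiftArray replicates)
      denom <- array(2, dim(u))
      idx <- slice.index(u, j)
      denom[idx == 1 | idx == shape[j]] <- 1
      J[[(i - 1) * nd + j]] <- (up - dn) / denom + (i == j)
    }
  }
  det <- if (nd == 2) {
    J[[1]] * J[[4]] - J[[2]] * J[[3]]
  } else {
    J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
      J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
      J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  }
  if (nd == 2)
    unfoldedMap(matrix(det, shape[1], shape[2]), channel = "jacobian",
                units = "", extent = t@spacing * shape)
  else det
}

# ---------------------------------------------------------------------------
# multiresolution pyramid helpers

downsampleImage <- function(img, factor) {
  if (factor == 1) return(img)
  d <- dim(img)
  sm <- array(cpp_gauss_smooth(as.numeric(img), d, rep(factor / 2, length(d))),
              d)
  idx <- lapply(d, function(n) unique(pmin(n, seq(1, n, by = factor))))
  do.call(`[`, c(list(sm), idx))
}

upsampleVelocity <- function(vel, from_shape, to_shape) {
  scl <- to_shape / from_shape
  pts <- sweep(gridPoints(to_shape), 2, scl, `/`)
  lapply(seq_along(vel), function(i)
    array(cpp_interp_linear(as.numeric(vel[[i]]), from_shape, pts) * scl[i],
          to_shape))
}

# ---------------------------------------------------------------------------

#' Multi-channel diffeomorphic registration
#'
#' Greedy stationary-velocity demons on the mean per-channel SSD of two
#' feature stacks (channels are expected to be standardized so equal
#' weighting is meaningful). Each iteration computes a demons force from
#' every channel, averages them, smooths the update with `fluid_sigma`,
#' accumulates it into the velocity, smooths the velocity with
#' `elastic_sigma`, and exponentiates by scaling-and-squaring. Sampling
#' clamps at the rectangle edges: the unfolded space has four true borders
#' and no wrap-around.
#'
#' @param fixed,moving [FeatureStack-class] objects (or plain named lists of
#'   arrays) with identical shapes and channel sets. Arrays may be 2D or 3D.
#' @param params a [regParams()] list.
#' @param verbose print per-level convergence summaries.
#' @return a [DiffeoTransform-class] mapping fixed-grid coordinates to
#'   moving-grid coordinates (pull-back convention), with its stationary
#'   velocity retained.
#' @export
registerMultichannel <- function(fixed, moving, params = regParams(),
                                 verbose = FALSE) {
  fch <- if (is(fixed, "FeatureStack")) fixed@channels else fixed
  mch <- if (is(moving, "FeatureStack")) moving@channels else moving
  spacing <- if (is(fixed, "FeatureStack")) fixed@spacing else
    rep(1, length(dim(fch[[1]])))
  if (!identical(sort(names(fch)), sort(names(mch))))
    stop("channel mismatch: fixed has [",
         paste(names(fch), collapse = ","), "], moving has [",
         paste(names(mch), collapse = ","), "]")
  mch <- mch[names(fch)]
  for (nm in names(fch)) {
    if (!identical(dim(fch[[nm]]), dim(mch[[nm]])))
      stop("shape mismatch in channel ", nm)
    if (all(!is.finite(fch[[nm]])) || all(!is.finite(mch[[nm]])))
      stop("channel ", nm, " contains no finite values")
  }
  # NaN-free copies (clamped sampling assumes finite arrays)
  fch <- lapply(fch, function(a) { a[!is.finite(a)] <- 0; a })
  mch <- lapply(mch, function(a) { a[!is.finite(a)] <- 0; a })
  shape <- as.integer(dim(fch[[1]]))
  nd <- length(shape)
  factors <- 2^((params$levels - 1):0)
  vel <- NULL
  prev_shape <- NULL
  for (lev in seq_len(params$levels)) {
    f <- factors[lev]
    flev <- lapply(fch, downsampleImage, factor = f)
    mlev <- lapply(mch, downsampleImage, factor = f)
    lshape <- as.integer(dim(flev[[1]]))
    vel <- if (is.null(vel))
      lapply(seq_len(nd), function(i) array(0, lshape))
    else upsampleVelocity(vel, prev_shape, lshape)
    vel <- runDemonsLevel(flev, mlev, vel, lshape, params, verbose, lev)
    prev_shape <- lshape
  }
  makeDiffeo(vel = vel, shape = shape, spacing = spacing)
}

runDemonsLevel <- function(flev, mlev, vel, shape, params, verbose, lev) {
  nd <- length(shape)
  npix <- prod(shape)
  best_ssd <- Inf
  best_vel <- vel
  since_best <- 0L
  consec_up <- 0L
  last_ssd <- Inf
  for (it in seq_len(params$iterations[lev])) {
    u <- expVelocity(vel, shape, target = 0.5)
    force <- lapply(seq_len(nd), function(i) numeric(npix))
    ssd <- 0
    for (ch in seq_along(flev)) {
      mw <- array(cpp_warp(as.numeric(mlev[[ch]]), shape,
                           lapply(u, as.numeric), 1L), shape)
      diffim <- flev[[ch]] - mw
      ssd <- ssd + mean(diffim^2)
      g <- lapply(seq_len(nd), function(ax)
        (shiftArray(mw, ax, 1) - shiftArray(mw, ax, -1)) / 2)
      g2 <- Reduce(`+`, lapply(g, function(x) x^2))
      denom <- g2 + diffim^2
      w <- ifelse(denom > 1e-9, diffim / denom, 0)
      for (i in seq_len(nd))
        force[[i]] <- force[[i]] + as.numeric(w * g[[i]])
    }
    ssd <- ssd / length(flev)
    if (ssd >= last_ssd) consec_up <- consec_up + 1L else consec_up <- 0L
    if (consec_up >= 20L)
      stop(sprintf("registration diverging at level %d, iteration %d (SSD %.4g)",
                   lev, it, ssd))
    last_ssd <- ssd
    if (ssd < best_ssd - 1e-12) {
      best_ssd <- ssd
      best_vel <- vel
      since_best <- 0L
    } else since_best <- since_best + 1L
    if (since_best >= params$conv_window) break
    force <- lapply(force, function(fc)
      array(cpp_box_smooth(fc / length(flev), shape,
                           rep(params$fluid_sigma, nd)), shape))
    vel <- lapply(seq_len(nd), function(i)
      array(cpp_box_smooth(as.numeric(vel[[i]] +
                                        params$step_size * force[[i]]),
                           shape, rep(params$elastic_sigma, nd)), shape))
  }
  if (verbose)
    message(sprintf("  level %d: best SSD %.5g", lev, best_ssd))
  best_vel
}

# ---------------------------------------------------------------------------

#' Iterative groupwise template building
#'
#' Builds an unbiased average template: iteration 0 takes the arithmetic
#' mean of the stacks; each subsequent iteration registers every stack to
#' the current template, averages the warped stacks, and applies the inverse
#' of the mean displacement to the average (the shape update) so the
#' template stays centred in the cohort. Repeated `n_iter` times (default
#' 4), with each pass sharpening the template.
#'
#' @param stacks list of >= 2 [FeatureStack-class] objects on a common grid.
#' @param n_iter number of template refinement passes.
#' @param params a [regParams()] list.
#' @param verbose print progress.
#' @return a `TemplateResult` list: `template` ([FeatureStack-class]),
#'   `transforms` (per-sample [DiffeoTransform-class], mapping template-grid
#'   coordinates to sample coordinates), and `history` (mean SSD per
#'   iteration).
#' @export
buildTemplate <- function(stacks, n_iter = 4L, params = regParams(),
                          verbose = FALSE) {
  stopifnot(length(stacks) >= 2)
  chans <- lapply(stacks, function(s)
    if (is(s, "FeatureStack")) s@channels else s)
  shape <- as.integer(dim(chans[[1]][[1]]))
  nd <- length(shape)
  spacing <- if (is(stacks[[1]], "FeatureStack")) stacks[[1]]@spacing
  else rep(1, nd)
  nms <- names(chans[[1]])
  avgChannels <- function(lst) {
    out <- lapply(nms, function(nm)
      Reduce(`+`, lapply(lst, `[[`, nm)) / length(lst))
    names(out) <- nms
    out
  }
  template <- avgChannels(chans)
  transforms <- NULL
  history <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    transforms <- vector("list", length(chans))
    warped <- vector("list", length(chans))
    for (s in seq_along(chans)) {
      t_s <- tryCatch(
        registerMultichannel(template, chans[[s]], params),
        error = function(e)
          stop(sprintf("template iteration %d: registration of sample %d failed: %s",
                       it, s, conditionMessage(e))))
      transforms[[s]] <- t_s
      warped[[s]] <- lapply(chans[[s]], applyTransform, t = t_s,
                            interp = "linear")
    }
    avg <- avgChannels(warped)
    history[it] <- mean(vapply(seq_along(chans), function(s)
      mean(vapply(nms, function(nm)
        mean((warped[[s]][[nm]] - avg[[nm]])^2), numeric(1))), numeric(1)))
    # shape update: recentre the template by the inverse mean displacement
    mean_disp <- lapply(seq_len(nd), function(i)
      Reduce(`+`, lapply(transforms, function(t) t@disp[[i]])) /
        length(transforms))
    psi <- invertTransform(makeDiffeo(disp = mean_disp, shape = shape,
                                      spacing = spacing))
    template <- lapply(avg, applyTransform, t = psi, interp = "linear")
    if (it == n_iter)
      transforms <- lapply(transforms, function(t) composeTransforms(psi, t))
    if (verbose)
      message(sprintf("template iteration %d: mean cross-sample variance %.5g",
                      it, history[it]))
  }
  tmpl_stack <- new("FeatureStack", channels = template,
                    standardization = data.frame(channel = character(),
                                                 mean = numeric(),
                                                 sd = numeric()),
                    spacing = spacing)
  structure(list(template = tmpl_stack, transforms = transforms,
                 history = history),
            class = "TemplateResult")
}

# ---------------------------------------------------------------------------

#' Moment-based rigid initialization of binary masks
#'
#' Two-moment alignment in world coordinates: the translation aligns mask
#' centroids (first moment) and the rotation aligns the principal axes of
#' the second-moment (covariance) matrices. Principal axes leave a four-fold
#' proper-rotation sign ambiguity; the candidate maximizing mask overlap is
#' returned. Near-isotropic masks (largest/smallest covariance eigenvalue
#' ratio < 1.05) fall back to translation-only with a warning.
#'
#' @param fixed,moving [LabelVolume-class] binary masks (nonzero = inside).
#' @return a [RigidTransform-class] mapping fixed-world to moving-world
#'   coordinates (pull-back convention).
#' @export
momentRigidInit <- function(fixed, moving) {
  wf <- maskWorldCoords(fixed)
  wm <- maskWorldCoords(moving)
  if (nrow(wf) == 0 || nrow(wm) == 0) stop("empty mask")
  cf <- colMeans(wf)
  cm <- colMeans(wm)
  Sf <- stats::cov(wf)
  Sm <- stats::cov(wm)
  ef <- eigen(Sf, symmetric = TRUE)
  em <- eigen(Sm, symmetric = TRUE)
  ratio_f <- ef$values[1] / ef$values[3]
  ratio_m <- em$values[1] / em$values[3]
  if (ratio_f < 1.05 || ratio_m < 1.05) {
    warning("near-isotropic second moments; falling back to translation-only")
    return(new("RigidTransform", rotation = diag(3),
               translation = cm - cf))
  }
  Uf <- ef$vectors
  Um <- em$vectors
  best <- NULL
  best_ov <- -1
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, 1))
    R <- Um %*% S %*% t(Uf)
    if (det(R) < 0) {
      S <- diag(c(s1, s2, -1))
      R <- Um %*% S %*% t(Uf)
    }
    tr <- cm - R %*% cf
    ov <- rigidOverlap(fixed, moving, R, as.numeric(tr))
    if (ov > best_ov) {
      best_ov <- ov
      best <- list(R = R, tr = as.numeric(tr))
    }
  }
  new("RigidTransform", rotation = best$R, translation = best$tr)
}

maskWorldCoords <- function(vol) {
  m <- voxelData(vol) != 0
  if (!any(m)) return(matrix(numeric(0), 0, 3))
  idx <- which(m, arr.ind = TRUE) - 1
  voxToWorld(idx, vol@affine)
}

rigidOverlap <- function(fixed, moving, R, tr) {
  m <- voxelData(fixed) != 0
  idx <- which(m, arr.ind = TRUE) - 1
  w <- voxToWorld(idx, fixed@affine)
  wmv <- w %*% t(R) + matrix(tr, nrow(w), 3, byrow = TRUE)
  vm <- worldToVox(wmv, moving@affine)
  vals <- cpp_interp_nearest(as.numeric(voxelData(moving) != 0),
                             dim(voxelData(moving)), vm)
  # reject samples clamped from far outside
  d <- dim(voxelData(moving))
  inside <- vm[, 1] > -1 & vm[, 2] > -1 & vm[, 3] > -1 &
    vm[, 1] < d[1] & vm[, 2] < d[2] & vm[, 3] < d[3]
  sum(vals[inside]) / nrow(w)
}

#' Apply a rigid world-coordinate transform to world points
#' @param t a [RigidTransform-class].
#' @param xyz n x 3 world coordinates (mm).
#' @return transformed n x 3 coordinates.
#' @export
applyRigid <- function(t, xyz) {
  xyz %*% t(t@rotation) + matrix(t@translation, nrow(xyz), 3, byrow = TRUE)
}
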