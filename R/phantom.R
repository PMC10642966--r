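#' Parameters for the folded-sheet phantom
#'
#' The phantom is a parametric sheet S(u, v): u in [0,1] runs
#' anterior-posterior (A-P, physical length `length_mm`), v in [0,1] runs
#' proximal-distal (P-D, cross-sectional arc length `arc_mm`). The
#' cross-section is a circular arc of total angle `curl_angle_rad`
#' (constant-curvature stand-in for the hippocampal curl), and longitudinal
#' gyri are modelled by displacing the sheet along its normal by
#' `gyral_amplitude_mm * sin(2*pi*n_gyri*u + phase)`. Subfields partition the
#' P-D axis in the order Sub, CA1, CA2, CA3, CA4 according to
#' `subfield_fractions`, each with its own laminar thickness.
#'
#' @param length_mm A-P extent (mm).
#' @param arc_mm P-D cross-sectional arc length (mm).
#' @param curl_angle_rad total cross-sectional curl angle (radians).
#' @param n_gyri number of longitudinal gyral waves (>= 0).
#' @param gyral_amplitude_mm amplitude of the gyral modulation (mm).
#' @param phase phase of the gyral wave (radians).
#' @param thickness_profile per-subfield laminar thickness (mm), length 5.
#' @param thickness_scale global multiplier on the thickness profile.
#' @param subfield_fractions 5 positive P-D fractions summing to 1
#'   (Sub, CA1, CA2, CA3, CA4).
#' @param voxel_mm isotropic voxel size (mm).
#' @param hemisphere "left" or "right" (right is mirrored about x = 0).
#' @param origin_mm world-space offset of the volume (mm, length 3).
#' @return a `PhantomParams` list.
#' @export
phantomParams <- function(length_mm = 40, arc_mm = 20,
                          curl_angle_rad = 3 * pi / 2,
                          n_gyri = 3L, gyral_amplitude_mm = 1.5, phase = 0,
                          thickness_profile = c(Sub = 1.8, CA1 = 1.4,
                                                CA2 = 1.2, CA3 = 1.3,
                                                CA4 = 2.0),
                          thickness_scale = 1,
                          subfield_fractions = c(0.28, 0.30, 0.10,
                                                 0.14, 0.18),
                          voxel_mm = 0.5, hemisphere = "left",
                          origin_mm = c(0, 0, 0)) {
  p <- list(length_mm = length_mm, arc_mm = arc_mm,
            curl_angle_rad = curl_angle_rad, n_gyri = as.integer(n_gyri),
            gyral_amplitude_mm = gyral_amplitude_mm, phase = phase,
            thickness_profile = unname(thickness_profile),
            thickness_scale = thickness_scale,
            subfield_fractions = unname(subfield_fractions),
            voxel_mm = voxel_mm, hemisphere = match.arg(hemisphere,
                                                        c("left", "right")),
            origin_mm = origin_mm)
  validatePhantomParams(p)
  class(p) <- "PhantomParams"
  p
}

validatePhantomParams <- function(p) {
  stopifnot(p$length_mm > 0, p$arc_mm > 0, p$voxel_mm > 0,
            p$n_gyri >= 0, p$gyral_amplitude_mm >= 0,
            length(p$subfield_fractions) == 5,
            length(p$thickness_profile) == 5,
            all(p$subfield_fractions > 0),
            all(p$thickness_profile > 0))
  if (abs(sum(p$subfield_fractions) - 1) > 1e-9)
    stop("subfield_fractions must sum to 1")
  invisible(TRUE)
}

# Evaluate the parametric mid-surface and its outward unit normal at (u, v).
# u, v may be vectors of equal length. Returns list(S = n x 3, N = n x 3).
# Axes: x = cross-section (flip axis), y = A-P, z = cross-section.
phantomSurface <- function(u, v, p) {
  curl <- max(p$curl_angle_rad, 1e-6)
  r <- p$arc_mm / curl
  th <- (v - 0.5) * curl
  base <- cbind(r * sin(th), p$length_mm * u, r * (1 - cos(th)))
  nrm2d <- cbind(sin(th), 0, -cos(th))  # outward cross-section normal
  amp <- p$gyral_amplitude_mm * sin(2 * pi * p$n_gyri * u + p$phase)
  S <- base + amp * nrm2d
  # true surface normal via finite differences of S
  du <- 1e-4; dv <- 1e-4
  Sa <- phantomSurfaceBase(u + du, v, p) - phantomSurfaceBase(u - du, v, p)
  Sb <- phantomSurfaceBase(u, v + dv, p) - phantomSurfaceBase(u, v - dv, p)
  N <- cbind(Sa[, 2] * Sb[, 3] - Sa[, 3] * Sb[, 2],
             Sa[, 3] * Sb[, 1] - Sa[, 1] * Sb[, 3],
             Sa[, 1] * Sb[, 2] - Sa[, 2] * Sb[, 1])
  len <- sqrt(rowSums(N^2))
  N <- N / pmax(len, 1e-12)
  # orient toward the outer (convex) side
  flip <- rowSums(N * nrm2d) < 0
  N[flip, ] <- -N[flip, ]
  list(S = S, N = N)
}

phantomSurfaceBase <- function(u, v, p) {
  curl <- max(p$curl_angle_rad, 1e-6)
  r <- p$arc_mm / curl
  th <- (v - 0.5) * curl
  base <- cbind(r * sin(th), p$length_mm * u, r * (1 - cos(th)))
  nrm2d <- cbind(sin(th), 0, -cos(th))
  amp <- p$gyral_amplitude_mm * sin(2 * pi * p$n_gyri * u + p$phase)
  base + amp * nrm2d
}

subfieldOfV <- function(v, fractions) {
  cuts <- cumsum(fractions)
  findInterval(pmin(pmax(v, 0), 1 - 1e-12), c(0, cuts[1:4]),
               rightmost.closed = FALSE)
}

#' Generate a folded-sheet phantom with known ground truth
#'
#' Voxelizes the parametric sheet of [phantomParams()] into a 3D labelmap:
#' gray-matter voxels within half the local subfield thickness of the
#' mid-surface are labelled by their P-D subfield interval; a one-voxel SRLM
#' shell is painted on the concave (inner) side; the four sheet edges carry
#' terminus labels (anterior 7, posterior 8, proximal 9, distal 10). The true
#' intrinsic coordinates (u, v, laminar fraction) of every gray-matter voxel
#' are returned, along with the true unfolded subfield map.
#'
#' @param params a `PhantomParams` list.
#' @param seed integer seed, kept for interface symmetry with
#'   [generateCohort()]: a phantom is fully determined by its params (all
#'   stochastic variation lives in the params jitter), so generation is
#'   deterministic for fixed (params, seed).
#' @param grid_shape shape of the truth unfolded label map.
#' @return a `PhantomSample` list with elements `labels` ([LabelVolume-class]),
#'   `truth_coords` ([CoordinateFields-class]), `truth_unfolded_labels`
#'   ([UnfoldedMap-class]) and `params`.
#' @export
generatePhantom <- function(params, seed = 0L, grid_shape = c(256L, 128L)) {
  p <- params
  validatePhantomParams(p)
  h <- p$voxel_mm
  thick <- p$thickness_profile * p$thickness_scale
  if (min(thick) < 2 * h)
    stop(sprintf(paste0("voxel size %.3g mm too coarse to resolve the ",
                        "thinnest subfield (%.3g mm < 2 voxels); use a ",
                        "finer resolution"), h, min(thick)))

  # sample the sheet densely enough that every voxel it passes through
  # receives at least one sample
  stretch <- sqrt(1 + (2 * pi * p$n_gyri * p$gyral_amplitude_mm /
                         p$length_mm)^2)
  step <- h / 2.5
  capw <- 1.5 * h  # physical width of edge terminus caps
  nu <- max(8L, ceiling(p$length_mm * stretch / step))
  nv <- max(8L, ceiling(p$arc_mm / step))
  ucap <- capw / p$length_mm
  vcap <- capw / p$arc_mm
  us <- seq(-ucap, 1 + ucap, length.out = nu + 2 * ceiling(capw / step))
  vs <- seq(-vcap, 1 + vcap, length.out = nv + 2 * ceiling(capw / step))
  uv <- expand.grid(u = us, v = vs)
  surf <- phantomSurface(uv$u, uv$v, p)

  vclamp <- pmin(pmax(uv$v, 1e-9), 1 - 1e-9)
  sf <- subfieldOfV(vclamp, p$subfield_fractions)
  tloc <- thick[sf]

  # sample the laminar axis past the slab on both sides so every voxel whose
  # centre lies within half the local thickness (plus the SRLM shell) has a
  # nearby sample; the centre's exact laminar fraction is refined below
  wmargin <- 1.4 * h / min(thick)
  nw <- max(7L, ceiling((1 + 2 * wmargin) * max(thick) / step) + 1L)
  ws <- seq(-0.5 - wmargin, 0.5 + wmargin, length.out = nw)
  nsamp <- nrow(uv)

  pos <- matrix(0, nsamp * nw, 3)
  for (k in seq_len(nw)) {
    idx <- (k - 1) * nsamp + seq_len(nsamp)
    pos[idx, ] <- surf$S + (ws[k] * tloc) * surf$N
  }
  uu <- rep(uv$u, nw)
  vv <- rep(uv$v, nw)
  ww <- rep(ws, each = nsamp)
  tt <- rep(tloc, nw)
  NN <- surf$N[rep(seq_len(nsamp), nw), , drop = FALSE]

  if (p$hemisphere == "right") {
    pos[, 1] <- -pos[, 1]
    NN[, 1] <- -NN[, 1]
  }

  # voxel grid covering the sheet with a 2-voxel margin
  lo <- apply(pos, 2, min) - 2 * h
  hi <- apply(pos, 2, max) + 2 * h
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4] <- lo + p$origin_mm
  world <- sweep(pos, 2, lo, `-`)
  idx <- round(world / h)  # 0-based voxel indices
  flat <- 1 + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  ctr <- idx * h
  off <- ctr - world
  d2 <- rowSums(off^2)
  # refine the laminar fraction at the voxel centre via the local normal
  wref <- ww + rowSums(off * NN) / tt

  # per voxel keep the sample nearest its centre (assign in order of
  # decreasing distance so the closest write lands last)
  ord <- order(-d2)
  nvox <- prod(dims)
  tu <- rep(NA_real_, nvox)
  tv <- rep(NA_real_, nvox)
  tw <- rep(NA_real_, nvox)
  tu[flat[ord]] <- uu[ord]
  tv[flat[ord]] <- vv[ord]
  tw[flat[ord]] <- wref[ord]

  # classify voxels from their centre's intrinsic coordinates
  voxels <- integer(nvox)
  got <- !is.na(tw)
  in_u <- got & tu >= 0 & tu <= 1
  in_v <- got & tv >= 0 & tv <= 1
  in_w <- got & abs(tw) <= 0.5
  tvc <- pmin(pmax(tv, 1e-9), 1 - 1e-9)
  sfv <- subfieldOfV(tvc[got], p$subfield_fractions)
  tloc_v <- rep(NA_real_, nvox)
  tloc_v[got] <- thick[sfv]
  gray <- in_u & in_v & in_w
  voxels[gray] <- subfieldOfV(tvc[gray], p$subfield_fractions)
  srlm <- in_u & in_v & !in_w & tw < -0.5 & tw >= -0.5 - h / tloc_v
  voxels[srlm] <- 6L
  voxels[in_w & in_v & got & tu < 0] <- 7L
  voxels[in_w & in_v & got & tu > 1] <- 8L
  voxels[in_w & in_u & got & tv < 0] <- 9L
  voxels[in_w & in_u & got & tv > 1] <- 10L

  voxels <- array(as.integer(voxels), dims)
  graym <- array(voxels %in% .GRAY_LABELS, dims)
  tu[!graym] <- NA_real_
  tv[!graym] <- NA_real_
  tio <- tw + 0.5
  tio[!graym] <- NA_real_

  vol <- new("LabelVolume", voxels = voxels, affine = affine,
             spacing = rep(h, 3))
  coords <- new("CoordinateFields",
                ap = array(tu, dims), pd = array(tv, dims),
                io = array(pmin(pmax(tio, 0), 1), dims), mask = graym)

  truth_lab <- matrix(rep(subfieldOfV(nodeCenters(grid_shape[2]),
                                      p$subfield_fractions),
                          each = grid_shape[1]),
                      grid_shape[1], grid_shape[2])
  tum <- unfoldedMap(truth_lab, channel = "subfields", units = "label",
                     extent = c(p$length_mm, p$arc_mm))

  structure(list(labels = vol, truth_coords = coords,
                 truth_unfolded_labels = tum, params = p),
            class = "PhantomSample")
}

#' Generate a cohort of jittered phantoms
#'
#' Emulates a study cohort of variable samples: per-sample seeded jitter of
#' gyral count (+/- 1), gyral amplitude, gyral phase, subfield fractions
#' (Dirichlet-style perturbation), thickness scale and world origin.
#' Hemispheres alternate left/right starting from left, so `n = 7` yields
#' four left and three right hippocampi.
#'
#' @param n number of samples (>= 2).
#' @param base a `PhantomParams` list of central values.
#' @param variation list of jitter scales: `n_gyri` (integer +/- range),
#'   `amplitude_rel`, `thickness_rel` (relative half-widths),
#'   `fraction_conc` (Dirichlet concentration; larger = less variable),
#'   `offset_mm` (world origin half-range).
#' @param seed integer seed; the cohort is deterministic given (base,
#'   variation, seed).
#' @param grid_shape truth unfolded grid shape.
#' @return list of `PhantomSample` objects.
#' @export
generateCohort <- function(n = 7L, base = phantomParams(),
                           variation = list(n_gyri = 1L, amplitude_rel = 0.3,
                                            thickness_rel = 0.1,
                                            fraction_conc = 150,
                                            offset_mm = 3),
                           seed = 42L, grid_shape = c(256L, 128L)) {
  stopifnot(n >= 2)
  hemis <- rep(c("left", "right"), length.out = n)
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        ng <- base$n_gyri + sample(seq(-variation$n_gyri, variation$n_gyri),
                                   1)
        ng <- max(0L, ng)
        amp <- base$gyral_amplitude_mm *
          stats::runif(1, 1 - variation$amplitude_rel,
                       1 + variation$amplitude_rel)
        tsc <- stats::runif(1, 1 - variation$thickness_rel,
                            1 + variation$thickness_rel)
        fr <- stats::rgamma(5, shape = base$subfield_fractions *
                              variation$fraction_conc)
        fr <- fr / sum(fr)
        ph <- stats::runif(1, 0, 2 * pi)
        off <- stats::runif(3, -variation$offset_mm, variation$offset_mm)
        if (min(fr) < 0.02) next  # degenerate fractions: resample
        pp <- base
        pp$n_gyri <- as.integer(ng)
        pp$gyral_amplitude_mm <- amp
        pp$thickness_scale <- tsc
        pp$subfield_fractions <- fr
        pp$phase <- ph
        pp$origin_mm <- off
        pp$hemisphere <- hemis[i]
        ok <- tryCatch({ validatePhantomParams(pp); TRUE },
                       error = function(e) FALSE)
        if (ok && min(pp$thickness_profile * tsc) >= 2 * pp$voxel_mm) break
      }
      generatePhantom(pp, grid_shape = grid_shape)
    })
  })
}

#' Generate a smooth random diffeomorphic warp with known displacement
#'
#' Draws Gaussian white noise per velocity component, smooths it with a
#' Gaussian of width `smoothness_px`, rescales so the exponentiated
#' displacement has the requested maximum magnitude, and exponentiates by
#' scaling-and-squaring. Used as a ground-truth oracle for registration
#' recovery tests.
#'
#' @param shape 2D grid shape.
#' @param amplitude_px target maximum displacement magnitude (px).
#' @param smoothness_px Gaussian smoothing width (px).
#' @param seed integer seed.
#' @param spacing physical pixel spacing (mm), metadata only.
#' @return a [DiffeoTransform-class] with everywhere-positive Jacobian.
#' @export
makeSyntheticWarp <- function(shape, amplitude_px, smoothness_px, seed = 1L,
                              spacing = gridSpacing(shape)) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (amplitude_px == 0) {
    zero <- lapply(seq_len(nd), function(i) array(0, shape))
    return(new("DiffeoTransform", velocity = zero, disp = zero,
               shape = shape, spacing = spacing, kind = "svf"))
  }
  vel <- withSeed(seed, lapply(seq_len(nd), function(i) {
    noise <- array(stats::rnorm(prod(shape)), shape)
    sm <- cpp_gauss_smooth(as.numeric(noise), shape, rep(smoothness_px, nd))
    array(sm, shape)
  }))
  # taper to zero at the rectangle borders: the unfolded space has four true
  # edges and permits no flux through them
  margin <- pmax(4, pmin(smoothness_px, floor(shape / 3)))
  env <- Reduce(`*`, lapply(seq_len(nd), function(ax) {
    dedge <- pmin(seq_len(shape[ax]) - 1, shape[ax] - seq_len(shape[ax]))
    w <- pmin(1, dedge / margin[min(ax, length(margin))])
    e <- sin(w * pi / 2)^2
    if (ax == 1) matrix(e, shape[1], shape[2]) else
      matrix(e, shape[1], shape[2], byrow = TRUE)
  }))
  vel <- lapply(vel, function(v) v * env)
  # iterate the scaling so max |exp(v)| hits the target amplitude
  for (rep in 1:4) {
    disp <- expVelocity(vel, shape)
    mx <- max(sqrt(Reduce(`+`, lapply(disp, function(u) u^2))))
    if (mx < 1e-12) break
    vel <- lapply(vel, function(v) v * amplitude_px / mx)
  }
  disp <- expVelocity(vel, shape)
  t <- new("DiffeoTransform", velocity = vel, disp = disp, shape = shape,
           spacing = spacing, kind = "svf")
  jd <- mapValues(jacobianDeterminant(t))
  if (min(jd) <= 0)
    stop(sprintf(paste0("amplitude %.3g px incompatible with positive ",
                        "Jacobian at smoothness %.3g px (min det %.3g)"),
                 amplitude_px, smoothness_px, min(jd)))
  t
}
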