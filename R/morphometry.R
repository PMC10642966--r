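# Per-vertex morphometry on the unfolded grid: laminar thickness by
# streamline integration through the io field, gyrification as the native /
# unfolded area ratio, and mean curvature of the mid-thickness surface by
# local quadric fitting. All three are deterministic functions of the input
# volume and are the channels driving unfolded registration.

#' Streamline laminar thickness
#'
#' At each surface node, integrates a streamline along the io-field gradient
#' in both laminar directions (RK4, step 0.25 x the smallest voxel) until
#' io <= 0.01 or io >= 0.99, and reports the arc length in mm. Because the
#' Dirichlet boundaries sit at voxel centres half a voxel outside the tissue
#' on each side, the traced length is corrected by the 2% threshold margin
#' and one voxel of boundary offset. Runaway streamlines (longer than
#' `max_mm`) are marked invalid (NaN).
#'
#' @param coords a [CoordinateFields-class].
#' @param grid a [SurfaceGrid-class].
#' @param vol the source [LabelVolume-class] (for world geometry).
#' @param max_mm streamline length cap (mm).
#' @return an [UnfoldedMap-class] of thickness in mm.
#' @export
computeThickness <- function(coords, grid, vol, max_mm = 20) {
  io <- coords@io
  if (all(is.na(io))) stop("io field is all-NA")
  iof <- extendIoField(coords, vol)
  g <- gradient3(iof)
  shape <- dim(grid@valid)
  xyz <- matrix(grid@xyz, prod(shape), 3)
  seeds <- worldToVox(xyz, vol@affine)
  sp <- vol@spacing
  step <- 0.25 * min(sp)
  len <- cpp_trace_thickness(as.numeric(iof), as.numeric(g[[1]]),
                             as.numeric(g[[2]]), as.numeric(g[[3]]),
                             dim(io), sp, seeds, step, 0.01, 0.99, max_mm)
  # boundary conditions are imposed half a voxel outside the tissue on each
  # side, and the 0.01/0.99 thresholds trim 2% of the laminar span
  thick <- len / 0.98 - mean(sp)
  thick[thick < 0] <- NA_real_
  bad <- sum(is.na(thick) & as.logical(grid@valid))
  if (bad > 0)
    warning(sprintf("%d surface nodes produced invalid thickness streamlines",
                    bad))
  thick[!as.logical(grid@valid)] <- NA_real_
  unfoldedMap(matrix(thick, shape[1], shape[2]), channel = "thickness",
              units = "mm", extent = grid@extent)
}

# re-attach the laminar Dirichlet boundaries (io = 0 on the SRLM shell,
# io = 1 on the outer background surface) so streamlines can cross the
# 0.01 / 0.99 thresholds, then extend beyond the mask
extendIoField <- function(coords, vol) {
  v <- voxelData(vol)
  io <- coords@io
  gray <- coords@mask
  io[v == 6L] <- 0
  bg <- array(v == 0L, dim(v))
  outer_bg <- adjacentTo(bg, gray) & !adjacentTo(bg, array(v == 6L, dim(v)))
  io[outer_bg] <- 1
  fillVolumeNA(io, gray | v == 6L | outer_bg)
}

# extend a masked volume a few voxels beyond the mask so gradients and
# interpolation behave at the boundary
fillVolumeNA <- function(a, mask, passes = 4L) {
  out <- a
  out[!mask] <- NA_real_
  for (p in seq_len(passes)) {
    nas <- is.na(out)
    if (!any(nas)) break
    acc <- array(0, dim(out))
    cnt <- array(0, dim(out))
    for (ax in 1:3) for (s in c(-1, 1)) {
      nb <- shiftArray(out, ax, s)
      okn <- !is.na(nb)
      acc[okn] <- acc[okn] + nb[okn]
      cnt <- cnt + okn
    }
    fill <- nas & cnt > 0
    out[fill] <- acc[fill] / cnt[fill]
  }
  out[is.na(out)] <- 0.5
  out
}

#' Gyrification index
#'
#' Ratio of the native mid-surface area attached to each vertex (a quarter
#' of every adjacent grid quad, the standard vertex-area assignment) to the
#' unfolded area the vertex occupies (the pixel area in unfolded mm^2).
#' Values above 1 mark tissue compressed by unfolding (gyral folding);
#' Gaussian-smoothed with `sigma_mm` in unfolded space.
#'
#' @param grid a [SurfaceGrid-class].
#' @param sigma_mm smoothing width in unfolded mm.
#' @return a dimensionless [UnfoldedMap-class].
#' @export
computeGyrification <- function(grid, sigma_mm = 1) {
  xyz <- grid@xyz
  d <- dim(xyz)[1:2]
  px <- grid@extent / d
  # quad areas as two triangles
  A <- xyz[-d[1], -d[2], , drop = FALSE]
  B <- xyz[-1, -d[2], , drop = FALSE]
  C <- xyz[-1, -1, , drop = FALSE]
  D <- xyz[-d[1], -1, , drop = FALSE]
  quad <- triArea(A, B, C) + triArea(A, C, D)
  # vertex dual area: quarter of each adjacent quad
  varea <- matrix(0, d[1], d[2])
  cnt <- matrix(0, d[1], d[2])
  for (di in 0:1) for (dj in 0:1) {
    ri <- seq_len(d[1] - 1) + di
    cj <- seq_len(d[2] - 1) + dj
    varea[ri, cj] <- varea[ri, cj] + quad / 4
    cnt[ri, cj] <- cnt[ri, cj] + 1
  }
  unf_area <- prod(px) * cnt / 4  # edge vertices own proportionally less
  gi <- varea / unf_area
  gi[varea <= 0] <- NA_real_
  ndeg <- sum(!is.finite(gi) & grid@valid)
  gi[!grid@valid] <- NA_real_
  if (ndeg > 0)
    warning(sprintf("%d degenerate native cells in gyrification", ndeg))
  gi <- gaussSmoothNA(gi, sigma_mm / px)
  unfoldedMap(gi, channel = "gyrification", units = "",
              extent = grid@extent)
}

triArea <- function(P, Q, R) {
  u <- Q - P
  v <- R - P
  cx <- u[,,2] * v[,,3] - u[,,3] * v[,,2]
  cy <- u[,,3] * v[,,1] - u[,,1] * v[,,3]
  cz <- u[,,1] * v[,,2] - u[,,2] * v[,,1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mean curvature of the mid-thickness surface
#'
#' Fits a quadric patch to each vertex's 5 x 5 grid neighbourhood in native
#' space and evaluates the mean curvature H at the vertex; the sign is
#' positive where the surface bends toward the outer (io = 1) side.
#' Gaussian-smoothed with `sigma_mm` in unfolded space; units 1/mm.
#' Rank-deficient neighbourhood fits yield NaN.
#'
#' @param grid a [SurfaceGrid-class].
#' @param coords a [CoordinateFields-class] (for the outer-side orientation).
#' @param vol the source [LabelVolume-class].
#' @param sigma_mm smoothing width in unfolded mm.
#' @return an [UnfoldedMap-class] of mean curvature (1/mm).
#' @export
computeCurvature <- function(grid, coords, vol, sigma_mm = 1) {
  xyz <- grid@xyz
  d <- dim(xyz)[1:2]
  px <- grid@extent / d
  H <- matrix(NA_real_, d[1], d[2])
  # outer direction from the io gradient at each node
  iof <- fillVolumeNA(coords@io, coords@mask)
  g <- gradient3(iof)
  seeds <- worldToVox(matrix(xyz, prod(d), 3), vol@affine)
  sp <- vol@spacing
  outer_dir <- vapply(1:3, function(ax)
    cpp_interp_linear(as.numeric(g[[ax]]), dim(iof), seeds) / sp[ax],
    numeric(prod(d)))
  nd <- sqrt(rowSums(outer_dir^2))
  outer_dir <- outer_dir / pmax(nd, 1e-12)
  offs <- as.matrix(expand.grid(di = -2:2, dj = -2:2))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!grid@valid[i, j]) next
      ii <- offs[, 1] + i
      jj <- offs[, 2] + j
      keep <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
      ii <- ii[keep]; jj <- jj[keep]
      ok <- grid@valid[cbind(ii, jj)]
      if (sum(ok) < 8) next
      P <- cbind(xyz[cbind(ii[ok], jj[ok], 1)],
                 xyz[cbind(ii[ok], jj[ok], 2)],
                 xyz[cbind(ii[ok], jj[ok], 3)])
      ctr <- c(xyz[i, j, 1], xyz[i, j, 2], xyz[i, j, 3])
      Q <- sweep(P, 2, ctr)
      # local frame: plane fit normal, oriented toward the outer side
      sv <- svd(Q, nu = 0, nv = 3)
      nrm <- sv$v[, 3]
      od <- outer_dir[i + (j - 1) * d[1], ]
      if (sum(nrm * od) < 0) nrm <- -nrm
      e1 <- sv$v[, 1]
      e2 <- sv$v[, 2]
      x <- Q %*% e1
      y <- Q %*% e2
      z <- Q %*% nrm
      X <- cbind(x^2, x * y, y^2, x, y, 1)
      fit <- tryCatch(qr.coef(qr(X), z), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit)) next
      fx <- fit[4]; fy <- fit[5]
      fxx <- 2 * fit[1]; fxy <- fit[2]; fyy <- 2 * fit[3]
      H[i, j] <- ((1 + fy^2) * fxx - 2 * fx * fy * fxy +
                    (1 + fx^2) * fyy) /
        (2 * (1 + fx^2 + fy^2)^1.5)
    }
  }
  H <- gaussSmoothNA(H, sigma_mm / px)
  unfoldedMap(H, channel = "curvature", units = "1/mm",
              extent = grid@extent)
}

#' Assemble and standardize a multi-channel feature stack
#'
#' Fills missing pixels with the nearest valid value, then z-scores each
#' channel over its (originally) valid pixels so the heterogeneous units
#' (mm, ratio, 1/mm) contribute with equal weight to multi-channel
#' registration. The per-channel mean and sd are retained for inversion.
#'
#' @param maps named list of [UnfoldedMap-class] objects on one grid (any
#'   subset of thickness / gyrification / curvature, used by the feature
#'   ablation).
#' @param standardize z-score the channels (default TRUE).
#' @return a [FeatureStack-class].
#' @export
prepareFeatureStack <- function(maps, standardize = TRUE) {
  stopifnot(length(maps) >= 1)
  nms <- names(maps)
  if (is.null(nms))
    nms <- vapply(maps, channelName, character(1))
  spacing <- maps[[1]]@spacing
  rec <- data.frame(channel = character(), mean = numeric(), sd = numeric())
  chans <- list()
  for (q in seq_along(maps)) {
    v <- maps[[q]]@values
    if (!any(is.finite(v))) stop("channel ", nms[q], " has no valid pixels")
    v <- fillNearest(v, spacing)
    if (standardize) {
      mu <- mean(v)
      sdv <- stats::sd(as.numeric(v))
      if (sdv < 1e-12)
        stop("channel ", nms[q], " has zero variance; cannot standardize")
      v <- (v - mu) / sdv
      rec <- rbind(rec, data.frame(channel = nms[q], mean = mu, sd = sdv))
    }
    chans[[nms[q]]] <- v
  }
  new("FeatureStack", channels = chans, standardization = rec,
      spacing = spacing)
}

#' Compute all morphometric features of one sample
#'
#' Convenience wrapper running unfolding, surface extraction and the three
#' feature maps for a labelled volume.
#'
#' @param vol a [LabelVolume-class].
#' @param shape unfolded grid shape.
#' @param extent unfolded physical extent (mm).
#' @param sigma_mm smoothing for gyrification/curvature.
#' @param tol,max_iter Laplace solver controls.
#' @return list with `coords`, `grid`, `maps` (named list of the three
#'   feature [UnfoldedMap-class]s) and `labels_unfolded`.
#' @export
computeSampleFeatures <- function(vol, shape = c(256L, 128L),
                                  extent = .UNFOLDED_EXTENT, sigma_mm = 1,
                                  tol = 1e-5, max_iter = 10000L) {
  coords <- computeCoordinates(vol, tol = tol, max_iter = max_iter)
  grid <- extractMidthicknessGrid(coords, vol, shape = shape,
                                  extent = extent)
  maps <- list(
    thickness = computeThickness(coords, grid, vol),
    gyrification = computeGyrification(grid, sigma_mm = sigma_mm),
    curvature = computeCurvature(grid, coords, vol, sigma_mm = sigma_mm))
  list(coords = coords, grid = grid, maps = maps,
       labels_unfolded = sampleLabelsToUnfolded(vol, grid))
}
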