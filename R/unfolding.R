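# Laplace-coordinate unfolding: harmonic scalar fields between opposing
# boundary labels give smooth monotone axes through the gray-matter sheet;
# the mid-thickness (io = 0.5) surface sampled on a regular unfolded lattice
# turns each sample into a flat 2D image.

#' Solve the masked Laplace equation between two boundary regions
#'
#' Solves the discrete Laplace equation over `domain` with Dirichlet value 0
#' on `source` voxels and 1 on `sink` voxels, using a 6-neighbour stencil
#' with zero-flux (reflecting) walls implemented by masked stencil
#' renormalization. The solver is red-black successive over-relaxation
#' (omega = 1.8).
#'
#' @param domain,source,sink logical 3D arrays of identical shape. Source
#'   and sink must be non-empty, disjoint, and 6-adjacent to the domain.
#' @param tol maximum relative residual for convergence.
#' @param max_iter sweep cap.
#' @return numeric 3D array: the harmonic field on domain (plus the fixed
#'   0/1 boundary values), NA elsewhere.
#' @export
solveLaplace <- function(domain, source, sink, tol = 1e-5,
                         max_iter = 10000L) {
  stopifnot(identical(dim(domain), dim(source)),
            identical(dim(domain), dim(sink)))
  if (!any(source)) stop("empty source mask")
  if (!any(sink)) stop("empty sink mask")
  if (any(source & sink)) stop("source and sink masks overlap")
  dom <- domain & !source & !sink
  # connectivity: every domain voxel must reach both boundaries
  comp <- array(cpp_label_components(as.logical(dom | source | sink),
                                     dim(domain), 6L), dim(domain))
  src_comps <- unique(comp[source])
  snk_comps <- unique(comp[sink])
  good <- intersect(src_comps, snk_comps)
  dom_comps <- unique(comp[dom])
  bad <- setdiff(dom_comps, good)
  if (length(bad)) {
    sizes <- vapply(bad, function(b) sum(comp == b & dom), integer(1))
    stop("domain has components with no source-to-sink path; sizes: ",
         paste(sizes, collapse = ", "))
  }
  fixed <- source | sink
  init <- array(0.5, dim(domain))
  init[source] <- 0
  init[sink] <- 1
  res <- cpp_solve_laplace(as.logical(dom), as.logical(fixed),
                           as.numeric(init), dim(domain),
                           1.8, tol, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("Laplace solver did not converge in %d iterations (residual %.3g)",
                 max_iter, res$residual))
  out <- array(res$field, dim(domain))
  out[!(dom | fixed)] <- NA_real_
  out
}

adjacentTo <- function(mask, target) {
  # voxels of `mask` 6-adjacent to `target`
  adj <- array(FALSE, dim(mask))
  for (ax in 1:3) for (s in c(-1, 1))
    adj <- adj | shiftArray(target, ax, s)
  mask & adj
}

#' Compute the three Laplace coordinate fields of a labelmap
#'
#' Builds the unfolding of a segmented sheet: `ap` runs from the anterior
#' terminus label (7) to the posterior (8), `pd` from the proximal edge (9)
#' to the distal edge (10), and `io` from the SRLM inner boundary (label 6)
#' to the outer background surface. All fields are harmonic over the
#' gray-matter domain (labels 1-5) and lie in [0, 1].
#'
#' @param vol a [LabelVolume-class] with subfield, SRLM and terminus labels.
#' @param tol,max_iter solver controls, see [solveLaplace()].
#' @return a [CoordinateFields-class].
#' @export
computeCoordinates <- function(vol, tol = 1e-5, max_iter = 10000L) {
  v <- voxelData(vol)
  needed <- c(SRLM = 6L, anterior = 7L, posterior = 8L, proximal = 9L,
              distal = 10L)
  for (nm in names(needed))
    if (!any(v == needed[nm]))
      stop(sprintf("missing label %d (%s)", needed[nm], nm))
  gray <- array(v %in% .GRAY_LABELS, dim(v))
  ap <- solveLaplace(gray, v == 7L, v == 8L, tol, max_iter)
  pd <- solveLaplace(gray, v == 9L, v == 10L, tol, max_iter)
  srlm <- array(v == 6L, dim(v))
  bg <- array(v == 0L, dim(v))
  outer_bg <- adjacentTo(bg, gray) & !adjacentTo(bg, srlm)
  io <- solveLaplace(gray, srlm, outer_bg, tol, max_iter)
  blank <- function(f) { f[!gray] <- NA_real_; f }
  new("CoordinateFields", ap = blank(ap), pd = blank(pd), io = blank(io),
      mask = gray)
}

#' Extract the mid-thickness surface on the regular unfolded grid
#'
#' For each node of the regular unfolded lattice (default 256 x 128 across
#' A-P x P-D), interpolates the world position of the io = 0.5 mid-thickness
#' surface from gray-matter voxels in the laminar band |io - 0.5| < 0.25,
#' using inverse-distance weighting in (ap, pd) space over the nearest
#' supporting voxels. Nodes whose nearest support is farther than 1.5 grid
#' cells are marked extrapolated in the validity mask.
#'
#' @param coords a [CoordinateFields-class].
#' @param vol the [LabelVolume-class] the coordinates were computed from.
#' @param shape grid shape (A-P, P-D).
#' @param extent physical extent (mm) of the unfolded rectangle.
#' @param io_band laminar half-width of supporting voxels around io = 0.5.
#' @param k number of supporting voxels per node.
#' @return a [SurfaceGrid-class].
#' @export
extractMidthicknessGrid <- function(coords, vol, shape = c(256L, 128L),
                                    extent = .UNFOLDED_EXTENT,
                                    io_band = 0.25, k = 8L) {
  shape <- as.integer(shape)
  band <- coords@mask & !is.na(coords@io) &
    abs(coords@io - 0.5) < io_band
  n <- sum(band)
  if (n < 100)
    stop(sprintf("only %d voxels support the mid-thickness surface; volume too coarse",
                 n))
  idx <- which(band, arr.ind = TRUE) - 1
  xyz <- voxToWorld(idx, vol@affine)
  uv <- cbind(coords@ap[band], coords@pd[band])
  res <- cpp_idw_grid(uv, xyz, shape[1], shape[2], as.integer(k))
  g <- array(res$values, c(shape, 3L))
  cell <- sqrt(sum((1 / shape)^2))
  valid <- matrix(res$nearest_dist <= 1.5 * cell, shape[1], shape[2])
  new("SurfaceGrid", xyz = g, valid = valid, extent = extent)
}

#' Sample a native label volume onto the unfolded grid
#'
#' Reads the subfield label at (the voxel nearest to) each surface node,
#' yielding this sample's subfields as a flat 2D label image. Labels outside
#' the subfield range map to the missing sentinel 0.
#'
#' @param vol a [LabelVolume-class].
#' @param grid a [SurfaceGrid-class].
#' @return an [UnfoldedMap-class] of labels 0-5.
#' @export
sampleLabelsToUnfolded <- function(vol, grid) {
  shape <- dim(grid@valid)
  xyz <- matrix(grid@xyz, prod(shape), 3)
  vox <- worldToVox(xyz, vol@affine)
  vals <- cpp_interp_nearest(as.numeric(voxelData(vol)),
                             dim(voxelData(vol)), vox)
  vals <- as.integer(round(vals))
  vals[!(vals %in% .GRAY_LABELS)] <- 0L
  vals[!as.logical(grid@valid)] <- 0L
  unfoldedMap(matrix(vals, shape[1], shape[2]), channel = "subfields",
              units = "label", extent = grid@extent)
}
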