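#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib unfoldreg, .registration = TRUE
NULL

# Label scheme shared across the package. Gray matter is labels 1-5; the SRLM
# (inner laminar boundary) and the four sheet-edge termini are auxiliary
# labels consumed by the Laplace coordinate solver.
.LABELS <- c(bg = 0L, Sub = 1L, CA1 = 2L, CA2 = 3L, CA3 = 4L, CA4 = 5L,
             SRLM = 6L, ant = 7L, post = 8L, prox = 9L, dist = 10L)
.GRAY_LABELS <- 1:5
.SUBFIELD_NAMES <- c("Sub", "CA1", "CA2", "CA3", "CA4")

#' LabelVolume: a 3D integer labelmap with world geometry
#'
#' Holds a 3D voxel grid of integer labels together with the 4x4
#' voxel-to-world affine (mm). Subfield labels are 1 (Sub) through 5
#' (CA4, dentate gyrus merged in), 6 marks the SRLM inner boundary and
#' 7-10 the anterior/posterior/proximal/distal sheet-edge termini.
#'
#' @slot voxels 3D integer array of labels (or numeric for scalar volumes).
#' @slot affine 4x4 voxel-index (0-based) to world (mm) matrix.
#' @slot spacing per-axis voxel size in mm (column norms of the affine).
#' @export
setClass("LabelVolume",
         representation(voxels = "array", affine = "matrix",
                        spacing = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (length(dim(object@voxels)) != 3)
             msg <- c(msg, "voxels must be a 3D array")
           if (!all(dim(object@affine) == c(4, 4)))
             msg <- c(msg, "affine must be 4x4")
           if (length(object@spacing) != 3 || any(object@spacing <= 0))
             msg <- c(msg, "spacing must be 3 positive values")
           if (is.null(msg)) TRUE else msg
         })

#' UnfoldedMap: a scalar or label image on the unfolded rectangle
#'
#' A regular 2D grid over the standardized unfolded space, rows indexing the
#' anterior-posterior axis and columns the proximal-distal axis. The grid
#' carries a physical pixel spacing in unfolded mm so that deformations and
#' smoothing kernels have physical units.
#'
#' @slot values numeric matrix (rows = A-P, cols = P-D). Label maps use the
#'   missing sentinel 0; scalar maps use NaN.
#' @slot spacing pixel spacing (mm) along (A-P, P-D).
#' @slot channel channel name, e.g. "thickness".
#' @slot units unit string, e.g. "mm".
#' @export
setClass("UnfoldedMap",
         representation(values = "matrix", spacing = "numeric",
                        channel = "character", units = "character"),
         validity = function(object) {
           if (length(object@spacing) != 2 || any(object@spacing <= 0))
             return("spacing must be 2 positive values")
           TRUE
         })

#' CoordinateFields: the Laplace unfolding of a labelmap
#'
#' Three harmonic scalar fields over gray matter, each in [0,1]: `ap`
#' (anterior to posterior), `pd` (proximal to distal) and `io` (inner/SRLM
#' side to outer side, the laminar coordinate). Together they assign every
#' gray-matter voxel a position in the standardized unfolded space.
#'
#' @slot ap,pd,io numeric 3D arrays, NA outside the gray-matter domain.
#' @slot mask logical 3D array marking the gray-matter domain.
#' @export
setClass("CoordinateFields",
         representation(ap = "array", pd = "array", io = "array",
                        mask = "array"),
         validity = function(object) {
           d <- dim(object@mask)
           if (!identical(dim(object@ap), d) || !identical(dim(object@pd), d) ||
               !identical(dim(object@io), d))
             return("all fields must share the mask's dimensions")
           for (f in list(object@ap, object@pd, object@io)) {
             v <- f[object@mask]
             v <- v[!is.na(v)]
             if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
               return("coordinate values must lie in [0,1]")
           }
           TRUE
         })

#' SurfaceGrid: the mid-thickness surface sampled on the unfolded lattice
#'
#' World coordinates (mm) of the io = 0.5 surface at every node of the
#' regular unfolded grid, plus a validity mask for nodes whose position had
#' to be extrapolated (no nearby supporting voxels).
#'
#' @slot xyz numeric array (nrow, ncol, 3) of world coordinates.
#' @slot valid logical matrix marking supported nodes.
#' @slot extent physical extent (mm) of the unfolded rectangle (A-P, P-D).
#' @export
setClass("SurfaceGrid",
         representation(xyz = "array", valid = "matrix", extent = "numeric"),
         validity = function(object) {
           d <- dim(object@xyz)
           if (length(d) != 3 || d[3] != 3)
             return("xyz must be (nrow, ncol, 3)")
           if (!identical(dim(object@valid), d[1:2]))
             return("valid mask must match grid shape")
           if (length(object@extent) != 2 || any(object@extent <= 0))
             return("extent must be 2 positive mm values")
           TRUE
         })

#' FeatureStack: co-registered multi-channel unfolded feature maps
#'
#' Named channels (thickness, gyrification, curvature, or any subset) on a
#' common unfolded grid, optionally z-scored so that heterogeneous units
#' contribute with equal weight to multi-channel registration. The
#' standardization record (per-channel mean and sd) is retained so maps can
#' be mapped back to physical units.
#'
#' @slot channels named list of numeric matrices with identical shape.
#' @slot standardization data.frame with columns channel, mean, sd (zero
#'   rows when the stack is not standardized).
#' @slot spacing pixel spacing (mm) of the grid.
#' @export
setClass("FeatureStack",
         representation(channels = "list", standardization = "data.frame",
                        spacing = "numeric"),
         validity = function(object) {
           if (length(object@channels) == 0) return("at least one channel")
           if (is.null(names(object@channels)) ||
               any(!nzchar(names(object@channels))))
             return("channels must be named")
           d <- dim(object@channels[[1]])
           ok <- vapply(object@channels,
                        function(ch) identical(dim(ch), d), logical(1))
           if (!all(ok)) return("all channels must share one shape")
           TRUE
         })

#' DiffeoTransform: an invertible dense deformation
#'
#' Dimension-generic (2D unfolded or 3D volumetric) diffeomorphic transform.
#' Transforms follow the resampling (pull-back) convention: the transform
#' maps fixed-space grid coordinates to moving-space coordinates via
#' x + u(x), where u is the forward displacement in pixels. Transforms
#' produced by the registration engine are parameterized by a stationary
#' velocity field and exponentiated by scaling-and-squaring, which keeps the
#' Jacobian determinant positive; composed or numerically inverted
#' transforms store the dense displacement directly.
#'
#' @slot velocity list of per-axis velocity component arrays (empty for
#'   displacement-parameterized transforms).
#' @slot disp list of per-axis forward displacement component arrays (px).
#' @slot shape integer grid shape.
#' @slot spacing physical pixel spacing (mm per px).
#' @slot kind "svf" (stationary velocity) or "disp" (dense displacement).
#' @export
setClass("DiffeoTransform",
         representation(velocity = "list", disp = "list", shape = "integer",
                        spacing = "numeric", kind = "character"),
         validity = function(object) {
           nd <- length(object@shape)
           if (!nd %in% 2:3) return("shape must have length 2 or 3")
           if (length(object@disp) != nd)
             return("one displacement component per axis")
           if (!object@kind %in% c("svf", "disp"))
             return("kind must be 'svf' or 'disp'")
           for (u in object@disp)
             if (!identical(as.integer(dim(u)), object@shape))
               return("displacement components must match shape")
           TRUE
         })

#' RigidTransform: a 3D rigid world-coordinate map
#'
#' Pull-back convention: maps fixed-space world coordinates (mm) to
#' moving-space world coordinates via x_mov = R x_fix + t.
#'
#' @slot rotation 3x3 proper rotation matrix.
#' @slot translation length-3 translation (mm).
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"),
         validity = function(object) {
           if (!all(dim(object@rotation) == c(3, 3)))
             return("rotation must be 3x3")
           if (abs(det(object@rotation) - 1) > 1e-6)
             return("rotation must be proper (det = +1)")
           if (length(object@translation) != 3)
             return("translation must have length 3")
           TRUE
         })

# ---------------------------------------------------------------------------
# show methods

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  tab <- table(object@voxels[object@voxels != 0])
  cat(sprintf("LabelVolume %dx%dx%d, spacing %s mm\n", d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = "x")))
  if (length(tab))
    cat("  labels:", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                           collapse = " "), "\n")
})

setMethod("show", "UnfoldedMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("UnfoldedMap '%s' %dx%d (%s), spacing %s mm\n",
              object@channel, d[1], d[2], object@units,
              paste(signif(object@spacing, 4), collapse = "x")))
})

setMethod("show", "CoordinateFields", function(object) {
  cat(sprintf("CoordinateFields over %d gray-matter voxels (grid %s)\n",
              sum(object@mask), paste(dim(object@mask), collapse = "x")))
})

setMethod("show", "SurfaceGrid", function(object) {
  d <- dim(object@xyz)
  cat(sprintf("SurfaceGrid %dx%d, %d valid nodes, extent %s mm\n",
              d[1], d[2], sum(object@valid),
              paste(object@extent, collapse = "x")))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@channels[[1]])
  std <- if (nrow(object@standardization)) "standardized" else "raw"
  cat(sprintf("FeatureStack %dx%d [%s] (%s)\n", d[1], d[2],
              paste(names(object@channels), collapse = ", "), std))
})

setMethod("show", "DiffeoTransform", function(object) {
  mags <- sqrt(Reduce(`+`, lapply(object@disp, function(u) u^2)))
  cat(sprintf("DiffeoTransform (%s, %dD) %s, max |u| = %.3f px\n",
              object@kind, length(object@shape),
              paste(object@shape, collapse = "x"), max(mags)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%s) mm\n",
              ang * 180 / pi,
              paste(signif(object@translation, 4), collapse = ", ")))
})
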