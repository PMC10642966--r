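# Label propagation: carry subfield labels between samples through the
# concatenated unfolded transforms, project them into the reference sample's
# native space, and fill sampling gaps by nearest-neighbour imputation.
# Labels are categorical, so every lookup along the way is nearest-pixel.

#' Propagate unfolded subfield labels to the reference sample
#'
#' Given the template-building transforms (each mapping template-grid
#' coordinates to its sample's grid coordinates under the pull-back
#' convention), resamples sample i's unfolded labels into the reference
#' sample's unfolded space: each reference pixel is mapped into template
#' space through the inverse of the reference transform and on into sample
#' i through sample i's transform, where the label is read nearest-neighbour.
#' Passing identity transforms gives the unfolding-only (no registration)
#' baseline.
#'
#' @param labels_i [UnfoldedMap-class] of sample i's subfield labels.
#' @param t_i sample i's transform from [buildTemplate()].
#' @param t_ref the reference sample's transform from the same run.
#' @return an [UnfoldedMap-class] of labels in reference unfolded space.
#' @export
propagateLabelsUnfolded <- function(labels_i, t_i, t_ref) {
  v <- labels_i@values
  if (!identical(as.integer(dim(v)), t_i@shape) ||
      !identical(t_i@shape, t_ref@shape))
    stop("grid mismatch between labels and transforms")
  chain <- composeTransforms(invertTransform(t_ref), t_i)
  out <- applyTransform(matrix(as.integer(v), nrow(v), ncol(v)), chain,
                        interp = "nearest")
  labels_i@values <- matrix(as.integer(out), nrow(v), ncol(v))
  labels_i
}

#' Project unfolded labels into the reference native space
#'
#' Assigns every gray-matter voxel of the reference volume the unfolded
#' label at its (ap, pd) coordinate (nearest grid pixel); the whole laminar
#' column inherits the label, consistent with subfields being full-thickness
#' parcels. Non-gray voxels keep 0.
#'
#' @param ref_coords the reference sample's [CoordinateFields-class].
#' @param unfolded_labels an [UnfoldedMap-class] of labels.
#' @param ref_vol the reference [LabelVolume-class] (for geometry).
#' @return a [LabelVolume-class] of propagated labels.
#' @export
projectToNative <- function(ref_coords, unfolded_labels, ref_vol) {
  m <- ref_coords@mask
  shape <- dim(unfolded_labels@values)
  out <- array(0L, dim(m))
  ap <- ref_coords@ap[m]
  pd <- ref_coords@pd[m]
  miss <- is.na(ap) | is.na(pd)
  if (any(miss)) {
    ap[miss] <- 0.5
    pd[miss] <- 0.5
  }
  i <- pmin(pmax(ceiling(ap * shape[1]), 1L), shape[1])
  j <- pmin(pmax(ceiling(pd * shape[2]), 1L), shape[2])
  lab <- as.integer(unfolded_labels@values)[i + (j - 1L) * shape[1]]
  lab[miss] <- 0L
  out[m] <- lab
  new("LabelVolume", voxels = out, affine = ref_vol@affine,
      spacing = ref_vol@spacing)
}

#' Impute missing unfolded labels by nearest neighbour
#'
#' Replaces every 0-valued pixel with the label of the nearest non-zero
#' pixel (Euclidean distance in unfolded mm); at exactly equal distance the
#' smaller label id wins, making the result deterministic.
#'
#' @param map an [UnfoldedMap-class] label image.
#' @return the imputed [UnfoldedMap-class].
#' @export
imputeMissing <- function(map) {
  v <- map@values
  if (all(v == 0)) stop("cannot impute an all-zero label map")
  out <- cpp_impute_nearest(as.integer(v), dim(v), map@spacing)
  map@values <- matrix(as.integer(out), nrow(v), ncol(v))
  map
}

#' Mirror a volume about the world sagittal plane
#'
#' Flips handedness by negating the world x axis (labels and voxel data are
#' untouched; only the affine changes), so right hippocampi can be pooled
#' with left ones before volumetric registration.
#'
#' @param vol a [LabelVolume-class].
#' @return the mirrored [LabelVolume-class].
#' @export
flipLR <- function(vol) {
  M <- diag(c(-1, 1, 1, 1))
  new("LabelVolume", voxels = vol@voxels, affine = M %*% vol@affine,
      spacing = vol@spacing)
}
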