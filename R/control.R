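# Conventional 3D volumetric control condition: idealized-contrast
# registration of binarized gray-matter masks. Right hemispheres are
# mirrored, masks are rigidly aligned to the reference by two-moment
# initialization, resampled to a common working grid, lightly smoothed (so
# binary images have usable gradients), and registered with the same
# diffeomorphic engine in 3D, unimodally. Subfield labels then ride through
# the concatenated transforms into reference native space and are sampled
# at the reference mid-thickness surface for unfolded-space evaluation.

#' Volumetric control parameters
#'
#' @param resolution_mm working isovoxel resolution for the 3D
#'   registrations (must be >= the native resolution).
#' @param mask_sigma_vox Gaussian smoothing of the binary masks (voxels).
#' @param reg a [regParams()] list for the 3D engine.
#' @param margin_mm padding around the reference mask bounding box.
#' @return a `ControlParams` list.
#' @export
controlParams <- function(resolution_mm = 0.5, mask_sigma_vox = 1,
                          reg = regParams(iterations = c(60L, 40L, 20L)),
                          margin_mm = 4) {
  structure(list(resolution_mm = resolution_mm,
                 mask_sigma_vox = mask_sigma_vox, reg = reg,
                 margin_mm = margin_mm),
            class = "ControlParams")
}

binarizeGray <- function(vol) {
  v <- array(as.integer(voxelData(vol) %in% .GRAY_LABELS),
             dim(voxelData(vol)))
  new("LabelVolume", voxels = v, affine = vol@affine, spacing = vol@spacing)
}

#' Run the 3D volumetric control condition
#'
#' Executes the full control pipeline on a cohort of labelled volumes and
#' propagates each sample's subfield labels into the reference sample's
#' native space and unfolded space. Hemisphere metadata decides which
#' samples are mirrored before rigid alignment.
#'
#' @param cohort list of [LabelVolume-class] objects.
#' @param hemispheres character vector ("left"/"right") per sample.
#' @param ref_index reference sample (evaluation target).
#' @param ref_coords the reference sample's [CoordinateFields-class].
#' @param ref_grid the reference sample's [SurfaceGrid-class].
#' @param params a [controlParams()] list.
#' @param verbose print stage progress.
#' @return list with per-sample elements `native` ([LabelVolume-class]
#'   propagated labels in reference native space) and `unfolded`
#'   (imputed [UnfoldedMap-class]); the reference maps to itself.
#' @export
runVolumetricCondition <- function(cohort, hemispheres, ref_index = 1L,
                                   ref_coords, ref_grid,
                                   params = controlParams(),
                                   verbose = FALSE) {
  n <- length(cohort)
  stage <- function(s, what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("control condition failed at stage '%s' for sample %d: %s",
                   what, s, conditionMessage(e))))
  }
  res <- params$resolution_mm
  native_res <- max(vapply(cohort, function(v) max(v@spacing), numeric(1)))
  if (res < native_res - 1e-9)
    stop("working resolution must be >= native resolution")

  # stages 1-2: binarize gray matter, mirror right hemispheres
  masks <- lapply(seq_len(n), function(s) stage(s, "binarize+flip", {
    b <- binarizeGray(cohort[[s]])
    if (hemispheres[s] == "right") flipLR(b) else b
  }))

  # stage 3: rigid moment initialization to the reference
  rigids <- lapply(seq_len(n), function(s) stage(s, "rigid", {
    if (s == ref_index)
      new("RigidTransform", rotation = diag(3), translation = rep(0, 3))
    else momentRigidInit(masks[[ref_index]], masks[[s]])
  }))

  # stage 4: common working grid around the reference mask
  wref <- maskWorldCoords(masks[[ref_index]])
  lo <- apply(wref, 2, min) - params$margin_mm
  hi <- apply(wref, 2, max) + params$margin_mm
  wdims <- as.integer(ceiling((hi - lo) / res)) + 1L
  waff <- diag(c(res, res, res, 1))
  waff[1:3, 4] <- lo
  wpts_world <- voxToWorld(gridPoints(wdims), waff)

  resampled <- lapply(seq_len(n), function(s) stage(s, "resample", {
    wmov <- applyRigid(rigids[[s]], wpts_world)
    vox <- worldToVox(wmov, masks[[s]]@affine)
    vals <- cpp_interp_linear(as.numeric(voxelData(masks[[s]])),
                              dim(voxelData(masks[[s]])), vox)
    d <- dim(voxelData(masks[[s]]))
    inside <- vox[, 1] > -1 & vox[, 2] > -1 & vox[, 3] > -1 &
      vox[, 1] < d[1] & vox[, 2] < d[2] & vox[, 3] < d[3]
    vals[!inside] <- 0
    array(vals, wdims)
  }))

  # stage 5: light smoothing so binary masks have gradient support
  smoothed <- lapply(seq_len(n), function(s) stage(s, "smooth", {
    array(cpp_gauss_smooth(as.numeric(resampled[[s]]), wdims,
                           rep(params$mask_sigma_vox, 3)), wdims)
  }))

  # stage 6: unimodal 3D template building with the shared engine
  stacks <- lapply(smoothed, function(m)
    new("FeatureStack", channels = list(mask = m),
        standardization = data.frame(channel = character(),
                                     mean = numeric(), sd = numeric()),
        spacing = rep(res, 3)))
  tmpl <- tryCatch(buildTemplate(stacks, n_iter = 4L, params = params$reg,
                                 verbose = verbose),
                   error = function(e)
                     stop("control condition failed at stage 'template': ",
                          conditionMessage(e)))

  # stage 7: propagate subfield labels into reference native space
  ref_vol <- cohort[[ref_index]]
  gm <- grayMask(ref_vol)
  gidx <- which(gm, arr.ind = TRUE) - 1
  gw <- voxToWorld(gidx, ref_vol@affine)
  if (hemispheres[ref_index] == "right") gw[, 1] <- -gw[, 1]
  gvox_w <- worldToVox(gw, waff)  # reference gray voxels on the working grid
  t_ref_inv <- invertTransform(tmpl$transforms[[ref_index]])

  out <- vector("list", n)
  for (s in seq_len(n)) {
    out[[s]] <- stage(s, "propagate", {
      # working-grid coords -> template -> sample s grid -> world -> labels
      p_t <- gvox_w + sampleDisp(t_ref_inv@disp, wdims, gvox_w)
      p_s <- p_t + sampleDisp(tmpl$transforms[[s]]@disp, wdims, p_t)
      x_w <- voxToWorld(p_s, waff)
      x_m <- applyRigid(rigids[[s]], x_w)
      lab_vol <- voxelData(cohort[[s]])
      if (hemispheres[s] == "right") x_m[, 1] <- -x_m[, 1]
      vox_m <- worldToVox(x_m, cohort[[s]]@affine)
      lab <- as.integer(round(cpp_interp_nearest(as.numeric(lab_vol),
                                                 dim(lab_vol), vox_m)))
      lab[!(lab %in% .GRAY_LABELS)] <- 0L
      nat <- array(0L, dim(gm))
      nat[gm] <- lab
      nat_vol <- new("LabelVolume", voxels = nat, affine = ref_vol@affine,
                     spacing = ref_vol@spacing)
      # stage 8: sample at the reference mid-thickness surface
      unf <- sampleLabelsToUnfolded(nat_vol, ref_grid)
      # stage 9: impute missing values in unfolded space
      unf <- imputeMissing(unf)
      list(native = nat_vol, unfolded = unf)
    })
  }
  out
}
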