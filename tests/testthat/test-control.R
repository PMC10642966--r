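test_that("the volumetric control recovers identical phantoms almost perfectly", {
  # three copies of one shape (mixed hemispheres, shifted origins): the
  # control pipeline should map subfields onto the reference nearly
  # voxel-exactly
  mk <- function(hemi, origin) {
    p <- phantomParams(hemisphere = hemi, origin_mm = origin)
    generatePhantom(p, grid_shape = c(32L, 16L))
  }
  coh <- list(mk("left", c(0, 0, 0)), mk("right", c(3, -2, 1)),
              mk("left", c(-2, 1, 2)))
  vols <- lapply(coh, function(s) s$labels)
  hem <- c("left", "right", "left")
  f1 <- suppressWarnings(
    computeSampleFeatures(vols[[1]], shape = c(32, 16), extent = c(40, 20)))
  res <- runVolumetricCondition(
    vols, hem, 1L, f1$coords, f1$grid,
    controlParams(reg = regParams(iterations = c(40L, 30L, 15L))))
  expect_length(res, 3)
  ref <- voxelData(vols[[1]])
  ref[!(ref %in% 1:5)] <- 0L
  refvol <- new("LabelVolume", voxels = ref,
                affine = worldAffine(vols[[1]]),
                spacing = voxelSpacing(vols[[1]]))
  for (s in 2:3) {
    d <- diceScores(refvol, res[[s]]$native)
    expect_gt(mean(d, na.rm = TRUE), 0.9)
    # unfolded output fully labelled after imputation
    expect_true(all(mapValues(res[[s]]$unfolded) %in% 1:5))
  }
})

test_that("the control refuses a working resolution finer than native", {
  coh <- generateCohort(2, seed = 3, grid_shape = c(16L, 8L))
  vols <- lapply(coh, function(s) s$labels)
  f1 <- suppressWarnings(
    computeSampleFeatures(vols[[1]], shape = c(16, 8), extent = c(40, 20)))
  expect_error(
    runVolumetricCondition(vols, c("left", "right"), 1L, f1$coords, f1$grid,
                           controlParams(resolution_mm = 0.2)),
    "working resolution")
})
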