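test_that("identity transforms give a verbatim label copy", {
  ph <- defaultPhantom()
  labs <- sampleLabelsToUnfolded(ph$labels, defaultGrid())
  ident <- identityTransform(c(64, 32), pixelSpacing(labs))
  out <- propagateLabelsUnfolded(labs, ident, ident)
  expect_identical(mapValues(out), mapValues(labs))
})

test_that("propagating through a sample's own transform is self-consistent", {
  ph <- defaultPhantom()
  labs <- sampleLabelsToUnfolded(ph$labels, defaultGrid())
  t <- makeSyntheticWarp(c(64, 32), 3, 8, seed = 7)
  out <- propagateLabelsUnfolded(labs, t, t)
  d <- diceScores(labs, out)
  expect_true(all(d[!is.nan(d)] == 1))
})

test_that("native projection round-trips the sample's own labels", {
  ph <- defaultPhantom()
  co <- defaultCoords()
  unf <- imputeMissing(sampleLabelsToUnfolded(ph$labels, defaultGrid()))
  nat <- projectToNative(co, unf, ph$labels)
  ref <- voxelData(ph$labels)
  ref[!(ref %in% 1:5)] <- 0L
  refvol <- new("LabelVolume", voxels = ref, affine = worldAffine(ph$labels),
                spacing = voxelSpacing(ph$labels))
  d <- diceScores(refvol, nat)
  expect_true(all(d > 0.9))
  expect_gt(mean(d), 0.95)
  # non-gray voxels stay 0
  expect_true(all(voxelData(nat)[!grayMask(refvol)] == 0L))
})

test_that("labels confined to the proximal half stay proximal in native space", {
  ph <- defaultPhantom()
  co <- defaultCoords()
  v <- matrix(0L, 64, 32)
  v[, 1:16] <- 2L
  half <- unfoldedMap(v, channel = "subfields", units = "label",
                      extent = c(40, 20))
  nat <- projectToNative(co, half, ph$labels)
  labelled <- voxelData(nat) == 2L
  expect_true(all(co@pd[labelled] <= 0.5 + 1 / 32))
  # empty map -> all gray voxels 0
  none <- unfoldedMap(matrix(0L, 64, 32), channel = "subfields",
                      units = "label", extent = c(40, 20))
  nat0 <- projectToNative(co, none, ph$labels)
  expect_true(all(voxelData(nat0) == 0L))
})

test_that("imputation fills gaps deterministically with the nearest label", {
  m <- matrix(2L, 9, 9)
  m[5, 5] <- 0L
  um <- unfoldedMap(m, channel = "subfields", units = "label",
                    extent = c(9, 9))
  expect_identical(mapValues(imputeMissing(um))[5, 5], 2L)

  # no zeros: unchanged
  expect_identical(mapValues(imputeMissing(um)),
                   mapValues(imputeMissing(imputeMissing(um))))

  # equidistant tie goes to the smaller label id
  tie <- matrix(0L, 5, 5)
  tie[1, ] <- 2L  # CA1
  tie[5, ] <- 1L  # Sub
  ut <- unfoldedMap(tie, channel = "subfields", units = "label",
                    extent = c(5, 5))
  filled <- mapValues(imputeMissing(ut))
  expect_identical(filled[3, 3], 1L)  # Sub wins the exact tie

  zero <- unfoldedMap(matrix(0L, 4, 4), channel = "subfields",
                      units = "label", extent = c(4, 4))
  expect_error(imputeMissing(zero), "all-zero")
})

test_that("hemisphere flip is an involution that mirrors world coordinates", {
  ph <- defaultPhantom()
  f2 <- flipLR(flipLR(ph$labels))
  expect_identical(voxelData(f2), voxelData(ph$labels))
  expect_equal(worldAffine(f2), worldAffine(ph$labels))

  w <- unfoldreg:::maskWorldCoords(unfoldreg:::binarizeGray(ph$labels))
  wf <- unfoldreg:::maskWorldCoords(
    unfoldreg:::binarizeGray(flipLR(ph$labels)))
  expect_equal(mean(wf[, 1]), -mean(w[, 1]), tolerance = 1e-9)
  expect_equal(mean(wf[, 2]), mean(w[, 2]), tolerance = 1e-9)
})

test_that("flipping a right phantom improves rigid overlap with a left one", {
  left <- defaultPhantom()
  pr <- phantomParams()
  pr$hemisphere <- "right"
  right <- generatePhantom(pr)
  bl <- unfoldreg:::binarizeGray(left$labels)
  br <- unfoldreg:::binarizeGray(right$labels)
  brf <- unfoldreg:::binarizeGray(flipLR(right$labels))
  ov <- function(moving) {
    r <- momentRigidInit(bl, moving)
    unfoldreg:::rigidOverlap(bl, moving, r@rotation, r@translation)
  }
  expect_gt(ov(brf), ov(br))
})
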