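test_that("phantom generation is deterministic and labels are exactly the declared scheme", {
  p <- phantomParams()
  a <- generatePhantom(p, seed = 5)
  b <- generatePhantom(p, seed = 5)
  expect_identical(voxelData(a$labels), voxelData(b$labels))
  expect_identical(worldAffine(a$labels), worldAffine(b$labels))
  expect_identical(sort(unique(as.vector(voxelData(a$labels)))), 0:10)
})

test_that("truth coordinates are in [0,1] and monotone along the sheet axes", {
  ph <- defaultPhantom()
  tc <- ph$truth_coords
  m <- grayMask(tc)
  for (f in list(tc@ap[m], tc@pd[m], tc@io[m])) {
    expect_true(all(is.finite(f)))
    expect_gte(min(f), 0)
    expect_lte(max(f), 1)
  }
  # u increases along the anterior-posterior (y) voxel axis, v along the
  # arc: check rank correlation against the voxel grid where applicable
  idx <- which(m, arr.ind = TRUE)
  expect_gt(cor(tc@ap[m], idx[, 2], method = "spearman"), 0.99)
})

test_that("gray-matter volume matches surface area times mean thickness", {
  ph <- defaultPhantom()
  p <- ph$params
  vol <- sum(voxelData(ph$labels) %in% 1:5) * p$voxel_mm^3
  us <- seq(0, 1, length.out = 4001)
  stretch <- mean(sqrt(1 + (2 * pi * p$n_gyri * p$gyral_amplitude_mm *
                              cos(2 * pi * p$n_gyri * us + p$phase) /
                              p$length_mm)^2))
  expected <- p$length_mm * p$arc_mm * stretch *
    sum(p$subfield_fractions * p$thickness_profile * p$thickness_scale)
  expect_lt(abs(vol - expected) / expected, 0.15)
})

test_that("unfolded truth label columns match the subfield fractions", {
  fr <- c(0.30, 0.30, 0.05, 0.15, 0.20)
  ph <- generatePhantom(phantomParams(subfield_fractions = fr))
  tl <- mapValues(ph$truth_unfolded_labels)
  got <- as.numeric(table(factor(tl, levels = 1:5))) / length(tl)
  # within one pixel column of a 128-column grid
  expect_true(all(abs(got - fr) <= 1 / 128 + 1e-12))
})

test_that("too-coarse voxels are rejected with advice", {
  expect_error(generatePhantom(phantomParams(voxel_mm = 0.8)),
               "finer resolution")
})

test_that("cohorts have the prescribed hemisphere mix and valid fractions", {
  coh <- generateCohort(7, seed = 42, grid_shape = c(16L, 8L))
  expect_length(coh, 7)
  hem <- vapply(coh, function(s) s$params$hemisphere, character(1))
  expect_identical(sum(hem == "left"), 4L)
  expect_identical(sum(hem == "right"), 3L)
  for (s in coh) {
    expect_equal(sum(s$params$subfield_fractions), 1, tolerance = 1e-9)
    expect_true(all(s$params$subfield_fractions > 0))
  }
  # deterministic
  coh2 <- generateCohort(7, seed = 42, grid_shape = c(16L, 8L))
  expect_identical(voxelData(coh2[[3]]$labels), voxelData(coh[[3]]$labels))
})

test_that("zero jitter yields identical samples up to hemisphere and origin", {
  novar <- list(n_gyri = 0L, amplitude_rel = 0, thickness_rel = 0,
                fraction_conc = 1e9, offset_mm = 0)
  coh <- generateCohort(3, variation = novar, seed = 1,
                        grid_shape = c(16L, 8L))
  p1 <- coh[[1]]$params
  p3 <- coh[[3]]$params
  expect_equal(p1$gyral_amplitude_mm, p3$gyral_amplitude_mm)
  expect_equal(p1$subfield_fractions, p3$subfield_fractions,
               tolerance = 1e-3)
  expect_identical(p1$hemisphere, p3$hemisphere)  # both left
})

test_that("synthetic warps honour their amplitude and stay diffeomorphic", {
  w0 <- makeSyntheticWarp(c(64, 32), 0, 6, seed = 1)
  expect_equal(max(dispMagnitude(w0)), 0)

  w <- makeSyntheticWarp(c(64, 32), 5, 12, seed = 1)
  mx <- max(dispMagnitude(w))
  expect_lt(abs(mx - 5) / 5, 0.10)
  expect_gt(min(mapValues(jacobianDeterminant(w))), 0)

  w2 <- makeSyntheticWarp(c(64, 32), 5, 12, seed = 2)
  expect_gt(max(abs(forwardDisplacement(w)[[1]] -
                      forwardDisplacement(w2)[[1]])), 0)
})
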