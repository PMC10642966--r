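test_that("flat-slab thickness recovers the true 2 mm within 5%", {
  ph <- flatSlabPhantom()
  th <- computeThickness(flatSlabCoords(), flatSlabGrid(), ph$labels)
  m <- mean(mapValues(th), na.rm = TRUE)
  expect_lt(abs(m - 2) / 2, 0.05)
  expect_true(all(mapValues(th) > 0, na.rm = TRUE))
})

test_that("a doubled thickness profile yields a doubled unfolded thickness", {
  # thicknesses chosen as integer multiples of the voxel size, where the
  # laminar quantization vanishes
  pp <- phantomParams(curl_angle_rad = 1e-9, n_gyri = 0L,
                      gyral_amplitude_mm = 0,
                      thickness_profile = c(3.0, 2.0, 1.5, 2.0, 2.5),
                      subfield_fractions = rep(0.2, 5))
  ph <- generatePhantom(pp)
  co <- computeCoordinates(ph$labels)
  g <- extractMidthicknessGrid(co, ph$labels, shape = c(64, 32),
                               extent = c(40, 20))
  th <- mapValues(computeThickness(co, g, ph$labels))
  sub_band <- mean(th[10:54, 2:5], na.rm = TRUE)   # Sub: 3.0 mm
  ca2_band <- mean(th[10:54, 15:18], na.rm = TRUE) # CA2: 1.5 mm
  expect_lt(abs(sub_band / ca2_band - 2) / 2, 0.10)
})

test_that("an all-NA io field is rejected", {
  co <- flatSlabCoords()
  co@io[] <- NA_real_
  expect_error(computeThickness(co, flatSlabGrid(), flatSlabPhantom()$labels),
               "all-NA")
})

test_that("gyrification is 1 on an isometric flat sheet and conserves area", {
  g <- flatSlabGrid()
  gi <- mapValues(computeGyrification(g))
  expect_lt(abs(mean(gi, na.rm = TRUE) - 1), 0.05)

  # area conservation: mean(GI) * unfolded area matches the mesh area
  xyz <- nodeCoordinates(g)
  d <- dim(xyz)[1:2]
  A <- xyz[-d[1], -d[2], , drop = FALSE]
  B <- xyz[-1, -d[2], , drop = FALSE]
  C <- xyz[-1, -1, , drop = FALSE]
  D <- xyz[-d[1], -1, , drop = FALSE]
  mesh_area <- sum(unfoldreg:::triArea(A, B, C) +
                     unfoldreg:::triArea(A, C, D))
  unf_area <- prod(g@extent)
  expect_lt(abs(mean(gi, na.rm = TRUE) * unf_area - mesh_area) / mesh_area,
            0.10)
})

test_that("folding increases mean gyrification", {
  gi_folded <- mapValues(computeGyrification(defaultGrid()))
  gi_flat <- mapValues(computeGyrification(flatSlabGrid()))
  expect_gt(mean(gi_folded, na.rm = TRUE), mean(gi_flat, na.rm = TRUE))
})

test_that("curvature is zero on a plane and 1/(2r) on a cylinder shell", {
  flatH <- mapValues(computeCurvature(flatSlabGrid(), flatSlabCoords(),
                                      flatSlabPhantom()$labels))
  expect_lt(max(abs(flatH), na.rm = TRUE), 0.005)

  # arc 20 mm with total curl 2 rad -> radius 10 mm, |H| = 0.05 / mm
  pp <- phantomParams(curl_angle_rad = 2, n_gyri = 0L,
                      gyral_amplitude_mm = 0, thickness_profile = rep(2, 5))
  ph <- generatePhantom(pp)
  co <- computeCoordinates(ph$labels)
  g <- extractMidthicknessGrid(co, ph$labels, shape = c(64, 32),
                               extent = c(40, 20))
  H <- mapValues(computeCurvature(g, co, ph$labels))
  interior <- abs(mean(H[8:56, 5:28], na.rm = TRUE))
  expect_lt(abs(interior - 0.05) / 0.05, 0.10)
})

test_that("gyral waves produce oscillating curvature along A-P", {
  ph <- defaultPhantom()  # n_gyri = 3
  H <- mapValues(computeCurvature(defaultGrid(), defaultCoords(),
                                  ph$labels))
  row <- H[, 16]
  row <- row[is.finite(row)]
  crossings <- sum(diff(sign(row)) != 0)
  expect_gte(crossings, 5)  # three sign-change pairs, edges may clip one
})

test_that("feature stacks standardize channels and reject degenerate input", {
  st <- defaultStack()
  for (ch in channels(st)) {
    expect_lt(abs(mean(ch)), 1e-9)
    expect_lt(abs(stats::sd(ch) - 1), 1e-9)
  }
  expect_identical(sort(names(channels(st))),
                   c("curvature", "gyrification", "thickness"))
  expect_equal(nrow(st@standardization), 3L)

  # channel subsets for the ablation
  ph <- defaultPhantom()
  maps <- list(curvature = computeCurvature(defaultGrid(), defaultCoords(),
                                            ph$labels))
  st1 <- prepareFeatureStack(maps)
  expect_identical(names(channels(st1)), "curvature")

  flat <- unfoldedMap(matrix(1, 16, 8), channel = "constant")
  expect_error(prepareFeatureStack(list(constant = flat)), "zero variance")
})
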