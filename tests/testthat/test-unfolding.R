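test_that("Laplace solution on a slab is the analytic linear ramp", {
  dims <- c(3, 3, 21)
  dom <- array(FALSE, dims); dom[2, 2, 2:20] <- TRUE
  src <- array(FALSE, dims); src[2, 2, 1] <- TRUE
  snk <- array(FALSE, dims); snk[2, 2, 21] <- TRUE
  f <- solveLaplace(dom, src, snk, tol = 1e-7)
  expect_lt(max(abs(f[2, 2, ] - (0:20) / 20)), 1e-3)
  expect_equal(f[2, 2, 11], 0.5, tolerance = 1e-5)
  expect_true(all(is.na(f[1, 1, ])))
})

test_that("solver contract violations raise errors", {
  dims <- c(3, 3, 9)
  dom <- array(FALSE, dims); dom[2, 2, 2:8] <- TRUE
  src <- array(FALSE, dims); src[2, 2, 1] <- TRUE
  expect_error(solveLaplace(dom, src, src), "overlap")
  expect_error(solveLaplace(dom, src & FALSE, src), "empty source")
  # disconnected domain: a second component with no boundary
  dom2 <- dom; dom2[1, 1, 4:6] <- TRUE
  snk <- array(FALSE, dims); snk[2, 2, 9] <- TRUE
  expect_error(solveLaplace(dom2, src, snk), "no source-to-sink path")
})

test_that("coordinate fields recover the phantom's intrinsic axes", {
  ph <- defaultPhantom()
  co <- defaultCoords()
  m <- grayMask(co)
  expect_gt(cor(co@ap[m], ph$truth_coords@ap[m], method = "spearman"), 0.98)
  expect_gt(cor(co@pd[m], ph$truth_coords@pd[m], method = "spearman"), 0.98)
  # Dirichlet values exact at the boundary labels
  v <- voxelData(ph$labels)
  expect_true(all(abs(co@io[m]) <= 1))
})

test_that("straight phantom fields are accurate and monotone", {
  ph <- flatSlabPhantom()
  co <- flatSlabCoords()
  m <- grayMask(co)
  tc <- ph$truth_coords
  expect_lt(mean(abs(co@ap[m] - tc@ap[m])), 0.05)
  expect_lt(mean(abs(co@pd[m] - tc@pd[m])), 0.05)
  # io carries a half-voxel boundary compression at 0.5 mm voxels: its
  # Dirichlet values sit at cell centres half a voxel outside the tissue
  expect_lt(mean(abs(co@io[m] - tc@io[m])), 0.06)
  expect_gt(cor(co@io[m], tc@io[m]), 0.97)
})

test_that("missing required labels are reported by name", {
  ph <- flatSlabPhantom()
  v <- voxelData(ph$labels)
  v[v == 6L] <- 0L
  broken <- new("LabelVolume", voxels = v, affine = worldAffine(ph$labels),
                spacing = voxelSpacing(ph$labels))
  expect_error(computeCoordinates(broken), "missing label 6")
})

test_that("pd is mirror-consistent between hemispheres", {
  base <- phantomParams()
  left <- generatePhantom(base)
  pr <- base; pr$hemisphere <- "right"
  right <- generatePhantom(pr)
  col <- computeCoordinates(left$labels)
  cor_ <- computeCoordinates(right$labels)
  # the right phantom is the mirror image: same pd distribution vs truth
  ml <- grayMask(col); mr <- grayMask(cor_)
  el <- mean(abs(col@pd[ml] - left$truth_coords@pd[ml]))
  er <- mean(abs(cor_@pd[mr] - right$truth_coords@pd[mr]))
  expect_lt(abs(el - er), 0.01)
})

test_that("mid-thickness grid has the configured shape and lies on the surface", {
  ph <- flatSlabPhantom()
  g <- flatSlabGrid()
  expect_identical(dim(nodeCoordinates(g))[1:2], c(64L, 32L))
  # flat slab: nodes form a plane to sub-voxel tolerance
  P <- matrix(nodeCoordinates(g), ncol = 3)
  P <- P[as.logical(validNodes(g)), ]
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  expect_lt(max(abs(sweep(P, 2, ctr) %*% sv$v[, 3])),
            voxelSpacing(ph$labels)[1])

  # default grid shape
  co <- defaultCoords()
  g2 <- extractMidthicknessGrid(co, defaultPhantom()$labels)
  expect_identical(dim(nodeCoordinates(g2))[1:2], c(256L, 128L))

  # too few supporting voxels
  co_small <- co
  co_small@io[] <- NA_real_
  expect_error(extractMidthicknessGrid(co_small, defaultPhantom()$labels),
               "too coarse")
})

test_that("folding increases native arc length over the flat extent", {
  g <- defaultGrid()  # n_gyri = 3 phantom
  xyz <- nodeCoordinates(g)
  mid <- 16L
  seg <- sqrt(apply((xyz[-1, mid, ] - xyz[-64, mid, ])^2, 1, sum))
  arc <- sum(seg)
  expect_gt(arc, 40)  # straight-line A-P extent is 40 mm
})

test_that("phantom surface nodes lie within one voxel of the true surface", {
  ph <- flatSlabPhantom()
  g <- flatSlabGrid()
  xyz <- nodeCoordinates(g)
  nr <- dim(xyz)[1]; nc <- dim(xyz)[2]
  uv <- cbind(rep((seq_len(nr) - 0.5) / nr, nc),
              rep((seq_len(nc) - 0.5) / nc, each = nr))
  truth <- unfoldreg:::phantomSurface(uv[, 1], uv[, 2], ph$params)$S
  err <- sqrt(rowSums((matrix(xyz, ncol = 3) - truth)^2))
  expect_lt(max(err[as.logical(validNodes(g))]),
            2 * voxelSpacing(ph$labels)[1])
})
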