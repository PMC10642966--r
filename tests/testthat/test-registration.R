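test_that("self-registration returns a near-identity transform", {
  st <- defaultStack()
  t <- registerMultichannel(st, st, regParams())
  expect_lt(median(dispMagnitude(t)), 0.25)
  expect_gt(min(mapValues(jacobianDeterminant(t))), 0)
})

test_that("a known synthetic warp is recovered", {
  st <- defaultStack()
  w <- makeSyntheticWarp(c(64, 32), 3, 8, seed = 1)
  fixed <- lapply(channels(st), applyTransform, t = w, interp = "linear")
  rec <- registerMultichannel(fixed, channels(st), regParams())
  ut <- forwardDisplacement(w)
  ur <- forwardDisplacement(rec)
  epe <- sqrt((ut[[1]] - ur[[1]])^2 + (ut[[2]] - ur[[2]])^2)
  expect_lt(mean(epe), 1.0)
  expect_gt(min(mapValues(jacobianDeterminant(rec))), 0)
})

test_that("channel mismatches and empty channels are rejected", {
  st <- defaultStack()
  only_th <- list(thickness = channels(st)$thickness)
  expect_error(registerMultichannel(channels(st), only_th,
                                    regParams()), "channel mismatch")
  nanch <- channels(st)
  nanch$thickness[] <- NaN
  expect_error(registerMultichannel(nanch, nanch, regParams()),
               "no finite values")
})

test_that("transform composition and inversion satisfy the group identities", {
  t <- makeSyntheticWarp(c(64, 32), 3, 8, seed = 3)
  ident <- identityTransform(c(64, 32))
  # compose(identity, t) == t
  ct <- composeTransforms(ident, t)
  expect_lt(max(abs(forwardDisplacement(ct)[[1]] -
                      forwardDisplacement(t)[[1]])), 1e-9)
  # invert(invert(t)) ~ t (exact for velocity-parameterized transforms)
  ii <- invertTransform(invertTransform(t))
  res <- sqrt(Reduce(`+`, Map(function(a, b) (a - b)^2,
                              forwardDisplacement(ii),
                              forwardDisplacement(t))))
  expect_lt(max(res), 0.1)
  # forward o inverse ~ identity
  fw <- composeTransforms(t, invertTransform(t))
  expect_lt(median(dispMagnitude(fw)), 0.1)
  # domain mismatch
  t2 <- makeSyntheticWarp(c(32, 16), 1, 4, seed = 1)
  expect_error(composeTransforms(t, t2), "domain mismatch")
})

test_that("composition matches brute-force point tracing", {
  a <- makeSyntheticWarp(c(64, 32), 3, 8, seed = 1)
  b <- makeSyntheticWarp(c(64, 32), 3, 8, seed = 2)
  cc <- composeTransforms(a, b)
  bilin <- function(u, p) {
    nx <- nrow(u); ny <- ncol(u)
    x <- min(max(p[1], 0), nx - 1); y <- min(max(p[2], 0), ny - 1)
    x0 <- max(min(floor(x), nx - 2), 0); y0 <- max(min(floor(y), ny - 2), 0)
    fx <- x - x0; fy <- y - y0
    (1 - fx) * (1 - fy) * u[x0 + 1, y0 + 1] + fx * (1 - fy) * u[x0 + 2, y0 + 1] +
      (1 - fx) * fy * u[x0 + 1, y0 + 2] + fx * fy * u[x0 + 2, y0 + 2]
  }
  ua <- forwardDisplacement(a); ub <- forwardDisplacement(b)
  uc <- forwardDisplacement(cc)
  set.seed(99)
  errs <- vapply(1:100, function(k) {
    p <- c(runif(1, 0, 63), runif(1, 0, 31))
    q <- p + c(bilin(ua[[1]], p), bilin(ua[[2]], p))
    r <- q + c(bilin(ub[[1]], q), bilin(ub[[2]], q))
    rc <- p + c(bilin(uc[[1]], p), bilin(uc[[2]], p))
    sqrt(sum((r - rc)^2))
  }, numeric(1))
  expect_lt(max(errs), 0.2)
})

test_that("images move correctly through transforms", {
  # identity leaves an image unchanged
  img <- matrix(rnorm(64 * 32), 64, 32)
  ident <- identityTransform(c(64, 32))
  expect_equal(applyTransform(img, ident, "linear"), img)

  # translation by (3, 0) px moves a delta peak 3 px
  shift <- makeDiffeoForTest(c(64, 32), dx = 3)
  delta <- matrix(0, 64, 32); delta[30, 16] <- 1
  moved <- applyTransform(delta, shift, "nearest")
  expect_equal(which(moved == 1, arr.ind = TRUE)[1, ],
               c(row = 27, col = 16))

  # label maps keep their value set and require nearest-neighbour
  lab <- matrix(sample(0:5, 64 * 32, replace = TRUE), 64, 32)
  lab <- matrix(as.integer(lab), 64, 32)
  w <- makeSyntheticWarp(c(64, 32), 3, 8, seed = 4)
  warped <- applyTransform(lab, w, "nearest")
  expect_true(all(warped %in% 0:5))
  expect_error(applyTransform(lab, w, "linear"), "nearest")
})

test_that("Jacobian determinants are exact on analytic fields", {
  ident <- identityTransform(c(32, 16))
  expect_equal(max(abs(mapValues(jacobianDeterminant(ident)) - 1)), 0)
  # uniform 2x dilation: u(x) = x  =>  J = 2I, det = 4
  x <- matrix(rep(0:31, 16), 32, 16)
  y <- matrix(rep(0:15, each = 32), 32, 16)
  dil <- new("DiffeoTransform", velocity = list(),
             disp = list(x, y), shape = c(32L, 16L),
             spacing = c(1, 1), kind = "disp")
  jd <- mapValues(jacobianDeterminant(dil))
  expect_equal(max(abs(jd[2:31, 2:15] - 4)), 0, tolerance = 1e-12)
})

test_that("template building centres identical inputs on themselves", {
  st <- defaultStack()
  tr <- buildTemplate(list(st, st, st), n_iter = 2,
                      params = regParams(iterations = c(40L, 30L, 20L)))
  expect_length(tr$transforms, 3)
  expect_length(tr$history, 2)
  for (t in tr$transforms)
    expect_lt(median(dispMagnitude(t)), 0.25)
  expect_equal(channels(tr$template)$thickness,
               channels(st)$thickness, tolerance = 1e-6)
})

test_that("template variance is non-increasing on a jittered cohort", {
  coh <- generateCohort(4, seed = 11, grid_shape = c(32L, 16L))
  feats <- suppressWarnings(lapply(coh, function(s)
    computeSampleFeatures(s$labels, shape = c(32, 16), extent = c(40, 20))))
  stacks <- lapply(feats, function(f)
    suppressWarnings(prepareFeatureStack(f$maps)))
  tr <- buildTemplate(stacks, n_iter = 3,
                      params = regParams(iterations = c(40L, 30L, 20L)))
  expect_lt(tr$history[3], tr$history[1] + 1e-9)
})

test_that("moment initialization recovers translations and rotations", {
  ph <- defaultPhantom()
  b1 <- unfoldreg:::binarizeGray(ph$labels)
  ph2 <- generatePhantom(phantomParams(origin_mm = c(5, -3, 2)))
  b2 <- unfoldreg:::binarizeGray(ph2$labels)
  r <- momentRigidInit(b1, b2)
  expect_equal(r@translation, c(5, -3, 2), tolerance = 0.5)
  expect_lt(max(abs(r@rotation - diag(3))), 1e-6)

  # identity when fixed == moving
  r0 <- momentRigidInit(b1, b1)
  expect_lt(max(abs(r0@translation)), 1e-6)

  # 30 degree rotation about z of the (anisotropic) phantom
  th <- 30 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  aff <- worldAffine(ph$labels)
  aff2 <- aff
  aff2[1:3, ] <- Rz %*% aff[1:3, ]
  volr <- new("LabelVolume", voxels = voxelData(ph$labels), affine = aff2,
              spacing = voxelSpacing(ph$labels))
  rr <- momentRigidInit(b1, unfoldreg:::binarizeGray(volr))
  ang <- acos(pmin(1, (sum(diag(t(rr@rotation) %*% Rz)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 2)

  # degenerate inputs
  empty <- new("LabelVolume", voxels = array(0L, c(4, 4, 4)),
               affine = diag(4), spacing = rep(1, 3))
  expect_error(momentRigidInit(b1, empty), "empty mask")
  # near-isotropic mask falls back to translation with a warning
  sph <- array(0L, c(21, 21, 21))
  idx <- which(array(TRUE, c(21, 21, 21)), arr.ind = TRUE)
  inside <- sqrt(rowSums((idx - 11)^2)) <= 8
  sph[idx[inside, ]] <- 1L
  svol <- new("LabelVolume", voxels = sph, affine = diag(4),
              spacing = rep(1, 3))
  expect_warning(momentRigidInit(svol, svol), "translation-only")
})
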