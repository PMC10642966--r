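test_that("Dice matches the formula and a brute-force counting oracle", {
  # worked example: |ref| 4, |test| 6, overlap 3 -> 0.6
  ref <- matrix(0L, 4, 4); ref[1:4] <- 1L
  test <- matrix(0L, 4, 4); test[2:7] <- 1L
  expect_equal(unname(diceScores(ref, test, 1L)), 2 * 3 / 10)

  # identity
  expect_equal(unname(diceScores(ref, ref, 1L)), 1)

  # random maps vs explicit set counting
  set.seed(21)
  for (rep in 1:5) {
    a <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
    got <- diceScores(a, b)
    for (L in 1:5) {
      inter <- sum(a == L & b == L)
      denom <- sum(a == L) + sum(b == L)
      want <- if (denom == 0) NaN else 2 * inter / denom
      expect_equal(unname(got[L]), want)
    }
    # symmetry
    expect_equal(diceScores(a, b), diceScores(b, a))
  }
  expect_error(diceScores(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "shape mismatch")
})

test_that("border distances match construction and a pairwise oracle", {
  # 1D toy: boundaries at index 10 and 13, 1 mm spacing -> 3 mm
  ref <- array(0L, c(21, 3, 3))
  ref[1:10, , ] <- 1L; ref[11:21, , ] <- 2L
  tst <- array(0L, c(21, 3, 3))
  tst[1:13, , ] <- 1L; tst[14:21, , ] <- 2L
  bd <- borderDistances(ref, tst, pairs = list(c(1, 2)),
                        spacing = c(1, 1, 1))
  expect_equal(bd$median, 3)
  # identical inputs -> all zero
  bd0 <- borderDistances(ref, ref, pairs = list(c(1, 2)),
                         spacing = c(1, 1, 1))
  expect_true(all(bd0$distances == 0))

  # random crop vs O(n^2) pairwise minimum distance
  set.seed(31)
  sp <- c(0.7, 1.1, 0.9)
  a <- array(sample(0:3, 7^3, replace = TRUE), c(7, 7, 7))
  b <- array(sample(0:3, 7^3, replace = TRUE), c(7, 7, 7))
  got <- suppressWarnings(borderDistances(a, b, pairs = list(c(1, 2)),
                                          spacing = sp))
  rb <- which(unfoldreg:::borderVoxels(a, 1, 2), arr.ind = TRUE)
  tb <- which(unfoldreg:::borderVoxels(b, 1, 2), arr.ind = TRUE)
  if (nrow(rb) && nrow(tb)) {
    oracle <- apply(tb, 1, function(q)
      min(sqrt(colSums((t(rb) * sp - q * sp)^2))))
    expect_lt(max(abs(sort(got$distances) - sort(oracle))), 1e-6)
  }

  # absent pair -> NaN with a warning
  expect_warning(bdna <- borderDistances(ref, tst,
                                         pairs = list(c(3, 4))),
                 "absent")
  expect_true(is.nan(bdna$per_pair[[1]]))
})

test_that("topology checks flag islands and order reversals only", {
  clean <- matrix(rep(c(rep(1L, 4), rep(2L, 4), rep(3L, 4), rep(4L, 6),
                        rep(5L, 6)), each = 8), 8, 24, byrow = FALSE)
  tc <- topologyCheck(clean)
  expect_identical(tc$component_violations, 0L)
  expect_identical(tc$ordering_violations, 0L)
  expect_true(tc$clean)

  # CA1 island inside CA3
  island <- clean
  island[4, 16] <- 2L
  ti <- topologyCheck(island)
  expect_identical(unname(ti$n_components["CA1"]), 2L)
  expect_gt(ti$component_violations, 0)

  # skipping a subfield is fine; reversing the order is not
  skip <- matrix(rep(c(rep(1L, 8), rep(2L, 8), rep(4L, 8)), each = 4),
                 4, 24, byrow = FALSE)
  expect_identical(topologyCheck(skip)$ordering_violations, 0L)
  rev <- matrix(rep(c(rep(4L, 8), rep(2L, 8), rep(1L, 8)), each = 4),
                4, 24, byrow = FALSE)
  expect_gt(topologyCheck(rev)$ordering_violations, 0)
})

test_that("the paired one-tailed t-test matches the closed form", {
  r <- pairedOneTailedT(c(0.1, 0.2, 0.3) + 1, c(1, 1, 1))
  expect_equal(r$t, 0.2 / (sd(c(0.1, 0.2, 0.3)) / sqrt(3)),
               tolerance = 1e-9)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$p, pt(3.4641016, df = 2, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(r$p, 0.0371, tolerance = 1e-3)

  same <- pairedOneTailedT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_true(same$degenerate)

  expect_error(pairedOneTailedT(c(1, 2), c(0, 0)), "at least 3")

  pos <- pairedOneTailedT(c(2, 3, 4), c(1, 2, 3))
  expect_identical(pos$t, Inf)
  expect_identical(pos$p, 0)
  expect_true(pos$degenerate)
})
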