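# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# World <-> voxel (0-based continuous index) conversions through the affine.
voxToWorld <- function(idx, affine) {
  # idx: n x 3 of 0-based indices
  h <- cbind(idx, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

worldToVox <- function(xyz, affine) {
  inv <- solve(affine)
  h <- cbind(xyz, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

# Central-difference gradient of a 3D array along each axis (index units).
gradient3 <- function(a) {
  lapply(1:3, function(ax)
    (shiftArray(a, ax, 1) - shiftArray(a, ax, -1)) / 2)
}

# Shift array along an axis: out[k] = a[k + s], replicate boundary.
shiftArray <- function(a, axis, s) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- seq_len(d[axis]) + s
  i[i < 1] <- 1
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx))
}

# NA-aware Gaussian smoothing of a matrix via normalized convolution.
gaussSmoothNA <- function(m, sigma_px) {
  if (all(sigma_px <= 0)) return(m)
  ok <- is.finite(m)
  v <- m
  v[!ok] <- 0
  num <- cpp_gauss_smooth(as.numeric(v), dim(m), sigma_px)
  den <- cpp_gauss_smooth(as.numeric(ok), dim(m), sigma_px)
  out <- matrix(num / pmax(den, 1e-12), nrow(m), ncol(m))
  out[!ok] <- NA_real_
  out
}

# Fill NA pixels of a matrix with the nearest finite value (Euclidean).
fillNearest <- function(m, spacing = c(1, 1)) {
  ok <- is.finite(m)
  if (all(ok)) return(m)
  if (!any(ok)) stop("cannot fill: no finite values")
  # integer surrogate: index of nearest valid pixel via label imputation on
  # a map whose "labels" are 1-based flat indices of valid pixels
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[ok] <- which(ok)
  filled <- cpp_impute_nearest(as.integer(lab), dim(m), spacing)
  matrix(m[filled], nrow(m), ncol(m))
}

# Grid node centers along one axis: n nodes covering [0,1] at cell centers.
nodeCenters <- function(n) (seq_len(n) - 0.5) / n

# Default physical extent of the unfolded rectangle (mm): canonical
# hippocampal scale, A-P x P-D. Recorded in metadata, not assumed by I/O.
.UNFOLDED_EXTENT <- c(40, 20)

gridSpacing <- function(shape, extent = .UNFOLDED_EXTENT) extent / shape

stopIfNot3D <- function(a, what = "volume") {
  if (length(dim(a)) != 3)
    stop(sprintf("expected 3D %s, got %dD", what, length(dim(a))))
}
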