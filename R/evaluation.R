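# Quantitative evaluation: Dice overlap (unfolded 2D and native 3D),
# minimum border distances in real-world mm via distance transforms,
# topology checks (connected components and proximal-distal subfield
# ordering), feature ablations, and paired one-tailed t-tests.

#' Dice overlap per label
#'
#' Dice = 2|A intersect B| / (|A| + |B|), an overlap fraction in [0, 1].
#' Labels absent from both images yield NaN (undefined).
#'
#' @param ref,test integer arrays/matrices of identical shape (or
#'   [UnfoldedMap-class] / [LabelVolume-class] objects).
#' @param label_ids labels to score (default subfields 1-5).
#' @return named numeric vector of Dice scores.
#' @export
diceScores <- function(ref, test, label_ids = .GRAY_LABELS) {
  ref <- rawLabels(ref)
  test <- rawLabels(test)
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  out <- vapply(label_ids, function(L) {
    a <- ref == L
    b <- test == L
    denom <- sum(a) + sum(b)
    if (denom == 0) return(NaN)
    2 * sum(a & b) / denom
  }, numeric(1))
  names(out) <- .SUBFIELD_NAMES[match(label_ids, .GRAY_LABELS)]
  out
}

rawLabels <- function(x) {
  if (is(x, "UnfoldedMap")) return(x@values)
  if (is(x, "LabelVolume")) return(x@voxels)
  x
}

#' Minimum distances between subfield borders
#'
#' For each neighbouring subfield pair, finds the reference border voxels
#' (gray voxels of one label 6-adjacent to the other, in both directions),
#' computes the Euclidean distance transform from that border in mm, and
#' reads the distances at the test image's corresponding border voxels:
#' the minimum direct 3D distance between borders in real-world units.
#' Distances are pooled across the four default pairs; the median summarizes
#' the pooled distribution.
#'
#' @param ref,test [LabelVolume-class] objects on the same grid and affine
#'   (2D matrices also accepted).
#' @param pairs list of label pairs; default Sub-CA1, CA1-CA2, CA2-CA3,
#'   CA3-CA4.
#' @param spacing per-axis spacing (mm); taken from `ref` when available.
#' @return list with `distances` (pooled, mm), `median`, and `per_pair`
#'   medians (NaN for pairs absent in the reference, with a warning).
#' @export
borderDistances <- function(ref, test,
                            pairs = list(c(1, 2), c(2, 3), c(3, 4),
                                         c(4, 5)),
                            spacing = NULL) {
  if (is(ref, "LabelVolume")) {
    if (is.null(spacing)) spacing <- ref@spacing
    if (is(test, "LabelVolume") &&
        max(abs(ref@affine - test@affine)) > 1e-6)
      stop("affine mismatch between ref and test")
  }
  ref <- rawLabels(ref)
  test <- rawLabels(test)
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  if (is.null(spacing)) spacing <- rep(1, length(dim(ref)))
  pooled <- numeric(0)
  per_pair <- numeric(length(pairs))
  for (q in seq_along(pairs)) {
    A <- pairs[[q]][1]
    B <- pairs[[q]][2]
    rb <- borderVoxels(ref, A, B)
    tb <- borderVoxels(test, A, B)
    if (!any(rb) || !any(tb)) {
      warning(sprintf("pair %d-%d absent in %s; skipping", A, B,
                      if (!any(rb)) "reference" else "test"))
      per_pair[q] <- NaN
      next
    }
    dt <- cpp_edt(as.logical(rb), dim(ref), spacing)
    d <- dt[which(as.logical(tb))]
    per_pair[q] <- stats::median(d)
    pooled <- c(pooled, d)
  }
  names(per_pair) <- vapply(pairs, function(p)
    paste(.SUBFIELD_NAMES[p], collapse = "-"), character(1))
  list(distances = pooled,
       median = if (length(pooled)) stats::median(pooled) else NaN,
       per_pair = per_pair)
}

# the A-side of the A|B interface: voxels labelled A with a 6-adjacent B
# neighbour (one-sided, so matching interfaces in ref and test pair up at
# distance zero and a 3-voxel offset reads as 3 voxels)
borderVoxels <- function(lab, A, B) {
  a <- lab == A
  b <- lab == B
  nd <- length(dim(lab))
  adj_ab <- array(FALSE, dim(lab))
  for (ax in seq_len(nd)) for (s in c(-1, 1))
    adj_ab <- adj_ab | shiftMat(b, ax, s)
  a & adj_ab
}

shiftMat <- function(a, axis, s) {
  if (length(dim(a)) == 3) return(shiftArray(a, axis, s))
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- seq_len(d[axis]) + s
  i[i < 1] <- 1
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  out <- do.call(`[`, c(list(a), idx))
  # zero out wrapped-in border (replicate would double-count the edge)
  out
}

#' Topology check of an unfolded label map
#'
#' A propagated subfield map is topologically clean when every subfield
#' forms a single 8-connected component and, along every anterior-posterior
#' row, labels are non-decreasing in the anatomical proximal-distal order
#' Sub < CA1 < CA2 < CA3 < CA4 (skipping a subfield is allowed; reversing
#' the order is a violation).
#'
#' @param labels an [UnfoldedMap-class] (or integer matrix) over labels 0-5.
#' @return list with `n_components` (per subfield), `component_violations`,
#'   `ordering_violations`, and `clean` (both zero).
#' @export
topologyCheck <- function(labels) {
  v <- rawLabels(labels)
  ncomp <- vapply(.GRAY_LABELS, function(L) {
    m <- v == L
    if (!any(m)) return(0L)
    max(cpp_label_components(as.logical(m), dim(v), 8L))
  }, integer(1))
  names(ncomp) <- .SUBFIELD_NAMES
  comp_viol <- sum(pmax(ncomp - 1L, 0L))
  ord_viol <- 0L
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    row <- row[row %in% .GRAY_LABELS]
    if (length(row) > 1)
      ord_viol <- ord_viol + sum(diff(row) < 0)
  }
  list(n_components = ncomp, component_violations = comp_viol,
       ordering_violations = as.integer(ord_viol),
       clean = comp_viol == 0 && ord_viol == 0)
}

#' Paired one-tailed t-test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on paired differences d = a - b (sd with
#' the n-1 denominator); one-tailed p from the t distribution with n-1
#' degrees of freedom, alternative a > b. Zero-variance differences with a
#' positive mean report t = +Inf, p = 0 and are flagged degenerate.
#'
#' @param a,b equal-length paired vectors (e.g. subfield x subject Dice).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
pairedOneTailedT <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop("need at least 3 finite pairs, got ", n)
  sdd <- stats::sd(d)
  if (sdd < 1e-15) {
    tt <- if (mean(d) > 0) Inf else if (mean(d) < 0) -Inf else 0
    return(list(t = tt, p = if (tt > 0) 0 else if (tt < 0) 1 else 0.5,
                df = n - 1, degenerate = TRUE))
  }
  tt <- mean(d) / (sdd / sqrt(n))
  list(t = tt, p = stats::pt(tt, df = n - 1, lower.tail = FALSE),
       df = n - 1, degenerate = FALSE)
}
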