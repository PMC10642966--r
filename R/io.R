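#' Read a 3D (label or scalar) volume from NIfTI
#'
#' Reads a 3D NIfTI image into a [LabelVolume-class]. Label volumes must be
#' integer-valued; pass `labels = FALSE` to read scalar volumes (e.g.
#' coordinate fields) without the integrality check.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param labels logical; enforce integer-valued data (default TRUE).
#' @return a [LabelVolume-class].
#' @export
readVolume <- function(path, labels = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  # tolerate trailing singleton dimensions
  d <- dim(a)
  if (length(d) > 3 && all(d[-(1:3)] == 1)) {
    dim(a) <- d[1:3]
    d <- d[1:3]
  }
  if (length(d) != 3)
    stop(sprintf("expected 3D image, got %dD: %s", length(d), path))
  if (labels) {
    if (max(abs(a - round(a))) > 1e-6)
      stop(sprintf("label volume has non-integer data (dtype %s): %s",
                   storage.mode(a), path))
    a <- array(as.integer(round(a)), d)
  } else {
    a <- array(as.numeric(a), d)
  }
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- matrix(as.numeric(aff[1:4, 1:4]), 4, 4)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  new("LabelVolume", voxels = a, affine = aff, spacing = sp)
}

#' Write a volume to NIfTI
#'
#' Writes a [LabelVolume-class] (or a bare 3D array with an affine) to NIfTI,
#' preserving the affine via the sform. Integer arrays are stored as int32,
#' doubles as float64, so [readVolume()] round-trips content exactly.
#'
#' @param vol a [LabelVolume-class], or a 3D array.
#' @param path output path; the parent directory must exist.
#' @param affine 4x4 affine when `vol` is a bare array.
#' @export
writeVolume <- function(vol, path, affine = NULL) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (is(vol, "LabelVolume")) {
    a <- vol@voxels
    affine <- vol@affine
  } else {
    a <- vol
    if (is.null(affine)) affine <- diag(4)
  }
  stopIfNot3D(a)
  dt <- if (is.integer(a)) "int32" else "double"
  img <- RNifti::asNifti(a, datatype = dt)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read unfolded maps and transforms
#'
#' Unfolded 2D maps are serialized as degenerate-third-axis NIfTI (so any
#' NIfTI viewer opens them) plus a JSON sidecar holding grid metadata
#' (channel name, pixel spacing, units). Transforms are serialized as a
#' multi-component NIfTI stacking the per-axis displacement (and, for
#' stationary-velocity transforms, velocity) components, with a JSON sidecar
#' describing kind, dimensionality, shape and spacing. Round-trips are
#' lossless.
#'
#' @param x an [UnfoldedMap-class] or [DiffeoTransform-class].
#' @param path output path ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it with extension `.json`.
#' @return `readUnfolded()` returns the reconstructed object.
#' @export
writeUnfolded <- function(x, path) {
  side <- sidecarPath(path)
  if (is(x, "UnfoldedMap")) {
    a <- array(x@values, c(dim(x@values), 1))
    img <- RNifti::asNifti(a, datatype = "double")
    RNifti::writeNifti(img, path)
    meta <- list(type = "UnfoldedMap", shape = dim(x@values),
                 spacing = x@spacing, channel = x@channel, units = x@units)
  } else if (is(x, "DiffeoTransform")) {
    nd <- length(x@shape)
    comp <- x@disp
    nvel <- 0L
    if (x@kind == "svf" && length(x@velocity)) {
      comp <- c(comp, x@velocity)
      nvel <- nd
    }
    flat <- vapply(comp, as.numeric, numeric(prod(x@shape)))
    a <- array(flat, c(x@shape, if (nd == 2) 1 else NULL, length(comp)))
    img <- RNifti::asNifti(a, datatype = "double")
    RNifti::writeNifti(img, path)
    meta <- list(type = "DiffeoTransform", kind = x@kind, dim = nd,
                 shape = x@shape, spacing = x@spacing,
                 n_velocity_components = nvel)
  } else stop("cannot serialize object of class ", class(x))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeUnfolded
#' @param expected_shape optional grid shape; a mismatch raises a warning
#'   (grids are configurable), not an error.
#' @export
readUnfolded <- function(path, expected_shape = NULL) {
  side <- sidecarPath(path)
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  a <- as.array(RNifti::readNifti(path))
  if (!is.null(expected_shape) &&
      !identical(as.integer(meta$shape[1:2]), as.integer(expected_shape[1:2])))
    warning(sprintf("grid shape %s differs from configured %s",
                    paste(meta$shape, collapse = "x"),
                    paste(expected_shape, collapse = "x")))
  if (identical(meta$type, "UnfoldedMap")) {
    v <- matrix(as.numeric(a), meta$shape[1], meta$shape[2])
    new("UnfoldedMap", values = v, spacing = as.numeric(meta$spacing),
        channel = meta$channel, units = meta$units)
  } else if (identical(meta$type, "DiffeoTransform")) {
    shape <- as.integer(meta$shape)
    nd <- as.integer(meta$dim)
    ncomp <- dim(a)[length(dim(a))]
    flat <- matrix(as.numeric(a), prod(shape), ncomp)
    comps <- lapply(seq_len(ncomp), function(i) array(flat[, i], shape))
    disp <- comps[seq_len(nd)]
    vel <- if (meta$n_velocity_components > 0) comps[nd + seq_len(nd)] else list()
    new("DiffeoTransform", velocity = vel, disp = disp, shape = shape,
        spacing = as.numeric(meta$spacing), kind = meta$kind)
  } else stop("unknown serialized type: ", meta$type)
}

sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Construct an UnfoldedMap
#'
#' @param values numeric matrix (rows = A-P, cols = P-D).
#' @param channel channel name.
#' @param units unit string.
#' @param extent physical extent (mm) of the unfolded rectangle.
#' @return an [UnfoldedMap-class].
#' @export
unfoldedMap <- function(values, channel = "map", units = "",
                        extent = .UNFOLDED_EXTENT) {
  new("UnfoldedMap", values = values, spacing = extent / dim(values),
      channel = channel, units = units)
}

#' Read/write a run configuration
#'
#' Configurations are YAML mappings of pipeline parameters (grid shape,
#' unfolded extent, solver tolerances, registration parameters, seed). Every
#' pipeline output directory receives a copy for provenance.
#'
#' @param path YAML file path.
#' @param config a named list.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
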