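#' Accessors for unfoldreg data objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an unfoldreg object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("worldAffine", function(x) standardGeneric("worldAffine"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setGeneric("grayMask", function(x) standardGeneric("grayMask"))
#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("nodeCoordinates", function(x) standardGeneric("nodeCoordinates"))
#' @rdname accessors
#' @export
setGeneric("validNodes", function(x) standardGeneric("validNodes"))
#' @rdname accessors
#' @export
setGeneric("forwardDisplacement", function(x) standardGeneric("forwardDisplacement"))

#' @rdname accessors
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("worldAffine", "LabelVolume", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("mapValues", "UnfoldedMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "UnfoldedMap", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("channelName", "UnfoldedMap", function(x) x@channel)
#' @rdname accessors
#' @export
setMethod("grayMask", "CoordinateFields", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("grayMask", "LabelVolume",
          function(x) array(x@voxels %in% .GRAY_LABELS, dim(x@voxels)))
#' @rdname accessors
#' @export
setMethod("channels", "FeatureStack", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("nodeCoordinates", "SurfaceGrid", function(x) x@xyz)
#' @rdname accessors
#' @export
setMethod("validNodes", "SurfaceGrid", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("forwardDisplacement", "DiffeoTransform", function(x) x@disp)
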