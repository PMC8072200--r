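# Generics and accessors. Slot access from user code goes through these.

#' Number of emitters in a point cloud
#' @param x a [PointCloud-class]
#' @return integer count
#' @export
setGeneric("nEmitters", function(x) standardGeneric("nEmitters"))

#' @rdname nEmitters
setMethod("nEmitters", "PointCloud", function(x) nrow(x@positions))

#' Emitter coordinates of a point cloud
#' @param x a [PointCloud-class]
#' @return numeric matrix with columns x, y, z in micrometres
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname positions
setMethod("positions", "PointCloud", function(x) x@positions)

#' Emitter weights accessor
#' @param x a [PointCloud-class]
#' @return numeric vector of relative brightness factors
#' @export
cloudWeights <- function(x) {
  stopifnot(is(x, "PointCloud"))
  x@weights
}

#' Bounding box of a point cloud
#' @param x a [PointCloud-class]
#' @return 2 x 3 matrix (rows min, max; columns x, y, z) in micrometres
#' @export
cloudBounds <- function(x) {
  stopifnot(is(x, "PointCloud"))
  x@bounds
}

#' Raw array data of a stack or volume
#' @param x a [SIMStack-class] or [VolumeStack-class]
#' @return the underlying numeric array
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname stackData
setMethod("stackData", "SIMStack", function(x) x@data)

#' @rdname stackData
setMethod("stackData", "VolumeStack", function(x) x@data)

#' Voxel spacing of a volume
#' @param x a [VolumeStack-class]
#' @return numeric (dz, dy, dx) in nm
#' @export
voxelSpacing <- function(x) {
  stopifnot(is(x, "VolumeStack"))
  x@spacing
}

#' Optics configuration attached to a stack
#' @param x a [SIMStack-class]
#' @return the [OpticsConfig-class]
#' @export
stackConfig <- function(x) {
  stopifnot(is(x, "SIMStack"))
  x@config
}

#' Sample-plane pixel size
#'
#' The physical camera pixel projected to the sample plane:
#' \code{cameraPixel * 1000 / magnification}, in nm.
#'
#' @param config an [OpticsConfig-class]
#' @return pixel size in nm
#' @export
samplePixel <- function(config) {
  stopifnot(is(config, "OpticsConfig"))
  config@cameraPixel * 1000 / config@magnification
}

#' Image-domain FWHM of an autocorrelation fit
#' @param x an [ACFFit-class]
#' @return FWHM in nm
#' @export
fittedFwhm <- function(x) {
  stopifnot(is(x, "ACFFit"))
  x@fwhm
}

#' Input / target arrays of a chunk pair
#' @param x a [ChunkPair-class]
#' @return 3D numeric array (channels, y, x)
#' @export
chunkInput <- function(x) {
  stopifnot(is(x, "ChunkPair"))
  x@input
}

#' @rdname chunkInput
#' @export
chunkTarget <- function(x) {
  stopifnot(is(x, "ChunkPair"))
  x@target
}
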