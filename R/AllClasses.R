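#' @import methods
NULL

#' PointCloud: a 3D point-cloud specimen
#'
#' Holds emitter coordinates (micrometres, specimen-centred) and per-emitter
#' relative brightness weights. This is the ground-truth object from which all
#' raw SIM stacks, widefield stacks and high-resolution confocal targets are
#' rendered.
#'
#' @slot positions numeric matrix with columns \code{x}, \code{y}, \code{z}
#'   (micrometres); one row per emitter. May have zero rows.
#' @slot weights numeric vector of strictly positive per-emitter relative
#'   brightness factors (dimensionless, default 1).
#' @slot bounds numeric matrix \code{2 x 3} (rows \code{min}, \code{max}) —
#'   the axis-aligned bounding box guaranteed to contain all emitters.
#'
#' @seealso [generateSphereCloud()], [generateChromatinCloud()],
#'   [readSmlmCsv()]
#' @export
setClass("PointCloud",
  representation(positions = "matrix", weights = "numeric", bounds = "matrix"))

setValidity("PointCloud", function(object) {
  p <- object@positions
  if (ncol(p) != 3L) return("positions must have 3 columns (x, y, z)")
  if (length(object@weights) != nrow(p))
    return("weights length must equal the number of emitters")
  if (nrow(p) > 0 && any(object@weights <= 0))
    return("weights must be strictly positive")
  b <- object@bounds
  if (!all(dim(b) == c(2L, 3L))) return("bounds must be a 2 x 3 matrix")
  if (nrow(p) > 0) {
    eps <- 1e-9
    for (j in 1:3)
      if (any(p[, j] < b[1, j] - eps) || any(p[, j] > b[2, j] + eps))
        return("all positions must lie inside bounds")
  }
  TRUE
})

#' OpticsConfig: microscope and simulation parameters
#'
#' All optical and sampling parameters of the simulated light-sheet hexagonal
#' SIM microscope. The default configuration is a 256 x 256 camera of 6.5 um
#' pixels behind a 60x objective (sample-plane pixel 108.33 nm), NA 1.1 and a
#' shared illumination/emission wavelength of 525 nm; 40 axial planes spaced
#' 250 nm apart with a Gaussian light-sheet of 700 nm FWHM.
#'
#' @slot na numerical aperture, in (0, 1.5].
#' @slot wavelength illumination/emission wavelength in nm.
#' @slot magnification objective magnification (dimensionless).
#' @slot cameraPixel physical camera pixel size in micrometres.
#' @slot cameraSize camera pixels per side.
#' @slot nPlanes number of SIM focal planes per stack.
#' @slot dz axial plane spacing in nm.
#' @slot lightsheetFwhm axial FWHM of the Gaussian illumination sheet in nm.
#' @slot zSub integer subdivision of \code{dz} used as the fine axial
#'   rendering grid (must be a multiple of 3 so confocal planes at dz/3 fall
#'   on the grid).
#'
#' @seealso [opticsConfig()], [samplePixel()]
#' @export
setClass("OpticsConfig",
  representation(na = "numeric", wavelength = "numeric",
    magnification = "numeric", cameraPixel = "numeric",
    cameraSize = "integer", nPlanes = "integer", dz = "numeric",
    lightsheetFwhm = "numeric", zSub = "integer"))

setValidity("OpticsConfig", function(object) {
  if (object@na <= 0 || object@na > 1.5) return("na must be in (0, 1.5]")
  if (object@wavelength <= 0) return("wavelength must be positive")
  if (object@magnification <= 0) return("magnification must be positive")
  if (object@cameraPixel <= 0) return("cameraPixel must be positive")
  if (object@cameraSize < 2L) return("cameraSize must be at least 2")
  if (object@nPlanes < 1L) return("nPlanes must be at least 1")
  if (object@dz <= 0) return("dz must be positive")
  if (object@lightsheetFwhm <= 0) return("lightsheetFwhm must be positive")
  if (object@zSub < 3L || object@zSub %% 3L != 0L)
    return("zSub must be a positive multiple of 3")
  px <- object@cameraPixel * 1000 / object@magnification
  if (px > object@wavelength / (4 * object@na))
    return(sprintf(
      "sample-plane pixel (%.1f nm) under-samples the OTF support (limit %.1f nm)",
      px, object@wavelength / (4 * object@na)))
  TRUE
})

#' SIMStack: a raw 7-frame structured-illumination stack
#'
#' Raw (or Poisson-noised) hexagonal SIM data, indexed
#' \code{[plane, frame, y, x]} with exactly 7 frames per plane. Pixel values
#' are expected photons (noise-free) or photon counts (after
#' [addPoissonNoise()]).
#'
#' @slot data 4D numeric array \code{(nPlanes, 7, ny, nx)}.
#' @slot config the [OpticsConfig-class] used to render the stack.
#' @slot units either \code{"expected"} or \code{"counts"}.
#' @export
setClass("SIMStack",
  representation(data = "array", config = "OpticsConfig", units = "character"))

setValidity("SIMStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (plane, frame, y, x)")
  if (d[2] != 7L) return("frame axis length must be exactly 7")
  if (any(object@data < 0)) return("pixel values must be non-negative")
  if (!object@units %in% c("expected", "counts"))
    return("units must be 'expected' or 'counts'")
  TRUE
})

#' VolumeStack: a 3D image volume with physical spacings
#'
#' Container for single-channel 3D stacks: widefield renders, high-resolution
#' confocal targets, classical SIM reconstructions and network outputs. The
#' high-resolution geometry (confocal target, reconstruction output) has
#' \code{3 * nPlanes} planes at \code{dz/3} spacing and a lateral grid of
#' \code{2 * cameraSize} pixels at half the SIM sample-plane pixel.
#'
#' @slot data 3D numeric array \code{(nz, ny, nx)}.
#' @slot spacing numeric length-3 vector \code{(dz, dy, dx)} in nm.
#' @export
setClass("VolumeStack",
  representation(data = "array", spacing = "numeric"))

setValidity("VolumeStack", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (dz, dy, dx) in nm")
  TRUE
})

#' ACFFit: two-Gaussian decomposition of an autocorrelation profile
#'
#' Result of fitting \code{a1 G(tau; sigma1) + a2 G(tau; sigma2)} to a 1D
#' autocorrelation profile. The narrow component reflects the point spread
#' function; the broad component absorbs neighbour cross-correlations. The
#' image-domain FWHM is \code{2 sqrt(2 log 2) * sigma_min / sqrt(2)}: the
#' autocorrelation of a Gaussian of width sigma has width sigma*sqrt(2).
#'
#' @slot a1,sigma1 amplitude and width (nm) of the first Gaussian.
#' @slot a2,sigma2 amplitude and width (nm) of the second Gaussian.
#' @slot fwhm image-domain full width at half maximum in nm, from the
#'   narrower Gaussian.
#' @slot residual residual norm of the least-squares fit.
#' @slot profile data.frame with columns \code{lag} (nm) and \code{acf}.
#' @export
setClass("ACFFit",
  representation(a1 = "numeric", sigma1 = "numeric", a2 = "numeric",
    sigma2 = "numeric", fwhm = "numeric", residual = "numeric",
    profile = "data.frame"))

setValidity("ACFFit", function(object) {
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    return("sigma1 and sigma2 must be positive")
  if (object@fwhm <= 0) return("fwhm must be positive")
  TRUE
})

#' ChunkPair: one network training datapoint
#'
#' A chunk of \code{chunkSize} consecutive SIM planes (7 frames each, so
#' \code{7 * chunkSize} input channels) paired with the aligned
#' \code{3 * chunkSize} high-resolution target planes at doubled lateral
#' sampling.
#'
#' @slot input numeric array \code{(7*chunkSize, H, W)}, plane-major
#'   frame-minor channel order.
#' @slot target numeric array \code{(3*chunkSize, 2H, 2W)}.
#' @slot stackId identifier of the source stack.
#' @slot startPlane first SIM plane of the chunk (0-based, pre-trim indexing).
#' @slot normInput,normTarget length-2 numeric \code{(min, range)} recorded by
#'   [normalizeChunks()]; \code{NA} before normalization.
#' @export
setClass("ChunkPair",
  representation(input = "array", target = "array", stackId = "character",
    startPlane = "integer", normInput = "numeric", normTarget = "numeric"))

setValidity("ChunkPair", function(object) {
  di <- dim(object@input); dt <- dim(object@target)
  if (length(di) != 3L || length(dt) != 3L)
    return("input and target must be 3D arrays (channels, y, x)")
  if (di[1] %% 7L != 0L) return("input channel count must be a multiple of 7")
  cs <- di[1] %/% 7L
  if (dt[1] != 3L * cs)
    return("target channel count must be 3 * chunkSize")
  if (dt[2] != 2L * di[2] || dt[3] != 2L * di[3])
    return("target lateral size must be twice the input lateral size")
  TRUE
})

#' SplitManifest: reproducible train/validation/test bookkeeping
#'
#' @slot testIds character vector of stacks reserved for testing (selected
#'   before any training, per class).
#' @slot trainIds character vector of the remaining stacks used for training
#'   and validation.
#' @slot classes named character vector mapping stack id to specimen class.
#' @slot valFraction fraction of chunks carved out for validation.
#' @slot seed integer seed the split was drawn with.
#' @export
setClass("SplitManifest",
  representation(testIds = "character", trainIds = "character",
    classes = "character", valFraction = "numeric", seed = "integer"))

setValidity("SplitManifest", function(object) {
  if (length(intersect(object@testIds, object@trainIds)) > 0)
    return("test and train/validation stacks must be disjoint")
  if (object@valFraction < 0 || object@valFraction >= 1)
    return("valFraction must be in [0, 1)")
  TRUE
})

#' RCANConfig: architecture hyper-parameters of the modified RCAN
#'
#' @slot nGroups number of residual groups.
#' @slot nBlocks residual channel-attention blocks per group.
#' @slot kernel spatial kernel side (odd).
#' @slot chunkSize SIM planes per processing chunk; input channels are
#'   \code{7*chunkSize}, output channels \code{3*chunkSize}.
#' @slot featChannels internal feature width.
#' @slot reduction channel-attention bottleneck ratio.
#' @slot conv3dChannels output channels of the leading 3D convolution over
#'   the interleaved (plane, frame) axis.
#' @slot upscale lateral upscaling factor (fixed at 2).
#' @export
setClass("RCANConfig",
  representation(nGroups = "integer", nBlocks = "integer", kernel = "integer",
    chunkSize = "integer", featChannels = "integer", reduction = "integer",
    conv3dChannels = "integer", upscale = "integer"))

setValidity("RCANConfig", function(object) {
  if (object@upscale != 2L) return("upscale must be 2")
  if (object@kernel %% 2L != 1L) return("kernel must be odd")
  if (object@nGroups < 1L || object@nBlocks < 1L)
    return("nGroups and nBlocks must be >= 1")
  if (object@chunkSize < 1L) return("chunkSize must be >= 1")
  if (object@featChannels < object@reduction)
    return("featChannels must be >= reduction")
  TRUE
})

#' ReconParams: classical SIM reconstruction parameters
#'
#' Constant reconstruction parameters matched to the simulation (no parameter
#' estimation from data): the 6 paired carrier wavevectors of the hexagonal
#' pattern, the 7x7 frame-phase mixing matrix, the Wiener regularizer and the
#' apodization cutoff.
#'
#' @slot carriers numeric matrix \code{7 x 2} of carrier wavevectors in
#'   cycles/nm (row 1 is DC).
#' @slot bandWeights numeric length-7 modulation amplitudes per band (3 for
#'   DC, 1 for each carrier band).
#' @slot phaseMatrix complex \code{7 x 7} mixing matrix (frames x bands).
#' @slot wienerEps Wiener regularization constant, relative to the peak of
#'   the summed squared OTFs.
#' @slot apodCutoff apodization cutoff in cycles/nm (triangle window).
#' @export
setClass("ReconParams",
  representation(carriers = "matrix", bandWeights = "numeric",
    phaseMatrix = "matrix", wienerEps = "numeric", apodCutoff = "numeric"))

setValidity("ReconParams", function(object) {
  if (!all(dim(object@phaseMatrix) == c(7L, 7L)))
    return("phaseMatrix must be 7 x 7")
  if (object@wienerEps <= 0) return("wienerEps must be positive")
  sv <- svd(object@phaseMatrix)$d
  if (min(sv) <= 0 || !is.finite(max(sv) / min(sv)))
    return("phaseMatrix must have finite condition number")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "PointCloud", function(object) {
  n <- nrow(object@positions)
  cat(sprintf("PointCloud with %d emitter%s\n", n, if (n == 1) "" else "s"))
  b <- object@bounds
  cat(sprintf("  bounds (um): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
    b[1, 1], b[2, 1], b[1, 2], b[2, 2], b[1, 3], b[2, 3]))
  if (n > 0)
    cat(sprintf("  weights: min %.3g, max %.3g\n",
      min(object@weights), max(object@weights)))
})

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig\n")
  cat(sprintf("  NA %.2f, wavelength %.0f nm, magnification %.0fx\n",
    object@na, object@wavelength, object@magnification))
  cat(sprintf("  camera %d x %d px of %.2f um (sample pixel %.2f nm)\n",
    object@cameraSize, object@cameraSize, object@cameraPixel,
    samplePixel(object)))
  cat(sprintf("  %d planes, dz %.0f nm, light-sheet FWHM %.0f nm\n",
    object@nPlanes, object@dz, object@lightsheetFwhm))
})

setMethod("show", "SIMStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("SIMStack: %d planes x 7 frames x %d x %d px (%s photons)\n",
    d[1], d[3], d[4], object@units))
})

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeStack: %d x %d x %d (z, y, x), spacing %.1f/%.1f/%.1f nm\n",
    d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "ACFFit", function(object) {
  cat(sprintf("ACFFit: fwhm %.1f nm (narrow sigma %.1f nm, broad %.1f nm)\n",
    object@fwhm, min(object@sigma1, object@sigma2),
    max(object@sigma1, object@sigma2)))
})

setMethod("show", "ChunkPair", function(object) {
  di <- dim(object@input); dt <- dim(object@target)
  cat(sprintf("ChunkPair %s@%d: input (%d, %d, %d) -> target (%d, %d, %d)\n",
    object@stackId, object@startPlane, di[1], di[2], di[3],
    dt[1], dt[2], dt[3]))
})

setMethod("show", "SplitManifest", function(object) {
  cat(sprintf(
    "SplitManifest: %d test stacks, %d train/validation stacks (val fraction %.2f, seed %d)\n",
    length(object@testIds), length(object@trainIds), object@valFraction,
    object@seed))
})
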