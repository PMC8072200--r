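# Forward rendering of point clouds into raw SIM stacks, widefield stacks
# and high-resolution confocal target stacks.
#
# Rendering is done per plane in Fourier space: each emitter contributes a
# phase ramp exp(-2i*pi*k.x) at its continuous position (no voxelization),
# multiplied by the defocused detection OTF. Emitters are grouped on a fine
# axial grid of step dz/zSub; the phase-ramp field of each occupied slice is
# a complex matrix product (BLAS) and is reused across the focal planes the
# slice contributes to. Lateral boundary handling is periodic.

# Map cloud coordinates (um, specimen-centred) to camera-frame nm
# coordinates with the specimen origin at the grid centre pixel.
cameraCoords <- function(cloud, n, pixel) {
  pos <- positions(cloud) * 1000
  list(x = pos[, 1] + (n / 2) * pixel,
       y = pos[, 2] + (n / 2) * pixel,
       z = pos[, 3])
}

# Phase-ramp k-space field of a weighted emitter subset on an n-grid:
# A[u, v] = sum_j c_j exp(-2i*pi*(ky_u * y_j + kx_v * x_j)).
phaseRampField <- function(kx, x, y, cw) {
  Pr <- exp(-2i * pi * outer(kx, y))       # [u, j]
  Pc <- exp(-2i * pi * outer(x, kx))       # [j, v]
  Pr %*% (cw * Pc)
}

# Light-sheet axial envelope cutoff distance (relative weight 1e-3).
sheetCutoff <- function(fwhm) fwhm * sqrt(log(1000) / (4 * log(2)))

#' Render a raw 7-frame hexagonal SIM stack
#'
#' For each focal plane and frame, emitters are weighted by the hexagonal
#' illumination pattern evaluated at their continuous lateral position and by
#' the Gaussian light-sheet envelope centred on the plane, then imaged
#' through the defocused widefield detection PSF onto the camera grid. The
#' output is a noise-free expected-photon stack of shape
#' \code{(nPlanes, 7, cameraSize, cameraSize)}; a unit-weight emitter at best
#' focus contributes 21 expected photons per unit of photon scaling (the
#' exact 7-frame sum of the illumination).
#'
#' @param cloud a [PointCloud-class]
#' @param config an [OpticsConfig-class]
#' @return a [SIMStack-class]
#' @export
renderSimStack <- function(cloud, config) {
  stopifnot(is(cloud, "PointCloud"), is(config, "OpticsConfig"))
  n <- config@cameraSize
  p <- samplePixel(config)
  nPl <- config@nPlanes
  h <- config@dz / config@zSub
  out <- array(0, c(nPl, 7L, n, n))
  z0 <- -(nPl - 1) / 2 * config@dz
  W <- ceiling(sheetCutoff(config@lightsheetFwhm) / h)

  cc <- cameraCoords(cloud, n, p)
  s <- if (nEmitters(cloud)) round((cc$z - z0) / h) else integer(0)
  keep <- s >= -W & s <= (nPl - 1) * config@zSub + W
  if (!any(keep)) {
    warning("no emitters inside the imaged volume; returning a zero stack")
    return(new("SIMStack", data = out, config = config, units = "expected"))
  }
  xs <- cc$x[keep]; ys <- cc$y[keep]; ss <- s[keep]
  wts <- cloudWeights(cloud)[keep]

  eng <- otfEngine(n, p, config@wavelength, config@na)
  # light-sheet envelope times defocused OTF depends only on the defocus
  wotfs <- lapply(-W:W, function(d)
    gaussianEnvelope(d * h, config@lightsheetFwhm) * eng$otfAt(d * h))
  names(wotfs) <- as.character(-W:W)
  kx <- fftFreq(n, p)
  bySlice <- split(seq_along(ss), ss)
  sliceIdx <- as.integer(names(bySlice))

  for (f in 0:6) {
    cf <- wts * hexIntensityAt(config, f, xs, ys)
    cacheA <- vector("list", length(bySlice))
    for (k in 0:(nPl - 1)) {
      ctr <- k * config@zSub
      inWin <- which(sliceIdx >= ctr - W & sliceIdx <= ctr + W)
      if (!length(inWin)) next
      acc <- matrix(0i, n, n)
      for (ii in inWin) {
        if (is.null(cacheA[[ii]])) {
          j <- bySlice[[ii]]
          cacheA[[ii]] <- phaseRampField(kx, xs[j], ys[j], cf[j])
        }
        d <- sliceIdx[ii] - ctr
        acc <- acc + wotfs[[as.character(d)]] * cacheA[[ii]]
      }
      out[k + 1L, f + 1L, , ] <- pmax(Re(ifft2(acc)), 0)
    }
  }
  new("SIMStack", data = out, config = config, units = "expected")
}

#' Render a widefield stack
#'
#' Images the cloud through the widefield detection PSF with spatially
#' uniform illumination (unit intensity). With \code{lightsheet = TRUE} the
#' Gaussian sheet envelope confines the illumination axially, matching the
#' total illumination of the 7-frame SIM sum up to the factor 21.
#'
#' @param cloud a [PointCloud-class]
#' @param config an [OpticsConfig-class]
#' @param lightsheet apply the light-sheet envelope? Default \code{FALSE}
#'   (conventional epifluorescence widefield).
#' @return a [VolumeStack-class] of shape \code{(nPlanes, n, n)}
#' @export
renderWidefieldStack <- function(cloud, config, lightsheet = FALSE) {
  stopifnot(is(cloud, "PointCloud"), is(config, "OpticsConfig"))
  n <- config@cameraSize
  p <- samplePixel(config)
  nPl <- config@nPlanes
  h <- config@dz / config@zSub
  out <- array(0, c(nPl, n, n))
  spacing <- c(config@dz, p, p)
  z0 <- -(nPl - 1) / 2 * config@dz
  W <- if (lightsheet) ceiling(sheetCutoff(config@lightsheetFwhm) / h) else NA

  cc <- cameraCoords(cloud, n, p)
  s <- if (nEmitters(cloud)) round((cc$z - z0) / h) else integer(0)
  if (!length(s)) {
    warning("no emitters inside the imaged volume; returning a zero stack")
    return(new("VolumeStack", data = out, spacing = spacing))
  }
  eng <- otfEngine(n, p, config@wavelength, config@na)
  kx <- fftFreq(n, p)
  bySlice <- split(seq_along(s), s)
  sliceIdx <- as.integer(names(bySlice))
  wts <- cloudWeights(cloud)
  fields <- lapply(bySlice, function(j)
    phaseRampField(kx, cc$x[j], cc$y[j], wts[j]))

  for (k in 0:(nPl - 1)) {
    ctr <- k * config@zSub
    acc <- matrix(0i, n, n)
    for (ii in seq_along(sliceIdx)) {
      d <- sliceIdx[ii] - ctr
      if (lightsheet && abs(d) > W) next
      env <- if (lightsheet)
        gaussianEnvelope(d * h, config@lightsheetFwhm) else 1
      acc <- acc + (env * eng$otfAt(d * h)) * fields[[ii]]
    }
    out[k + 1L, , ] <- pmax(Re(ifft2(acc)), 0)
  }
  new("VolumeStack", data = out, spacing = spacing)
}

#' Render the high-resolution confocal target stack
#'
#' The ground-truth target the network is trained toward: the cloud imaged
#' with the square of a widefield PSF computed at half the wavelength, on a
#' lateral grid of halved pixel size and with three times the axial plane
#' density. The result doubles both lateral and axial resolution relative to
#' the widefield detection.
#'
#' @param cloud a [PointCloud-class]
#' @param config an [OpticsConfig-class]
#' @return a [VolumeStack-class] of shape
#'   \code{(3*nPlanes, 2*cameraSize, 2*cameraSize)} with spacing
#'   \code{(dz/3, samplePixel/2, samplePixel/2)}
#' @export
renderConfocalTarget <- function(cloud, config) {
  stopifnot(is(cloud, "PointCloud"), is(config, "OpticsConfig"))
  n2 <- 2L * config@cameraSize
  p2 <- samplePixel(config) / 2
  nOut <- 3L * config@nPlanes
  h <- config@dz / config@zSub
  zStep <- config@zSub %/% 3L         # fine slices per output plane
  out <- array(0, c(nOut, n2, n2))
  spacing <- c(config@dz / 3, p2, p2)
  z0 <- -(config@nPlanes - 1) / 2 * config@dz

  cc <- cameraCoords(cloud, n2, p2)
  s <- if (nEmitters(cloud)) round((cc$z - z0) / h) else integer(0)
  eng <- otfEngine(n2, p2, config@wavelength / 2, config@na, power = 2)
  # adaptive axial support: extend while the defocused energy is above 1e-3
  W <- 1L
  maxW <- ceiling(2000 / h)
  while (W < maxW && eng$energyAt(W * h) > 1e-3) W <- W + 1L
  keep <- s >= -W & s <= (nOut - 1) * zStep + W
  if (!any(keep)) {
    warning("no emitters inside the imaged volume; returning a zero stack")
    return(new("VolumeStack", data = out, spacing = spacing))
  }
  xs <- cc$x[keep]; ys <- cc$y[keep]; ss <- s[keep]
  wts <- cloudWeights(cloud)[keep]

  kx <- fftFreq(n2, p2)
  bySlice <- split(seq_along(ss), ss)
  sliceIdx <- as.integer(names(bySlice))
  fields <- lapply(bySlice, function(j)
    phaseRampField(kx, xs[j], ys[j], wts[j]))

  for (pOut in 0:(nOut - 1)) {
    ctr <- pOut * zStep
    inWin <- which(sliceIdx >= ctr - W & sliceIdx <= ctr + W)
    if (!length(inWin)) next
    acc <- matrix(0i, n2, n2)
    for (ii in inWin) {
      d <- sliceIdx[ii] - ctr
      acc <- acc + eng$otfAt(d * h) * fields[[ii]]
    }
    out[pOut + 1L, , ] <- pmax(Re(ifft2(acc)), 0)
  }
  new("VolumeStack", data = out, spacing = spacing)
}

#' Add Poisson shot noise to a raw SIM stack
#'
#' Rescales the stack so that a unit-weight emitter contributes
#' \code{photonsPerEmitter} expected photons summed over its 7 frames at its
#' best-focus plane (the noise-free renderer yields exactly 21 such units),
#' then replaces every pixel by a Poisson draw. Deterministic given the seed.
#'
#' @param stack a [SIMStack-class] in \code{"expected"} units.
#' @param photonsPerEmitter expected photon budget per emitter over 7 frames
#'   (e.g. 2048 for the high-SNR regime, 16 for extreme noise).
#' @param seed integer seed.
#' @return a [SIMStack-class] in \code{"counts"} units
#' @export
addPoissonNoise <- function(stack, photonsPerEmitter, seed = 1L) {
  stopifnot(is(stack, "SIMStack"))
  if (!is.numeric(photonsPerEmitter) || photonsPerEmitter <= 0)
    stop("photonsPerEmitter must be positive")
  if (stack@units != "expected")
    stop("stack already holds photon counts")
  lam <- stack@data * (photonsPerEmitter / 21)
  counts <- withSeed(seed,
    stats::rpois(length(lam), as.vector(lam)))
  new("SIMStack", data = array(counts, dim(lam)), config = stack@config,
    units = "counts")
}
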