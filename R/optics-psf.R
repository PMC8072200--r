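# Scalar-diffraction PSF/OTF machinery: circular pupil with paraxial defocus
# phase, evaluated by 2D FFT per defocus plane.

#' Construct an optics configuration
#'
#' Defaults reproduce the simulated microscope: 256 x 256 camera of 6.5 um
#' pixels, 60x magnification (sample pixel 108.33 nm), NA 1.1, shared
#' illumination/emission wavelength 525 nm, 40 planes at 250 nm spacing and a
#' 700 nm FWHM Gaussian light-sheet.
#'
#' @param na numerical aperture.
#' @param wavelength wavelength in nm.
#' @param magnification objective magnification.
#' @param cameraPixel camera pixel size in micrometres.
#' @param cameraSize camera pixels per side.
#' @param nPlanes SIM planes per stack.
#' @param dz axial plane spacing in nm.
#' @param lightsheetFwhm light-sheet axial FWHM in nm.
#' @param zSub fine axial rendering subdivisions of dz (multiple of 3).
#' @return an [OpticsConfig-class]
#' @export
opticsConfig <- function(na = 1.1, wavelength = 525, magnification = 60,
                         cameraPixel = 6.5, cameraSize = 256L, nPlanes = 40L,
                         dz = 250, lightsheetFwhm = 700, zSub = 3L) {
  new("OpticsConfig", na = na, wavelength = wavelength,
    magnification = magnification, cameraPixel = cameraPixel,
    cameraSize = as.integer(cameraSize), nPlanes = as.integer(nPlanes),
    dz = dz, lightsheetFwhm = lightsheetFwhm, zSub = as.integer(zSub))
}

# Internal OTF factory. Returns cached defocused intensity OTFs on an n-grid
# of the given pixel (nm). `power` = 1 for a widefield intensity PSF, 2 for
# the squared-PSF confocal model. OTFs are normalized so the in-focus OTF has
# value 1 at DC (unit-sum in-focus PSF).
otfEngine <- function(n, pixel, wavelength, na, power = 1) {
  if (pixel > wavelength / (4 * na))
    stop(sprintf(
      "grid under-samples the OTF support: pixel %.2f nm exceeds %.2f nm",
      pixel, wavelength / (4 * na)))
  kx <- fftFreq(n, pixel)
  kr2 <- outer(kx^2, kx^2, `+`)  # [ky, kx]
  kc <- na / wavelength
  pupil <- kr2 <= kc^2
  cache <- new.env(parent = emptyenv())
  norm <- NA_real_
  rawOtf <- function(d) {
    a <- ifft2(pupil * exp(-1i * pi * wavelength * d * kr2))
    psf <- Mod(a)^2
    if (power == 2) psf <- psf^2
    fft2(psf)
  }
  norm <- Re(rawOtf(0)[1, 1])
  list(
    otfAt = function(d) {
      key <- sprintf("%.6f", d)
      if (is.null(cache[[key]])) cache[[key]] <- rawOtf(d) / norm
      cache[[key]]
    },
    # total detected energy at defocus d, relative to focus
    energyAt = function(d) {
      key <- sprintf("%.6f", d)
      if (is.null(cache[[key]])) cache[[key]] <- rawOtf(d) / norm
      Re(cache[[key]][1, 1])
    },
    kc = kc, kx = kx)
}

#' Simulate a widefield point spread function
#'
#' Rotationally symmetric intensity PSF of a circular-pupil widefield
#' microscope (scalar model: uniform pupil with paraxial defocus phase,
#' evaluated by FFT per z-plane), sampled on the requested grid and
#' peak-normalized to 1. The lateral FWHM is close to the classical
#' \code{0.51 * wavelength / NA}.
#'
#' @param config an [OpticsConfig-class]; \code{na} and \code{wavelength} are
#'   used.
#' @param shape integer (nz, ny, nx); ny must equal nx.
#' @param spacing numeric (dz, dy, dx) in nm; defaults to the config's
#'   \code{(dz, samplePixel, samplePixel)}. The lateral spacing must Nyquist
#'   sample the OTF support (\code{<= wavelength / (4 NA)}).
#' @param wavelength optional wavelength override in nm.
#' @param power 1 for the widefield intensity PSF, 2 for its square.
#' @return a [VolumeStack-class] with the PSF centred at the middle voxel and
#'   peak value 1
#' @export
widefieldPsf <- function(config, shape = c(1L, 65L, 65L), spacing = NULL,
                         wavelength = config@wavelength, power = 1) {
  stopifnot(is(config, "OpticsConfig"), length(shape) == 3L)
  if (shape[2] != shape[3]) stop("ny must equal nx")
  if (is.null(spacing))
    spacing <- c(config@dz, samplePixel(config), samplePixel(config))
  eng <- otfEngine(shape[2], spacing[2], wavelength, config@na, power = power)
  nz <- shape[1]
  zc <- fftCentre(nz)
  out <- array(0, shape)
  for (iz in seq_len(nz)) {
    d <- (iz - zc) * spacing[1]
    psfHat <- eng$otfAt(d)
    psf <- Re(ifft2(psfHat)) * length(psfHat)  # unit-sum scale back
    out[iz, , ] <- fftShift(psf)
  }
  out <- out / max(out)
  new("VolumeStack", data = out, spacing = spacing)
}
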