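# Hexagonal three-beam interference illumination and its 7-frame phase
# scheme.
#
# Three unit-amplitude coherent beams with lateral wavevectors at 120 degree
# spacing on a circle of radius NA/wavelength interfere to a 2D hexagonal
# pattern carrying DC plus 6 carrier frequencies (the pairwise beam
# differences, magnitude sqrt(3)*NA/wavelength). Frame f (0..6) advances the
# phases of beams 2 and 3 by 2*pi*f/7 and 6*pi*f/7, so the 6 carrier bands
# pick up frame factors exp(2i*pi*f*d/7) with d = +/-1, +/-2, +/-3: the 7x7
# mixing matrix is a unitary DFT matrix, the component separation is exactly
# invertible, and the 7-frame sum is exactly uniform (value 21).

# Beam wavevectors (cycles/nm), one row per beam.
hexBeams <- function(config) {
  kc <- config@na / config@wavelength
  ang <- pi / 2 + 2 * pi * (0:2) / 3
  cbind(x = kc * cos(ang), y = kc * sin(ang))
}

# Integer phase multipliers per beam: beam m gains phase 2*pi*f*mult[m]/7.
hexPhaseMult <- c(0, 1, 3)

# Band table: DFT index d, carrier wavevector (beam pair difference) and
# modulation amplitude. Order: DC, +1, -1, +2, -2, +3, -3.
hexBands <- function(config) {
  q <- hexBeams(config)
  g <- function(m, mp) q[m, ] - q[mp, ]   # pair (m, m') has Dc = mult m - mult m'
  carriers <- rbind(
    c(0, 0),
    g(2, 1), g(1, 2),   # d = +1, -1
    g(3, 2), g(2, 3),   # d = +2, -2
    g(3, 1), g(1, 3))   # d = +3, -3
  colnames(carriers) <- c("x", "y")
  list(d = c(0, 1, -1, 2, -2, 3, -3), carriers = carriers,
    weights = c(3, 1, 1, 1, 1, 1, 1))
}

# Complex field sum and intensity of the pattern at continuous positions
# (nm). Vectorized over positions.
hexIntensityAt <- function(config, frame, x, y) {
  if (length(frame) != 1L || frame < 0 || frame > 6 || frame %% 1 != 0)
    stop("frame must be a single integer in 0..6")
  q <- hexBeams(config)
  E <- 0
  for (m in 1:3) {
    phase <- 2 * pi * (q[m, 1] * x + q[m, 2] * y) +
      2 * pi * frame * hexPhaseMult[m] / 7
    E <- E + exp(1i * phase)
  }
  Mod(E)^2
}

#' Hexagonal illumination pattern on the camera grid
#'
#' Intensity of the three-beam interference pattern for one of the 7 phase
#' frames, sampled on the sample-plane pixel grid. The mean over the 7 frames
#' is exactly uniform (each pixel sums to 21 across frames), and the Fourier
#' transform of any single frame carries energy only at DC and the 6
#' hexagonal carrier frequencies.
#'
#' @param config an [OpticsConfig-class]
#' @param frame frame index 0..6.
#' @param n grid side in pixels (default \code{cameraSize}).
#' @return an n x n numeric matrix \code{[y, x]} of intensities
#' @export
hexagonalIllumination <- function(config, frame, n = config@cameraSize) {
  p <- samplePixel(config)
  coord <- (seq_len(n) - 1) * p
  xm <- matrix(coord, n, n, byrow = TRUE)
  ym <- matrix(coord, n, n)
  matrix(hexIntensityAt(config, frame, as.vector(xm), as.vector(ym)), n, n)
}
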