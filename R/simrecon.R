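# Classical reconstruction of 7-frame hexagonal SIM stacks: band
# separation by inverting the unitary frame-phase matrix, sub-pixel carrier
# shifting via real-space phase ramps on the doubled grid, generalized
# Wiener combination with triangle apodization, and band-limited axial
# interpolation to three times the plane density.

#' Default reconstruction parameters matched to the simulation
#'
#' Constant reconstruction parameters matching those used to simulate the
#' raw images (no parameter estimation from data): the hexagonal carrier
#' wavevectors, the unitary 7x7 frame-phase matrix, a scalar Wiener
#' regularizer and a triangle apodization reaching the extended cutoff
#' \code{2*NA/wavelength + sqrt(3)*NA/wavelength}.
#'
#' @param config an [OpticsConfig-class]
#' @param wienerEps Wiener regularization constant relative to the peak of
#'   the summed squared OTFs (default 1e-3).
#' @param apodCutoff apodization cutoff in cycles/nm; default the extended
#'   support \code{(2 + sqrt(3)) * NA / wavelength}.
#' @return a [ReconParams-class]
#' @export
defaultReconParams <- function(config, wienerEps = 1e-3, apodCutoff = NULL) {
  stopifnot(is(config, "OpticsConfig"))
  bands <- hexBands(config)
  kc <- config@na / config@wavelength
  if (is.null(apodCutoff)) apodCutoff <- (2 + sqrt(3)) * kc
  M <- outer(0:6, bands$d, function(f, d) exp(2i * pi * f * d / 7))
  new("ReconParams", carriers = bands$carriers, bandWeights = bands$weights,
    phaseMatrix = M, wienerEps = wienerEps, apodCutoff = apodCutoff)
}

#' Separate the 7 Fourier components of one SIM plane
#'
#' Inverts the 7x7 frame-phase mixing matrix applied to the Fourier
#' transforms of the 7 raw frames, yielding the DC band and the 6 carrier
#' bands (still centred at their observed, unshifted positions). With the
#' package's phase scheme the matrix is a unitary DFT matrix, so the
#' round trip mix-then-separate is the identity.
#'
#' @param frames a \code{(7, n, n)} numeric array or a list of 7 matrices.
#' @param params a [ReconParams-class]
#' @return list of 7 complex k-space matrices, ordered as
#'   \code{params@carriers} (DC, +/-1, +/-2, +/-3)
#' @export
separateComponents <- function(frames, params) {
  stopifnot(is(params, "ReconParams"))
  if (is.list(frames)) {
    if (length(frames) != 7L) stop("exactly 7 frames are required")
    F <- lapply(frames, fft2)
  } else {
    if (length(dim(frames)) != 3L || dim(frames)[1] != 7L)
      stop("frames must be a (7, n, n) array")
    F <- lapply(1:7, function(f) fft2(frames[f, , ]))
  }
  M <- params@phaseMatrix
  sv <- svd(M)$d
  cn <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (!is.finite(cn) || cn > 1e8)
    stop(sprintf("phase matrix is numerically singular (condition %.3g)", cn))
  Minv <- solve(M)
  lapply(1:7, function(j) {
    acc <- matrix(0i, nrow(F[[1]]), ncol(F[[1]]))
    for (f in 1:7) acc <- acc + Minv[j, f] * F[[f]]
    acc
  })
}

# Zero-pad an n x n spectrum (fft layout) to 2n x 2n, preserving real-space
# sample amplitudes. Content must be band-limited below the original
# Nyquist (true for OTF-limited bands).
padSpectrum2 <- function(B) {
  n <- nrow(B)
  h <- n %/% 2L
  out <- matrix(0i, 2L * n, 2L * n)
  lo <- 1:h; hiSrc <- (h + 1L):n; hiDst <- (2L * n - (n - h) + 1L):(2L * n)
  out[lo, lo] <- B[lo, lo]
  out[lo, hiDst] <- B[lo, hiSrc]
  out[hiDst, lo] <- B[hiSrc, lo]
  out[hiDst, hiDst] <- B[hiSrc, hiSrc]
  out * 4
}

# In-focus widefield intensity OTF of a circular pupil (chat function),
# radius in cycles/nm; kc is the pupil (amplitude) cutoff NA/wavelength.
analyticOtf <- function(r, kc) {
  rho <- pmin(r / (2 * kc), 1)
  (2 / pi) * (acos(rho) - rho * sqrt(1 - rho^2))
}

# Band-limited axial interpolation of (nz, ny, nx) to factor * nz planes by
# Fourier zero-padding along z (Nyquist bin split symmetrically).
zFourierInterp <- function(arr, factor = 3L) {
  d <- dim(arr)
  nz <- d[1]
  m <- matrix(arr, nz, d[2] * d[3])
  F <- stats::mvfft(m)
  nOut <- factor * nz
  Fp <- matrix(0i, nOut, ncol(F))
  h <- nz %/% 2L
  if (nz %% 2L == 0L) {
    Fp[1:h, ] <- F[1:h, ]
    Fp[h + 1L, ] <- F[h + 1L, ] / 2
    Fp[nOut - h + 1L, ] <- F[h + 1L, ] / 2
    if (h >= 2L) Fp[(nOut - h + 2L):nOut, ] <- F[(h + 2L):nz, ]
  } else {
    Fp[1:(h + 1L), ] <- F[1:(h + 1L), ]
    if (h >= 1L) Fp[(nOut - h + 1L):nOut, ] <- F[(h + 2L):nz, ]
  }
  out <- Re(stats::mvfft(Fp, inverse = TRUE)) / nz
  array(out, c(nOut, d[2], d[3]))
}

#' Classical SIM reconstruction
#'
#' Per plane: separates the 7 Fourier components, shifts the 6 carrier bands
#' to their true frequencies (sub-pixel, via real-space phase ramps on the
#' doubled lateral grid), combines them with a generalized Wiener filter
#' weighted by the shifted in-focus OTF, applies a triangle apodization to
#' the extended cutoff and inverse transforms. The 40 reconstructed planes
#' are then interpolated to 120 by Fourier zero-padding along z and negative
#' ringing is clamped to zero at output.
#'
#' @param stack a [SIMStack-class]
#' @param params a [ReconParams-class]; defaults to
#'   [defaultReconParams()] of the stack's config.
#' @param config optics configuration; defaults to the stack's.
#' @param clampNegative clamp negative apodization ringing to zero at
#'   output (default TRUE)? The pre-clamp result is linear in the input and
#'   strictly band-limited to the apodization support.
#' @return a [VolumeStack-class] of shape
#'   \code{(3*nPlanes, 2*cameraSize, 2*cameraSize)}
#' @export
reconstructSim <- function(stack, params = NULL, config = NULL,
                           clampNegative = TRUE) {
  stopifnot(is(stack, "SIMStack"))
  if (is.null(config)) config <- stackConfig(stack)
  if (is.null(params)) params <- defaultReconParams(config)
  n <- dim(stack@data)[3]
  if (n != config@cameraSize)
    stop("stack lateral size does not match the configuration")
  nPl <- dim(stack@data)[1]
  p <- samplePixel(config)
  n2 <- 2L * n
  p2 <- p / 2
  kc <- config@na / config@wavelength

  kxf <- fftFreq(n2, p2)
  coordF <- (seq_len(n2) - 1) * p2
  kxMat <- matrix(kxf, n2, n2, byrow = TRUE)   # [ky, kx]
  kyMat <- matrix(kxf, n2, n2)
  nBands <- 7L
  # Wiener denominator and apodization are analytic, so each band's full
  # combined weight can be evaluated on its own (unshifted) grid: for band j
  # at final frequency k, the contribution is
  #   w_j * OTF(k + g_j) * apod(k) / (den(k) + eps)
  # which in the band's native coordinates k' = k + g_j reads
  #   w_j * OTF(k') * apod(k' - g_j) / (den(k' - g_j) + eps).
  # Each weighted band is inverse-transformed once and shifted to its true
  # carrier by a real-space phase ramp; the shifted bands sum in real space.
  denAt <- function(qx, qy) {
    den <- 0
    for (m in seq_len(nBands)) {
      g <- params@carriers[m, ]
      den <- den + params@bandWeights[m]^2 *
        analyticOtf(sqrt((qx + g[1])^2 + (qy + g[2])^2), kc)^2
    }
    den
  }
  eps <- params@wienerEps * max(denAt(kxMat, kyMat))
  otfGrid <- analyticOtf(sqrt(kxMat^2 + kyMat^2), kc)
  bandWeight <- vector("list", nBands)
  ramps <- vector("list", nBands)
  for (j in seq_len(nBands)) {
    g <- params@carriers[j, ]
    qx <- kxMat - g[1]; qy <- kyMat - g[2]
    apod <- pmax(0, 1 - sqrt(qx^2 + qy^2) / params@apodCutoff)
    bandWeight[[j]] <- params@bandWeights[j] * otfGrid * apod /
      (denAt(qx, qy) + eps)
    ramps[[j]] <- if (all(g == 0)) NULL else
      outer(exp(-2i * pi * g[2] * coordF), exp(-2i * pi * g[1] * coordF))
  }

  recon <- array(0, c(nPl, n2, n2))
  for (k in seq_len(nPl)) {
    bands <- separateComponents(stack@data[k, , , ], params)
    img <- matrix(0, n2, n2)
    for (j in seq_len(nBands)) {
      cj <- ifft2(padSpectrum2(bands[[j]]) * bandWeight[[j]])
      img <- img + if (is.null(ramps[[j]])) Re(cj) else Re(cj * ramps[[j]])
    }
    recon[k, , ] <- img
  }
  out <- zFourierInterp(recon, 3L)
  if (clampNegative) out <- pmax(out, 0)
  new("VolumeStack", data = out,
    spacing = c(config@dz / 3, p2, p2))
}
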