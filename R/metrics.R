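# Resolution and fidelity metrics: the autocorrelation-based FWHM estimator
# (two-Gaussian decomposition of the image ACF), mean squared error and
# structural similarity.

#' 3D autocorrelation via the power spectrum
#'
#' Computes the circular autocorrelation of a volume as the inverse Fourier
#' transform of its power spectrum, after subtracting the volume mean (so the
#' ACF decays toward zero at large lags instead of a DC pedestal). The result
#' is normalized to 1 at zero lag and shifted so zero lag sits at the centre
#' voxel \code{floor(dim/2) + 1}.
#'
#' @param volume a 3D numeric array or a [VolumeStack-class].
#' @param demean subtract the volume mean first (default TRUE).
#' @return a 3D numeric array of the same shape
#' @export
autocorrelation3d <- function(volume, demean = TRUE) {
  if (is(volume, "VolumeStack")) volume <- stackData(volume)
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  v <- volume
  if (demean) v <- v - mean(v)
  if (all(v == 0))
    stop("volume has no signal: autocorrelation normalization undefined")
  P <- Mod(stats::fft(v))^2
  ac <- Re(stats::fft(P, inverse = TRUE)) / length(P)
  ac <- ac / ac[1, 1, 1]
  fftShift(ac)
}

#' Fit a two-Gaussian model to an autocorrelation profile
#'
#' Bounded least squares of \code{a1*exp(-tau^2/(2*sigma1^2)) +
#' a2*exp(-tau^2/(2*sigma2^2))}: the narrow Gaussian models the
#' autocorrelation of individual PSFs, the broad one the cross-correlation of
#' neighbouring emitters. The image-domain FWHM is derived from the smaller
#' sigma: the ACF of a Gaussian PSF of width sigma_p has width
#' sigma_p*sqrt(2), so \code{fwhm = 2*sqrt(2*log(2)) * sigma_min / sqrt(2)}.
#'
#' @param profile numeric vector of ACF values at lags \code{0, spacing,
#'   2*spacing, ...} (one-sided, peak first), or at the explicit \code{lags}.
#' @param spacing lag spacing in nm (used for the default lags and the
#'   fit bounds).
#' @param lags optional explicit lag positions in nm (e.g. exact radial
#'   distances for a laterally averaged profile).
#' @param narrowBounds,broadBounds length-2 vectors (nm) bounding the two
#'   sigmas; defaults \code{spacing*c(1, 20)} and \code{spacing*c(2, 200)}.
#' @return an [ACFFit-class]
#' @export
fitTwoGaussians <- function(profile, spacing, lags = NULL,
                            narrowBounds = spacing * c(1, 20),
                            broadBounds = spacing * c(2, 200)) {
  if (length(profile) < 4L) stop("profile too short to fit")
  tau <- if (is.null(lags)) (seq_along(profile) - 1) * spacing else lags
  if (length(tau) != length(profile))
    stop("lags must match the profile length")
  pk <- max(profile)
  model <- function(p)
    p[1] * exp(-tau^2 / (2 * p[2]^2)) + p[3] * exp(-tau^2 / (2 * p[4]^2))
  # multi-start bounded Levenberg-Marquardt over narrow/broad width
  # combinations; keep the best converged fit by residual norm
  starts <- expand.grid(s1 = spacing * c(1.5, 3, 6, 12),
                        s2 = spacing * c(10, 30, 100))
  best <- NULL; bestRss <- Inf; lastErr <- NULL
  for (r in seq_len(nrow(starts))) {
    par0 <- c(pk * 0.7,
      max(narrowBounds[1], min(starts$s1[r], narrowBounds[2])),
      pk * 0.3,
      max(broadBounds[1], min(starts$s2[r], broadBounds[2])))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0,
        fn = function(p) profile - model(p),
        lower = c(0, narrowBounds[1], 0, broadBounds[1]),
        upper = c(Inf, narrowBounds[2], Inf, broadBounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { lastErr <<- e; NULL })
    if (!is.null(fit) && all(is.finite(fit$par))) {
      rss <- fit$deviance
      if (rss < bestRss) { bestRss <- rss; best <- fit }
    }
  }
  if (is.null(best))
    stop("two-Gaussian fit failed to converge",
      if (!is.null(lastErr)) paste0(": ", conditionMessage(lastErr)))
  cf <- best$par
  names(cf) <- c("a1", "s1", "a2", "s2")
  # the FWHM comes from the narrowest component carrying real amplitude;
  # a vanishing-amplitude component's width is unidentified
  amps <- c(cf["a1"], cf["a2"])
  sigs <- c(cf["s1"], cf["s2"])
  live <- amps >= 0.05 * sum(amps)
  if (!any(live)) live <- amps == max(amps)
  sMin <- min(sigs[live])
  new("ACFFit",
    a1 = unname(cf["a1"]), sigma1 = unname(cf["s1"]),
    a2 = unname(cf["a2"]), sigma2 = unname(cf["s2"]),
    fwhm = 2 * sqrt(2 * log(2)) * sMin / sqrt(2),
    residual = sqrt(bestRss),
    profile = data.frame(lag = tau, acf = profile))
}

# Radially averaged central-plane ACF profile in half-pixel bins, each bin
# placed at its empirical mean radius (avoids the small-lag bias of
# integer ring binning while keeping lags equally weighted in the fit).
radialProfile <- function(plane, maxR, binWidth = 0.5) {
  n <- dim(plane)
  cy <- fftCentre(n[1]); cx <- fftCentre(n[2])
  dy <- matrix(seq_len(n[1]) - cy, n[1], n[2])
  dx <- matrix(seq_len(n[2]) - cx, n[1], n[2], byrow = TRUE)
  r <- sqrt(dy^2 + dx^2)
  keep <- r <= maxR
  bin <- floor(r[keep] / binWidth)
  ord <- order(as.integer(names(tapply(r[keep], bin, mean))))
  list(r = as.numeric(tapply(r[keep], bin, mean))[ord],
       v = as.numeric(tapply(plane[keep], bin, mean))[ord])
}

#' Estimate resolution FWHM from the image autocorrelation
#'
#' Extracts the ACF profile through zero lag along the requested axis
#' (lateral: radially averaged over the central z-plane of the ACF; axial:
#' the on-axis z profile), fits the two-Gaussian model and converts the
#' narrow ACF width to an image-domain FWHM in nm. The estimate covers every
#' point source in the image at once and is invariant to global intensity
#' scaling.
#'
#' @param volume a 3D array or [VolumeStack-class] containing signal.
#' @param axis \code{"lateral"} or \code{"axial"}.
#' @param spacing voxel spacing along the chosen axis in nm; defaults to the
#'   [VolumeStack-class] spacing.
#' @param maxLags number of one-sided lag samples used in the fit (default
#'   up to 64, limited by the volume size).
#' @param details return the full [ACFFit-class] instead of the FWHM?
#' @return FWHM in nm (or an [ACFFit-class] if \code{details = TRUE})
#' @export
estimateFwhm <- function(volume, axis = c("lateral", "axial"), spacing = NULL,
                         maxLags = 64L, details = FALSE) {
  axis <- match.arg(axis)
  if (is(volume, "VolumeStack")) {
    if (is.null(spacing))
      spacing <- if (axis == "axial") voxelSpacing(volume)[1] else
        voxelSpacing(volume)[2]
    volume <- stackData(volume)
  }
  if (is.null(spacing)) stop("spacing (nm) is required for plain arrays")
  ac <- autocorrelation3d(volume)
  d <- dim(ac)
  cz <- fftCentre(d[1]); cy <- fftCentre(d[2]); cx <- fftCentre(d[3])
  if (axis == "axial") {
    half <- min(d[1] - cz, maxLags)
    prof <- ac[cz:(cz + half), cy, cx]
    fit <- fitTwoGaussians(prof, spacing)
  } else {
    half <- min(d[2] - cy, d[3] - cx, maxLags)
    rs <- radialProfile(ac[cz, , ], half)
    fit <- fitTwoGaussians(rs$v, spacing, lags = rs$r * spacing)
  }
  if (details) fit else fittedFwhm(fit)
}

#' Mean squared error between two volumes
#'
#' @param a,b numeric arrays (or [VolumeStack-class]) of identical shape.
#' @return mean of squared differences
#' @export
imageMse <- function(a, b) {
  if (is(a, "VolumeStack")) a <- stackData(a)
  if (is(b, "VolumeStack")) b <- stackData(b)
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  mean((a - b)^2)
}

# 2D separable Gaussian-weighted local means ('valid' region).
gaussWindowStats <- function(x, w) {
  n <- length(w)
  half <- (n - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  if (nr < n || nc < n) stop("plane smaller than the SSIM window")
  conv1 <- function(m, along) {
    if (along == 1) {
      out <- matrix(0, nr - 2L * half, nc)
      for (i in seq_len(n))
        out <- out + w[i] * m[i:(nr - n + i), , drop = FALSE]
    } else {
      out <- matrix(0, nrow(m), nc - 2L * half)
      for (i in seq_len(n))
        out <- out + w[i] * m[, i:(nc - n + i), drop = FALSE]
    }
    out
  }
  conv1(conv1(x, 1), 2)
}

#' Structural similarity index between two volumes
#'
#' Mean SSIM computed per z-plane with a Gaussian window (default 11 samples,
#' sigma 1.5) and the standard stabilizing constants
#' \code{C1 = (K1*L)^2, C2 = (K2*L)^2}; the dynamic range L defaults to the
#' range of the reference \code{b}. Window statistics are taken over the
#' valid interior (no padding); the per-plane maps are averaged over planes.
#'
#' @param a,b numeric arrays (or [VolumeStack-class]) of identical shape;
#'   \code{b} is the reference.
#' @param winSize odd window size (default 11).
#' @param sigma Gaussian window sigma in samples (default 1.5).
#' @param K1,K2 stabilizing constants (defaults 0.01, 0.03).
#' @param dataRange dynamic range L; default \code{diff(range(b))}.
#' @return mean SSIM in [-1, 1]
#' @export
imageSsim <- function(a, b, winSize = 11L, sigma = 1.5, K1 = 0.01,
                      K2 = 0.03, dataRange = NULL) {
  if (is(a, "VolumeStack")) a <- stackData(a)
  if (is(b, "VolumeStack")) b <- stackData(b)
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  if (winSize %% 2L != 1L) stop("winSize must be odd")
  if (length(dim(a)) == 2L) {
    a <- array(a, c(1L, dim(a))); b <- array(b, c(1L, dim(b)))
  }
  if (is.null(dataRange)) dataRange <- diff(range(b))
  if (dataRange <= 0) dataRange <- 1
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  t <- seq_len(winSize) - (winSize + 1) / 2
  w <- exp(-t^2 / (2 * sigma^2)); w <- w / sum(w)
  vals <- vapply(seq_len(dim(a)[1]), function(iz) {
    pa <- a[iz, , ]; pb <- b[iz, , ]
    mua <- gaussWindowStats(pa, w)
    mub <- gaussWindowStats(pb, w)
    saa <- gaussWindowStats(pa * pa, w) - mua^2
    sbb <- gaussWindowStats(pb * pb, w) - mub^2
    sab <- gaussWindowStats(pa * pb, w) - mua * mub
    m <- ((2 * mua * mub + C1) * (2 * sab + C2)) /
      ((mua^2 + mub^2 + C1) * (saa + sbb + C2))
    mean(m)
  }, numeric(1))
  mean(vals)
}
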