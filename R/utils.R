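# Internal numerical helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package go
# through this so they are pure functions of (parameters, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Unnormalized / normalized 2D FFT pair on matrices.
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT sample frequencies in cycles per unit, spacing `d` (numpy fftfreq order).
fftFreq <- function(n, d) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / (n * d)
}

# Centre index (1-based) of the zero-lag sample after fftshift of length n.
fftCentre <- function(n) floor(n / 2) + 1L

# Shift the zero-frequency / zero-lag sample to the centre along every axis.
fftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    s <- floor(n / 2)
    return(x[c((n - s + 1L):n, 1L:(n - s))])
  }
  idx <- lapply(d, function(n) {
    s <- floor(n / 2)
    c((n - s + 1L):n, 1L:(n - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Gaussian with unit peak and FWHM `fwhm`.
gaussianEnvelope <- function(x, fwhm) exp(-4 * log(2) * (x / fwhm)^2)

# FWHM of a sampled 1D profile by linear interpolation of the half-maximum
# crossings around the peak. `spacing` converts samples to physical units.
profileFwhm <- function(y, spacing = 1) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  right <- NA_real_
  for (i in i0:(length(y) - 1L)) {
    if (y[i + 1L] <= half) {
      right <- i - i0 + (y[i] - half) / (y[i] - y[i + 1L])
      break
    }
  }
  left <- NA_real_
  for (i in i0:2L) {
    if (y[i - 1L] <= half) {
      left <- i0 - i + (y[i] - half) / (y[i] - y[i - 1L])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("profile does not fall below half maximum on both sides")
  (left + right) * spacing
}

# Validate a single non-negative count.
checkCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x %% 1 != 0)
    stop(sprintf("%s must be a single non-negative integer", name))
  as.integer(x)
}
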