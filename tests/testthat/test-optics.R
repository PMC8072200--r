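# Independent oracle: widefield in-focus PSF by direct numerical pupil
# integration (Hankel transform of a uniform circular pupil).
pupilIntegralPsf <- function(r, kc, nq = 4000L) {
  q <- seq(0, kc, length.out = nq)
  vapply(r, function(ri) {
    amp <- sum(besselJ(2 * pi * ri * q, 0) * q) * (kc / nq)
    amp^2
  }, numeric(1))
}

test_that("widefield PSF matches the direct pupil-integration oracle", {
  cfg <- opticsConfig()
  psf <- widefieldPsf(cfg, shape = c(1L, 129L, 129L), spacing = c(250, 25, 25))
  pl <- stackData(psf)[1, , ]
  ctr <- fftCentre(129L)
  prof <- pl[ctr, ctr:(ctr + 16L)]
  r <- (0:16) * 25
  oracle <- pupilIntegralPsf(r, cfg@na / cfg@wavelength)
  # discrete pupil-mask pixelation: agreement to 1% of the peak
  expect_lt(max(abs(prof / prof[1] - oracle / oracle[1])), 0.01)
  # lateral FWHM within 5% of 0.51 lambda / NA
  fw <- profileFwhm(pl[ctr, ], 25)
  expect_lt(abs(fw - 0.51 * 525 / 1.1) / (0.51 * 525 / 1.1), 0.05)
})

test_that("widefield PSF is peak-normalized, symmetric, and alias-guarded", {
  cfg <- opticsConfig()
  psf <- widefieldPsf(cfg, shape = c(3L, 64L, 64L), spacing = c(400, 100, 100))
  a <- stackData(psf)
  expect_equal(max(a), 1)
  expect_equal(a[2, fftCentre(64L), fftCentre(64L)], 1)
  # PSF(x, y, z) = PSF(-x, -y, z) for the circular pupil
  pl <- a[1, 2:64, 2:64]
  expect_equal(pl, pl[63:1, 63:1], tolerance = 1e-10)
  expect_error(widefieldPsf(cfg, shape = c(1L, 32L, 32L),
    spacing = c(250, 200, 200)), "under-samples")
})

test_that("hexagonal illumination is non-negative with an exactly uniform 7-frame sum", {
  cfg <- smallConfig()
  s <- matrix(0, 48, 48)
  for (f in 0:6) {
    fr <- hexagonalIllumination(cfg, f, 48L)
    expect_true(min(fr) >= 0)
    s <- s + fr
  }
  expect_lt(max(abs(s / 7 - 3)) / 3, 1e-6)
  expect_error(hexagonalIllumination(cfg, 7), "0..6")
})

test_that("one frame is exactly a DC plus 6 hexagonal carriers", {
  cfg <- smallConfig()
  n <- 32L
  fr <- hexagonalIllumination(cfg, 2, n)
  bands <- AxialSIM:::hexBands(cfg)
  p <- samplePixel(cfg)
  coord <- (seq_len(n) - 1) * p
  model <- matrix(0i, n, n)
  for (j in 1:7) {
    g <- bands$carriers[j, ]
    phase <- 2 * pi * 2 * bands$d[j] / 7
    model <- model + bands$weights[j] * exp(1i * phase) *
      outer(exp(2i * pi * g[2] * coord), exp(2i * pi * g[1] * coord))
  }
  expect_equal(fr, Re(model), tolerance = 1e-10)
  # all six carriers share the magnitude sqrt(3) * NA / lambda
  mags <- sqrt(rowSums(bands$carriers[2:7, ]^2))
  expect_equal(mags, rep(sqrt(3) * cfg@na / cfg@wavelength, 6))
})

test_that("raw SIM stacks have the contracted shape and degenerate cases", {
  cfg <- smallConfig()
  st <- renderSimStack(singleEmitterCloud(), cfg)
  expect_s4_class(st, "SIMStack")
  expect_identical(dim(stackData(st)), c(8L, 7L, 64L, 64L))
  expect_true(min(stackData(st)) >= 0)
  expect_warning(z <- renderSimStack(newPointCloud(NULL), cfg),
    "no emitters")
  expect_true(all(stackData(z) == 0))
  # emitters far outside the axial range also yield a zero stack
  expect_warning(
    z2 <- renderSimStack(singleEmitterCloud(z = 50), cfg), "no emitters")
  expect_true(all(stackData(z2) == 0))
})

test_that("a single on-axis emitter images to the detection PSF", {
  cfg <- oddConfig()
  wf <- renderWidefieldStack(singleEmitterCloud(), cfg)
  img <- stackData(wf)[5, , ]    # plane exactly at the emitter's focus
  eng <- AxialSIM:::otfEngine(64L, samplePixel(cfg), cfg@wavelength, cfg@na)
  psf <- fftShift(Re(ifft2(eng$otfAt(0))) * 64^2)
  psf <- psf / sum(psf)
  expect_equal(img / max(img), psf / max(psf), tolerance = 1e-6)
})

test_that("rendering is linear and translation-equivariant", {
  cfg <- smallConfig()
  a <- newPointCloud(matrix(c(-0.4, 0.2, 0.1, 0.3, -0.1, -0.2), 2, 3,
    byrow = TRUE))
  b <- newPointCloud(matrix(c(0.5, -0.3, 0.0), 1, 3))
  ab <- newPointCloud(rbind(positions(a), positions(b)))
  sa <- stackData(renderSimStack(a, cfg))
  sb <- stackData(renderSimStack(b, cfg))
  sab <- stackData(renderSimStack(ab, cfg))
  expect_equal(sab, sa + sb, tolerance = 1e-6 * max(sab))

  # shifting by an integer number of sample pixels shifts the image
  # identically (periodic boundaries). The fixed-in-space illumination
  # pattern is not translation-invariant frame by frame, so equivariance
  # holds for the pattern-free widefield image and for the uniform 7-frame
  # total.
  px <- samplePixel(cfg) / 1000   # um
  sh <- newPointCloud(sweep(positions(a), 2, c(5 * px, 3 * px, 0), `+`))
  roll <- function(x, k) if (k == 0) x else c(tail(x, k), head(x, -k))
  wa <- stackData(renderWidefieldStack(a, cfg))
  ws <- stackData(renderWidefieldStack(sh, cfg))
  expect_equal(ws, wa[, roll(1:64, 3), roll(1:64, 5)],
    tolerance = 1e-9 * max(wa))
  ss <- stackData(renderSimStack(sh, cfg))
  totA <- apply(sa, c(1, 3, 4), sum)
  totS <- apply(ss, c(1, 3, 4), sum)
  expect_equal(totS, totA[, roll(1:64, 3), roll(1:64, 5)],
    tolerance = 1e-8 * max(totA))
})

test_that("the 7-frame sum equals 21x the light-sheet widefield image", {
  cfg <- smallConfig()
  cl <- generateSphereCloud(40, 0.9, seed = 4)
  sim <- stackData(renderSimStack(cl, cfg))
  wf <- stackData(renderWidefieldStack(cl, cfg, lightsheet = TRUE))
  total <- apply(sim, c(1, 3, 4), sum)
  expect_equal(total, 21 * wf, tolerance = 1e-6 * max(total))
})

test_that("confocal targets triple planes, double pixels and sharpen axially", {
  cfg <- smallConfig()
  hr <- renderConfocalTarget(singleEmitterCloud(), cfg)
  expect_identical(dim(stackData(hr)), c(24L, 128L, 128L))
  expect_equal(voxelSpacing(hr), c(cfg@dz / 3, samplePixel(cfg) / 2,
    samplePixel(cfg) / 2))
  d <- stackData(hr)
  pk <- which(d == max(d), arr.ind = TRUE)[1, ]
  axHr <- profileFwhm(d[, pk[2], pk[3]], cfg@dz / 3)
  wf <- stackData(renderWidefieldStack(singleEmitterCloud(), cfg))
  pkw <- which(wf == max(wf), arr.ind = TRUE)[1, ]
  axWf <- profileFwhm(wf[, pkw[2], pkw[3]], cfg@dz)
  expect_lt(axHr, axWf / 2)
  expect_warning(z <- renderConfocalTarget(newPointCloud(NULL), cfg),
    "no emitters")
  expect_true(all(stackData(z) == 0))
})

test_that("Poisson noise is seeded, zero-preserving and correctly scaled", {
  cfg <- oddConfig()
  st <- renderSimStack(singleEmitterCloud(), cfg)
  n1 <- addPoissonNoise(st, 2048, seed = 3)
  n2 <- addPoissonNoise(st, 2048, seed = 3)
  expect_identical(stackData(n1), stackData(n2))
  expect_identical(n1@units, "counts")
  # a unit emitter at best focus yields ~2048 expected photons over the
  # 7 frames of its focal plane
  expected <- sum(stackData(st)[5, , , ]) * 2048 / 21
  expect_equal(expected, 2048, tolerance = 0.02)
  observed <- sum(stackData(n1)[5, , , ])
  expect_lt(abs(observed - expected), 6 * sqrt(expected))
  # Poisson(0) = 0
  zero <- new("SIMStack", data = array(0, c(2, 7, 8, 8)),
    config = cfg, units = "expected")
  expect_true(all(stackData(addPoissonNoise(zero, 100, 1)) == 0))
  expect_error(addPoissonNoise(st, 0), "positive")
})
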