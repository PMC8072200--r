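test_that("band separation matches the closed form for a single emitter", {
  cfg <- oddConfig()
  x0 <- 0.13; y0 <- -0.21     # um, sub-pixel position
  st <- renderSimStack(singleEmitterCloud(x0, y0, 0), cfg)
  params <- defaultReconParams(cfg)
  bands <- separateComponents(stackData(st)[5, , , ], params)

  n <- 64L
  p <- samplePixel(cfg)
  xc <- x0 * 1000 + (n / 2) * p
  yc <- y0 * 1000 + (n / 2) * p
  eng <- AxialSIM:::otfEngine(n, p, cfg@wavelength, cfg@na)
  otf0 <- eng$otfAt(0)
  kx <- fftFreq(n, p)
  ramp <- outer(exp(-2i * pi * kx * yc), exp(-2i * pi * kx * xc))
  hb <- AxialSIM:::hexBands(cfg)
  for (j in 1:7) {
    g <- hb$carriers[j, ]
    expected <- hb$weights[j] * exp(2i * pi * (g[1] * xc + g[2] * yc)) *
      otf0 * ramp
    expect_equal(bands[[j]], expected,
      tolerance = 1e-6 * max(Mod(expected)))
  }
})

test_that("identical frames carry no modulation and mixing round-trips", {
  cfg <- smallConfig()
  params <- defaultReconParams(cfg)
  one <- matrix(runif(32 * 32), 32, 32)
  frames <- array(0, c(7, 32, 32))
  for (f in 1:7) frames[f, , ] <- one
  bands <- separateComponents(frames, params)
  dc <- max(Mod(bands[[1]]))
  for (j in 2:7) expect_lt(max(Mod(bands[[j]])), 1e-10 * dc)

  # forward mix with the phase matrix, then separate: identity on bands.
  # Bands in conjugate pairs so the mixed frames are real images.
  set.seed(11)
  cplx <- function() matrix(complex(real = rnorm(256),
    imaginary = rnorm(256)), 16)
  synth <- list(matrix(rnorm(256), 16))
  for (m in 1:3) {
    cm <- cplx()
    synth <- c(synth, list(cm, Conj(cm)))
  }
  M <- params@phaseMatrix
  mixed <- array(0, c(7, 16, 16))
  for (f in 1:7) {
    acc <- matrix(0i, 16, 16)
    for (j in 1:7) acc <- acc + M[f, j] * synth[[j]]
    expect_lt(max(abs(Im(acc))), 1e-10)
    mixed[f, , ] <- Re(acc)
  }
  sep <- separateComponents(mixed, params)
  for (j in 1:7)
    expect_equal(sep[[j]], fft2(synth[[j]]), tolerance = 1e-8)
})

test_that("separation validates input shape and matrix conditioning", {
  cfg <- smallConfig()
  params <- defaultReconParams(cfg)
  expect_error(separateComponents(array(0, c(6, 8, 8)), params), "7")
  bad <- params
  bad@phaseMatrix <- matrix(1 + 0i, 7, 7)
  expect_error(separateComponents(array(1, c(7, 8, 8)), bad), "singular")
})

test_that("reconstruction has the contracted geometry and degenerate cases", {
  cfg <- smallConfig()
  zero <- new("SIMStack", data = array(0, c(8, 7, 64, 64)), config = cfg,
    units = "expected")
  rec <- reconstructSim(zero)
  expect_identical(dim(stackData(rec)), c(24L, 128L, 128L))
  expect_true(all(stackData(rec) == 0))
  expect_equal(voxelSpacing(rec),
    c(cfg@dz / 3, samplePixel(cfg) / 2, samplePixel(cfg) / 2))
})

test_that("reconstruction doubles lateral resolution on a single emitter", {
  cfg <- smallConfig()
  st <- getFixture("recSingle", function()
    reconstructSim(renderSimStack(singleEmitterCloud(), cfg)))
  d <- stackData(st)
  pk <- which(d == max(d), arr.ind = TRUE)[1, ]
  fwRec <- profileFwhm(d[pk[1], pk[2], ], samplePixel(cfg) / 2)
  wf <- stackData(renderWidefieldStack(singleEmitterCloud(), cfg))
  pkw <- which(wf == max(wf), arr.ind = TRUE)[1, ]
  fwWf <- profileFwhm(wf[pkw[1], pkw[2], ], samplePixel(cfg))
  expect_lt(abs(fwRec / fwWf - 0.5), 0.15 * 0.5)
})

test_that("150 nm emitter pairs resolve in the reconstruction but not widefield", {
  cfg <- smallConfig()
  pair <- newPointCloud(matrix(c(-0.075, 0, 0, 0.075, 0, 0), 2, 3,
    byrow = TRUE))
  rec <- stackData(reconstructSim(renderSimStack(pair, cfg)))
  wf <- stackData(renderWidefieldStack(pair, cfg))
  pk <- which(rec == max(rec), arr.ind = TRUE)[1, ]
  profR <- rec[pk[1], pk[2], ]
  # two local maxima with a dip between them along x
  localMax <- which(diff(sign(diff(profR))) == -2) + 1L
  sep150 <- localMax[profR[localMax] > 0.3 * max(profR)]
  expect_gte(length(sep150), 2L)
  pkw <- which(wf == max(wf), arr.ind = TRUE)[1, ]
  profW <- wf[pkw[1], pkw[2], ]
  localMaxW <- which(diff(sign(diff(profW))) == -2) + 1L
  expect_equal(length(localMaxW[profW[localMaxW] > 0.3 * max(profW)]), 1L)
})

test_that("apodization suppresses energy beyond the extended support", {
  cfg <- smallConfig()
  rec <- reconstructSim(renderSimStack(singleEmitterCloud(), cfg),
    clampNegative = FALSE)
  pl <- stackData(rec)[12, , ]
  sp <- Mod(fft2(pl))^2
  kf <- fftFreq(128L, samplePixel(cfg) / 2)
  kr <- sqrt(outer(kf^2, kf^2, `+`))
  beyond <- kr > 2 * (2 * cfg@na / cfg@wavelength)
  expect_lt(sum(sp[beyond]) / sum(sp), 1e-4)
})

test_that("reconstruction is approximately linear before clamping", {
  cfg <- smallConfig()
  a <- renderSimStack(newPointCloud(matrix(c(-0.5, 0.3, 0.2), 1, 3)), cfg)
  b <- renderSimStack(newPointCloud(matrix(c(0.4, -0.2, -0.3), 1, 3)), cfg)
  ab <- new("SIMStack", data = stackData(a) + stackData(b), config = cfg,
    units = "expected")
  ra <- stackData(reconstructSim(a))
  rb <- stackData(reconstructSim(b))
  rab <- stackData(reconstructSim(ab))
  # clamping-only nonlinearity: agreement to a small fraction of the peak
  expect_equal(rab, ra + rb, tolerance = 5e-3 * max(rab))
})
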