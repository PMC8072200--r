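test_that("autocorrelation matches direct circular correlation on random volumes", {
  set.seed(3)
  v <- array(runif(16^3), c(16, 16, 16))
  ac <- autocorrelation3d(v)
  # brute-force circular autocovariance oracle
  vc <- v - mean(v)
  shift3 <- function(a, s) {
    idx <- lapply(1:3, function(k) ((seq_len(16) - 1 + s[k]) %% 16) + 1)
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  ctr <- fftCentre(16L)
  norm0 <- sum(vc * vc)
  for (lag in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 5), c(3, 3, 3),
    c(15, 1, 7))) {
    direct <- sum(vc * shift3(vc, lag)) / norm0
    got <- ac[ctr + ifelse(lag[1] > 8, lag[1] - 16, lag[1]),
      ctr + ifelse(lag[2] > 8, lag[2] - 16, lag[2]),
      ctr + ifelse(lag[3] > 8, lag[3] - 16, lag[3])]
    expect_equal(got, direct, tolerance = 1e-10)
  }
})

test_that("autocorrelation basics: impulse, symmetry, peak at zero lag", {
  imp <- array(0, c(8, 8, 8)); imp[3, 5, 2] <- 1
  ac <- autocorrelation3d(imp, demean = FALSE)
  ctr <- fftCentre(8L)
  expect_equal(ac[ctr, ctr, ctr], 1)
  expect_equal(sum(abs(ac) > 1e-12), 1L)

  set.seed(8)
  v <- array(runif(12^3), c(12, 12, 12))
  ac2 <- autocorrelation3d(v)
  expect_equal(which(ac2 == max(ac2), arr.ind = TRUE)[1, ],
    rep(fftCentre(12L), 3), ignore_attr = TRUE)
  # ACF(tau) = ACF(-tau)
  flip <- ac2[12:2, 12:2, 12:2]
  expect_equal(ac2[2:12, 2:12, 2:12], flip[11:1, 11:1, 11:1],
    tolerance = 1e-12)
  expect_error(autocorrelation3d(array(0, c(4, 4, 4))), "no signal")
})

test_that("two-Gaussian fit recovers known profiles and picks the narrow term", {
  tau <- (0:60) * 50
  prof1 <- exp(-tau^2 / (2 * 200^2))
  fit1 <- fitTwoGaussians(prof1, 50)
  expect_lt(abs(min(fit1@sigma1, fit1@sigma2) - 200) / 200, 1e-3)

  prof2 <- 0.6 * exp(-tau^2 / (2 * 150^2)) + 0.4 * exp(-tau^2 / (2 * 600^2))
  fit2 <- fitTwoGaussians(prof2, 50)
  # FWHM reported from the 150 nm component
  expect_equal(fittedFwhm(fit2), 2 * sqrt(2 * log(2)) * 150 / sqrt(2),
    tolerance = 0.01)
})

test_that("bead volumes with Gaussian PSF yield FWHM = 2.355 sigma", {
  for (sig in c(100, 200, 400)) {
    nl <- as.integer(128 * sig / 100)
    vol <- makeBeadVolume(sig, spacing = 50, dims = c(24L, nl, nl))
    fw <- estimateFwhm(vol, "lateral", spacing = 50)
    expect_lt(abs(fw - 2.355 * sig) / (2.355 * sig), 0.05)
  }
})

test_that("FWHM estimation is unit-linear and scale-invariant", {
  vol <- makeBeadVolume(150, spacing = 50)
  f1 <- estimateFwhm(vol, "lateral", spacing = 50)
  expect_equal(estimateFwhm(vol, "lateral", spacing = 100), 2 * f1,
    tolerance = 1e-9)
  expect_equal(estimateFwhm(vol * 370, "lateral", spacing = 50), f1,
    tolerance = 1e-8)
})

test_that("widefield FWHM of a sparse in-focus cloud matches the single-bead PSF", {
  cfg <- opticsConfig(cameraSize = 128L, nPlanes = 3L)
  wf <- renderWidefieldStack(makeThinCloud(250, seed = 14), cfg)
  fw <- estimateFwhm(wf, "lateral")
  single <- stackData(renderWidefieldStack(singleEmitterCloud(), cfg))
  pk <- which(single == max(single), arr.ind = TRUE)[1, ]
  direct <- profileFwhm(single[pk[1], pk[2], ], samplePixel(cfg))
  expect_lt(abs(fw - direct) / direct, 0.10)
})

test_that("emitter density does not move the narrow FWHM component", {
  cfg <- opticsConfig(cameraSize = 128L, nPlanes = 3L)
  fs <- estimateFwhm(
    renderWidefieldStack(makeThinCloud(250, seed = 14), cfg), "lateral")
  fd <- estimateFwhm(
    renderWidefieldStack(makeThinCloud(1500, seed = 114), cfg), "lateral")
  expect_lt(abs(fs - fd) / fs, 0.10)
})

test_that("axial resolution orders as confocal < SIM reconstruction < widefield", {
  cfg <- toyConfig()
  cl <- generateChromatinCloud(300L, 2.5, 0.05, seed = 21, zExtent = 1)
  sim <- renderSimStack(cl, cfg)
  fwRec <- estimateFwhm(reconstructSim(sim), "axial")
  fwHr <- estimateFwhm(renderConfocalTarget(cl, cfg), "axial")
  fwWf <- estimateFwhm(renderWidefieldStack(cl, cfg), "axial")
  expect_lt(fwHr, fwRec)
  expect_lt(fwRec, fwWf)
})

test_that("mse and ssim behave on identity, degradation and a hand oracle", {
  set.seed(2)
  a <- array(runif(4 * 20 * 20), c(4, 20, 20))
  expect_equal(imageMse(a, a), 0)
  expect_equal(imageSsim(a, a), 1)
  expect_lt(imageSsim(1 - a, a), imageSsim(a, a))
  expect_gt(imageMse(1 - a, a), 0)
  expect_error(imageMse(a, a[, 1:10, ]), "differ")

  # direct windowed-SSIM oracle on one plane, small window
  pa <- a[1, , ]; pb <- (a[2, , ] + pa) / 2
  win <- 5L; sigma <- 1.5
  t <- seq_len(win) - 3; w1 <- exp(-t^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  w2 <- outer(w1, w1)
  L <- diff(range(pb)); C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  vals <- c()
  for (i in 3:18) for (j in 3:18) {
    wa <- pa[(i - 2):(i + 2), (j - 2):(j + 2)]
    wb <- pb[(i - 2):(i + 2), (j - 2):(j + 2)]
    mua <- sum(w2 * wa); mub <- sum(w2 * wb)
    va <- sum(w2 * wa^2) - mua^2; vb <- sum(w2 * wb^2) - mub^2
    cab <- sum(w2 * wa * wb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
      ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  got <- imageSsim(pa, pb, winSize = 5L, sigma = 1.5, dataRange = L)
  expect_equal(got, mean(vals), tolerance = 1e-10)
})
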