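# Shared fixtures, memoised so expensive renders are computed once per run.

.fixtureCache <- new.env(parent = emptyenv())

getFixture <- function(name, fn) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- fn()
  .fixtureCache[[name]]
}

# small optics for unit tests (64 px camera, 8 planes)
smallConfig <- function() opticsConfig(cameraSize = 64L, nPlanes = 8L)

# odd-plane config: plane 5 sits exactly at z = 0
oddConfig <- function() opticsConfig(cameraSize = 64L, nPlanes = 9L)

# toy scale used for network experiments (32 px, 16 planes)
toyConfig <- function() opticsConfig(cameraSize = 32L, nPlanes = 16L)

singleEmitterCloud <- function(x = 0, y = 0, z = 0, w = 1) {
  newPointCloud(matrix(c(x, y, z), 1, 3), weights = w)
}

# synthetic volume of isolated beads blurred by a Gaussian PSF of known
# sigma (nm), built directly in image space: the independent oracle for the
# ACF-based FWHM estimator. Beads are kept sparse and clear of the
# boundaries so the narrow ACF component is the PSF autocorrelation.
makeBeadVolume <- function(sigmaLat, spacing, dims = c(24L, 128L, 128L),
                           nBeads = 10L, sigmaAx = sigmaLat / 2,
                           seed = 42L) {
  set.seed(seed)
  vol <- array(0, dims)
  zc <- seq_len(dims[1]); yc <- seq_len(dims[2]); xc <- seq_len(dims[3])
  margin <- ceiling(3 * sigmaLat / spacing) + 4
  minSep <- 8 * sigmaLat / spacing   # enforce isolation (pixels)
  placed <- matrix(numeric(0), 0, 2)
  for (b in seq_len(nBeads)) {
    repeat {
      lat <- c(runif(1, margin, dims[2] - margin + 1),
        runif(1, margin, dims[3] - margin + 1))
      if (nrow(placed) == 0 ||
          min(sqrt(rowSums(sweep(placed, 2, lat)^2))) >= minSep) break
    }
    placed <- rbind(placed, lat)
    p <- c(runif(1, dims[1] / 2 - 2, dims[1] / 2 + 3), lat)
    gz <- exp(-((zc - p[1]) * spacing)^2 / (2 * sigmaAx^2))
    gy <- exp(-((yc - p[2]) * spacing)^2 / (2 * sigmaLat^2))
    gx <- exp(-((xc - p[3]) * spacing)^2 / (2 * sigmaLat^2))
    vol <- vol + outer(gz, outer(gy, gx))
  }
  vol
}

# thin, laterally spread in-focus cloud: the geometry under which the
# narrow ACF component equals the in-focus PSF autocorrelation
makeThinCloud <- function(n, seed, halfSide = 5, zHalf = 0.05) {
  set.seed(seed)
  newPointCloud(cbind(runif(n, -halfSide, halfSide),
    runif(n, -halfSide, halfSide), runif(n, -zHalf, zHalf)))
}

# random normalized chunk pairs for training smoke tests
randomChunkPairs <- function(n, chunkSize = 3L, H = 16L, seed = 5L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    new("ChunkPair",
      input = array(runif(7L * chunkSize * H * H), c(7L * chunkSize, H, H)),
      target = array(runif(3L * chunkSize * 4L * H * H),
        c(3L * chunkSize, 2L * H, 2L * H)),
      stackId = sprintf("rand%d", i), startPlane = 0L,
      normInput = c(0, 1), normTarget = c(0, 1)))
}

# small trained network on matched simulated data (toy scale), shared by
# network-behaviour tests; a few minutes of CPU once per run.
getToyTrained <- function() {
  getFixture("toyTrained", function() {
    cfg <- toyConfig()
    stacks <- lapply(1:7, function(i) {
      cl <- generateChromatinCloud(400L, 3, 0.05, seed = 100 + i,
        zExtent = 1)
      list(sim = renderSimStack(cl, cfg),
        hr = renderConfocalTarget(cl, cfg))
    })
    chunks <- unlist(lapply(seq_along(stacks)[1:5], function(i) {
      s <- stacks[[i]]
      sa <- stackData(s$sim); sa <- sa / max(sa)
      ha <- stackData(s$hr); ha <- ha / max(ha)
      normalizeChunks(chunkStack(sa, ha, stackId = sprintf("toy%d", i)))
    }), recursive = FALSE)
    model <- buildRcan(rcanConfig(nGroups = 2L, nBlocks = 2L,
      featChannels = 16L), seed = 1L)
    fit <- trainRcan(model, chunks, list(), epochs = 30L, lr = 2e-3,
      seed = 2L)
    list(cfg = cfg, fit = fit, held = stacks[6:7])
  })
}
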