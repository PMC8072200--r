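# End-to-end experiment drivers: dataset generation, baseline comparison
# and the Poisson-noise sweep. Every run is reproducible from its
# configuration and seed alone.

# Stable per-specimen seed derived from the experiment seed (kept below
# 2^31 - 1).
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}

# Min-max normalize a volume to [0, 1] (for scale-free MSE/SSIM comparisons
# between reconstructions and the reference).
norm01 <- function(v) {
  v <- v - min(v)
  m <- max(v)
  if (m > 0) v / m else v
}

# Central lateral crop of a (nz, ny, nx) array to at most `side` pixels;
# keeps ACF estimation affordable on large reconstructions.
centralCrop <- function(arr, side = 256L) {
  d <- dim(arr)
  iy <- if (d[2] > side) (d[2] - side) %/% 2L + seq_len(side) else
    seq_len(d[2])
  ix <- if (d[3] > side) (d[3] - side) %/% 2L + seq_len(side) else
    seq_len(d[3])
  arr[, iy, ix, drop = FALSE]
}

#' Specimen recipe for dataset generation
#'
#' Defaults describe the training corpus: 100 chromatin structures of 5000
#' emitters (confined walks bounded in a 16 x 16 um square) and 68 spherical
#' clouds of 1000 emitters within a 5 um radius.
#'
#' @param nChromatin,nSphere number of specimens per class.
#' @param chromatinPoints,spherePoints emitters per specimen.
#' @param boxSide,step,zExtent chromatin walk parameters (um).
#' @param sphereRadius sphere radius (um).
#' @return a list recipe consumed by [generateDataset()]
#' @export
specimenRecipe <- function(nChromatin = 100L, nSphere = 68L,
                           chromatinPoints = 5000L, spherePoints = 1000L,
                           boxSide = 16, step = 0.05, zExtent = 2,
                           sphereRadius = 5) {
  list(nChromatin = as.integer(nChromatin), nSphere = as.integer(nSphere),
    chromatinPoints = as.integer(chromatinPoints),
    spherePoints = as.integer(spherePoints), boxSide = boxSide, step = step,
    zExtent = zExtent, sphereRadius = sphereRadius)
}

#' Simulate a training dataset of SIM / high-resolution stack pairs
#'
#' For every specimen in the recipe: generates the point cloud, renders the
#' raw 7-frame SIM stack and the high-resolution confocal target (both
#' peak-scaled to 1), chunks the pair, applies the low-signal filters and
#' records the counts. Stacks are optionally written as TIFF pairs; chunks
#' are optionally returned in memory (normalized). Rerunning with the same
#' configuration and seed reproduces the dataset exactly.
#'
#' @param recipe a [specimenRecipe()].
#' @param config an [OpticsConfig-class].
#' @param chunkSize,trim chunking parameters (defaults 3 and 2).
#' @param pairThreshold,chunkThreshold low-signal thresholds (defaults 5e-7
#'   and 1e-7).
#' @param nTestChromatin,nTestSphere stacks reserved for the test split.
#' @param valFraction chunk-level validation fraction (default 0.1).
#' @param seed experiment seed; per-specimen seeds derive from it.
#' @param outDir optional directory for TIFF output and the JSON manifest.
#' @param returnChunks keep the normalized chunks in memory (lists
#'   \code{train}, \code{validation}, \code{test})? Default FALSE.
#' @return list with \code{manifest} ([SplitManifest-class]), \code{counts}
#'   (per-stack data.frame with pre/post-filter chunk counts) and, when
#'   requested, \code{chunks}
#' @export
generateDataset <- function(recipe = specimenRecipe(),
                            config = opticsConfig(), chunkSize = 3L,
                            trim = 2L, pairThreshold = 5e-7,
                            chunkThreshold = 1e-7, nTestChromatin = 10L,
                            nTestSphere = 20L, valFraction = 0.1, seed = 1L,
                            outDir = NULL, returnChunks = FALSE) {
  classes <- c(rep("chromatin", recipe$nChromatin),
    rep("sphere", recipe$nSphere))
  ids <- sprintf("%s%03d", classes, c(seq_len(recipe$nChromatin),
    seq_len(recipe$nSphere)))
  counts <- data.frame(stackId = ids, class = classes,
    nChunksPreFilter = 0L, nChunksPostFilter = 0L,
    stringsAsFactors = FALSE)
  allChunks <- list()
  processSpecimen <- function(i) {
    si <- deriveSeed(seed, i)
    cloud <- if (classes[i] == "chromatin")
      generateChromatinCloud(recipe$chromatinPoints, recipe$boxSide,
        recipe$step, seed = si, zExtent = recipe$zExtent)
    else
      generateSphereCloud(recipe$spherePoints, recipe$sphereRadius,
        seed = si)
    sim <- renderSimStack(cloud, config)
    hr <- renderConfocalTarget(cloud, config)
    simScaled <- stackData(sim)
    if (max(simScaled) > 0) simScaled <- simScaled / max(simScaled)
    hrScaled <- stackData(hr)
    if (max(hrScaled) > 0) hrScaled <- hrScaled / max(hrScaled)
    pairs <- suppressWarnings(chunkStack(simScaled, hrScaled,
      chunkSize = chunkSize, trim = trim, stackId = ids[i]))
    pre <- length(pairs)
    pairs <- filterLowSignal(pairs, pairThreshold, chunkThreshold)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeTiffStack(sim, file.path(outDir, paste0(ids[i], "_sim.tif")))
      writeTiffStack(hr, file.path(outDir, paste0(ids[i], "_hr.tif")))
    }
    list(pre = pre, post = length(pairs),
      chunks = if (returnChunks && length(pairs)) normalizeChunks(pairs)
        else list())
  }
  for (i in seq_along(ids)) {
    res <- tryCatch(processSpecimen(i), error = function(e) {
      warning(sprintf("specimen %s failed: %s", ids[i],
        conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    counts$nChunksPreFilter[i] <- res$pre
    counts$nChunksPostFilter[i] <- res$post
    if (returnChunks && length(res$chunks))
      allChunks[[ids[i]]] <- res$chunks
  }
  manifest <- makeSplit(ids, classes, nTestChromatin, nTestSphere,
    valFraction, seed)
  out <- list(manifest = manifest, counts = counts)
  if (returnChunks) {
    trainAll <- unlist(allChunks[names(allChunks) %in% manifest@trainIds],
      recursive = FALSE, use.names = FALSE)
    testAll <- unlist(allChunks[names(allChunks) %in% manifest@testIds],
      recursive = FALSE, use.names = FALSE)
    if (is.null(trainAll)) trainAll <- list()
    if (is.null(testAll)) testAll <- list()
    nVal <- round(valFraction * length(trainAll))
    valIdx <- withSeed(deriveSeed(seed, 999983), {
      if (nVal > 0) sample(length(trainAll), nVal) else integer(0)
    })
    out$chunks <- list(
      train = if (length(valIdx)) trainAll[-valIdx] else trainAll,
      validation = trainAll[valIdx],
      test = testAll)
  }
  if (!is.null(outDir)) {
    jsonlite::write_json(list(
      stackIds = ids, classes = classes,
      testIds = manifest@testIds, trainIds = manifest@trainIds,
      valFraction = valFraction, seed = seed,
      counts = counts), file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Compare the RCAN against the classical SIM baseline
#'
#' Simulates held-out chromatin structures, reconstructs each with the
#' classical algorithm and with the network, and evaluates axial and
#' lateral FWHM (autocorrelation method) plus MSE and SSIM against the
#' high-resolution confocal reference (volumes min-max normalized before
#' comparison). The reference's own FWHM values are reported alongside.
#'
#' @param model a trained \code{RCANModel}.
#' @param config an [OpticsConfig-class].
#' @param nStructures held-out structures to simulate (default 5).
#' @param nPoints,boxSide,step,zExtent chromatin parameters.
#' @param seed experiment seed (structures derive from it; disjoint from
#'   dataset seeds by offset).
#' @return list with \code{results} (long data.frame: structure, method,
#'   metric, value) and \code{summary} (mean and sd per method and metric)
#' @export
compareBaseline <- function(model, config = opticsConfig(),
                            nStructures = 5L, nPoints = 5000L, boxSide = 16,
                            step = 0.05, zExtent = 2, seed = 1L) {
  rows <- list()
  for (i in seq_len(nStructures)) {
    cloud <- generateChromatinCloud(nPoints, boxSide, step,
      seed = deriveSeed(seed, 5000 + i), zExtent = zExtent)
    sim <- renderSimStack(cloud, config)
    hr <- renderConfocalTarget(cloud, config)
    ref <- norm01(stackData(hr))
    outs <- list(
      sim = norm01(stackData(reconstructSim(sim))),
      rcan = norm01(stackData(inferRcan(model, sim))))
    p2 <- samplePixel(config) / 2
    for (method in names(outs)) {
      v <- outs[[method]]
      rows[[length(rows) + 1L]] <- data.frame(structure = i,
        method = method,
        axialFwhm = estimateFwhm(centralCrop(v), "axial", config@dz / 3),
        lateralFwhm = estimateFwhm(centralCrop(v), "lateral", p2),
        mse = imageMse(v, ref), ssim = imageSsim(v, ref))
    }
    rows[[length(rows) + 1L]] <- data.frame(structure = i,
      method = "reference",
      axialFwhm = estimateFwhm(centralCrop(ref), "axial", config@dz / 3),
      lateralFwhm = estimateFwhm(centralCrop(ref), "lateral", p2),
      mse = 0, ssim = 1)
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(
    results[, c("axialFwhm", "lateralFwhm", "mse", "ssim")],
    by = list(method = results$method),
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  list(results = results, summary = agg)
}

#' Poisson-noise robustness sweep
#'
#' For each noise level (expected signal photons per emitter over 7 SIM
#' frames) and each simulated chromatin structure: adds Poisson noise to the
#' clean raw stack, reconstructs with the classical algorithm and the
#' network, and evaluates axial FWHM, MSE and SSIM against the clean
#' high-resolution reference.
#'
#' @param model a trained \code{RCANModel}.
#' @param config an [OpticsConfig-class].
#' @param levels photon levels, e.g. \code{c(2048, 16)}.
#' @param nStructures structures per level (default 4).
#' @param nPoints,boxSide,step,zExtent chromatin parameters.
#' @param seed experiment seed.
#' @param csvPath optional path for a CSV copy of the table.
#' @return data.frame (level, structure, method, axialFwhm, mse, ssim)
#' @export
runNoiseSweep <- function(model, config = opticsConfig(),
                          levels = c(2048, 512, 128, 32, 16),
                          nStructures = 4L, nPoints = 5000L, boxSide = 16,
                          step = 0.05, zExtent = 2, seed = 1L,
                          csvPath = NULL) {
  rows <- list()
  if (length(levels)) for (i in seq_len(nStructures)) {
    cloud <- generateChromatinCloud(nPoints, boxSide, step,
      seed = deriveSeed(seed, 7000 + i), zExtent = zExtent)
    sim <- renderSimStack(cloud, config)
    ref <- norm01(stackData(renderConfocalTarget(cloud, config)))
    for (lv in levels) {
      noisy <- addPoissonNoise(sim, lv, seed = deriveSeed(seed, 8000 + i))
      outs <- list(
        sim = norm01(stackData(reconstructSim(noisy))),
        rcan = norm01(stackData(inferRcan(model, noisy))))
      for (method in names(outs)) {
        v <- outs[[method]]
        rows[[length(rows) + 1L]] <- data.frame(level = lv, structure = i,
          method = method,
          axialFwhm = estimateFwhm(centralCrop(v), "axial", config@dz / 3),
          mse = imageMse(v, ref), ssim = imageSsim(v, ref))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = numeric(0), structure = integer(0),
      method = character(0), axialFwhm = numeric(0), mse = numeric(0),
      ssim = numeric(0))
  if (!is.null(csvPath)) utils::write.csv(out, csvPath, row.names = FALSE)
  out
}
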