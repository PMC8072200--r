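# Chunking, low-signal filtering, normalization and split bookkeeping for
# network training data.

#' Slice a SIM/HR stack pair into training chunks
#'
#' Trims \code{trim} planes at each stack end (the simulated stacks carry
#' little signal there), then emits non-overlapping chunks of
#' \code{chunkSize} consecutive SIM planes with the aligned
#' \code{3*chunkSize} high-resolution planes. A 40-plane stack at the
#' default \code{chunkSize = 3} and \code{trim = 2} yields 12 chunks; in
#' general \code{floor((nPlanes - 2*trim) / chunkSize)}.
#'
#' @param sim a [SIMStack-class] (or a \code{(nPlanes, 7, H, W)} array).
#' @param hr a [VolumeStack-class] (or a \code{(3*nPlanes, 2H, 2W)} array)
#'   with exactly 3x the SIM plane count.
#' @param chunkSize consecutive SIM planes per chunk (default 3).
#' @param trim planes dropped at each stack end (default 2).
#' @param stackId identifier recorded in chunk provenance.
#' @return list of [ChunkPair-class] (possibly empty, with a warning when
#'   the trimmed stack is shorter than one chunk)
#' @export
chunkStack <- function(sim, hr, chunkSize = 3L, trim = 2L,
                       stackId = "stack") {
  simArr <- if (is(sim, "SIMStack")) stackData(sim) else sim
  hrArr <- if (is(hr, "VolumeStack")) stackData(hr) else hr
  if (length(dim(simArr)) != 4L || dim(simArr)[2] != 7L)
    stop("sim must be a (nPlanes, 7, H, W) stack")
  if (length(dim(hrArr)) != 3L || dim(hrArr)[1] != 3L * dim(simArr)[1])
    stop("hr plane count must be exactly 3x the SIM plane count")
  chunkSize <- checkCount(chunkSize, "chunkSize")
  trim <- checkCount(trim, "trim")
  nPl <- dim(simArr)[1]
  usable <- nPl - 2L * trim
  nChunks <- if (usable >= chunkSize) usable %/% chunkSize else 0L
  if (nChunks == 0L) {
    warning("stack shorter than one chunk after trimming; no chunks emitted")
    return(list())
  }
  H <- dim(simArr)[3]; W <- dim(simArr)[4]
  lapply(seq_len(nChunks) - 1L, function(i) {
    a <- trim + i * chunkSize           # 0-based first SIM plane
    inp <- array(0, c(7L * chunkSize, H, W))
    for (q in seq_len(chunkSize))
      inp[(q - 1L) * 7L + 1:7, , ] <- simArr[a + q, , , ]
    tgt <- hrArr[(3L * a + 1L):(3L * (a + chunkSize)), , , drop = FALSE]
    new("ChunkPair", input = inp, target = tgt, stackId = stackId,
      startPlane = a, normInput = c(NA_real_, NA_real_),
      normTarget = c(NA_real_, NA_real_))
  })
}

#' Discard low-signal chunks
#'
#' Removes chunks whose signal content falls below the configured
#' thresholds, preserving order: a chunk is dropped when its mean input
#' pixel value is below \code{chunkThreshold}, or when every one of its
#' per-plane 7-frame image groups has a mean below \code{pairThreshold}.
#'
#' @param pairs list of [ChunkPair-class].
#' @param pairThreshold mean-pixel threshold applied per plane pair
#'   (default 5e-7).
#' @param chunkThreshold mean-pixel threshold applied to the whole chunk
#'   (default 1e-7).
#' @return the filtered list
#' @export
filterLowSignal <- function(pairs, pairThreshold = 5e-7,
                            chunkThreshold = 1e-7) {
  if (pairThreshold < 0 || chunkThreshold < 0)
    stop("thresholds must be non-negative")
  keep <- vapply(pairs, function(ch) {
    inp <- chunkInput(ch)
    if (mean(inp) < chunkThreshold) return(FALSE)
    cs <- dim(inp)[1] %/% 7L
    planeMeans <- vapply(seq_len(cs), function(q)
      mean(inp[(q - 1L) * 7L + 1:7, , ]), numeric(1))
    if (pairThreshold > 0 && all(planeMeans < pairThreshold)) return(FALSE)
    TRUE
  }, logical(1))
  pairs[keep]
}

#' Min-max normalize chunks to [0, 1]
#'
#' Scales the input and target of each chunk independently to the range
#' [0, 1] (per-chunk min-max, so inference needs no dataset-level
#' statistics). The scale factors \code{(min, range)} are stored on the
#' chunk for de-normalization. A constant (zero-range) chunk maps to all
#' zeros with a warning.
#'
#' @param pairs list of [ChunkPair-class].
#' @return list of normalized [ChunkPair-class]
#' @export
normalizeChunks <- function(pairs) {
  if (!length(pairs)) stop("no chunks to normalize")
  lapply(pairs, function(ch) {
    scale01 <- function(x, what) {
      mn <- min(x); rg <- max(x) - mn
      if (rg == 0) {
        warning(sprintf("constant %s chunk mapped to all-zero", what))
        list(x = array(0, dim(x)), f = c(mn, 0))
      } else {
        list(x = (x - mn) / rg, f = c(mn, rg))
      }
    }
    i <- scale01(chunkInput(ch), "input")
    t <- scale01(chunkTarget(ch), "target")
    initialize(ch, input = i$x, target = t$x,
      normInput = i$f, normTarget = t$f)
  })
}

#' Undo chunk normalization
#'
#' @param pair a normalized [ChunkPair-class].
#' @return the chunk with original input/target scales restored
#' @export
denormalizeChunk <- function(pair) {
  stopifnot(is(pair, "ChunkPair"))
  if (anyNA(pair@normInput)) stop("chunk carries no normalization factors")
  initialize(pair,
    input = chunkInput(pair) * pair@normInput[2] + pair@normInput[1],
    target = chunkTarget(pair) * pair@normTarget[2] + pair@normTarget[1],
    normInput = c(NA_real_, NA_real_), normTarget = c(NA_real_, NA_real_))
}

#' Reserve test stacks and record the split
#'
#' Reproducibly reserves \code{nTestChromatin} chromatin and
#' \code{nTestSphere} sphere stacks for testing (selected before any
#' training); the remainder forms the train/validation pool, from which a
#' \code{valFraction} of chunks is carved out downstream.
#'
#' @param stackIds character vector of stack identifiers.
#' @param classes character vector (same length) of specimen classes,
#'   \code{"chromatin"} or \code{"sphere"}.
#' @param nTestChromatin,nTestSphere stacks reserved per class
#'   (defaults 10 and 20).
#' @param valFraction validation fraction of chunks (default 0.1).
#' @param seed integer seed.
#' @return a [SplitManifest-class]
#' @export
makeSplit <- function(stackIds, classes, nTestChromatin = 10L,
                      nTestSphere = 20L, valFraction = 0.1, seed = 1L) {
  if (length(stackIds) != length(classes))
    stop("stackIds and classes must have equal length")
  if (anyDuplicated(stackIds)) stop("stackIds must be unique")
  nTestChromatin <- checkCount(nTestChromatin, "nTestChromatin")
  nTestSphere <- checkCount(nTestSphere, "nTestSphere")
  chrom <- stackIds[classes == "chromatin"]
  sph <- stackIds[classes == "sphere"]
  if (length(chrom) < nTestChromatin || length(sph) < nTestSphere)
    stop("not enough stacks of each class to reserve the test set")
  test <- withSeed(seed, c(
    if (nTestChromatin > 0) sample(chrom, nTestChromatin) else character(0),
    if (nTestSphere > 0) sample(sph, nTestSphere) else character(0)))
  names(classes) <- stackIds
  new("SplitManifest", testIds = test,
    trainIds = setdiff(stackIds, test), classes = classes,
    valFraction = valFraction, seed = as.integer(seed))
}
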