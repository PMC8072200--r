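# The modified residual channel attention network: a leading 3D convolution
# over the interleaved (plane, frame) axis of a SIM chunk, residual groups
# of residual channel-attention blocks with short and long skips, 2x
# sub-pixel lateral upsampling and a final convolution to 3 output planes
# per SIM image in the chunk.

#' Construct an RCAN architecture configuration
#'
#' Defaults follow the published lineage: 12 groups of 3 residual
#' channel-attention blocks, 3x3 kernels, chunk size 3 (21 input frames, 9
#' output planes), 64 feature channels with a channel-attention bottleneck
#' of 16, and a fixed 2x lateral upscale. The reduced test-surface model
#' used throughout the package's own tests is 2 groups x 2 blocks with 16
#' features.
#'
#' @param nGroups residual groups (default 12).
#' @param nBlocks residual channel-attention blocks per group (default 3).
#' @param kernel spatial kernel side (default 3).
#' @param chunkSize SIM planes per chunk (default 3).
#' @param featChannels feature width (default 64).
#' @param reduction channel-attention bottleneck ratio (default 16).
#' @param conv3dChannels channels of the leading 3D convolution (default 4).
#' @return an [RCANConfig-class]
#' @export
rcanConfig <- function(nGroups = 12L, nBlocks = 3L, kernel = 3L,
                       chunkSize = 3L, featChannels = 64L, reduction = 16L,
                       conv3dChannels = 4L) {
  new("RCANConfig", nGroups = as.integer(nGroups),
    nBlocks = as.integer(nBlocks), kernel = as.integer(kernel),
    chunkSize = as.integer(chunkSize),
    featChannels = as.integer(featChannels),
    reduction = as.integer(reduction),
    conv3dChannels = as.integer(conv3dChannels), upscale = 2L)
}

initConv <- function(fanIn, nOut, gain = 2) {
  matrix(stats::rnorm(fanIn * nOut, sd = sqrt(gain / fanIn)), fanIn, nOut)
}

#' Build an RCAN model with seeded initialization
#'
#' Creates the full parameter set (He-normal weights, zero biases) for the
#' architecture described by \code{config}. Two builds with the same seed
#' are bit-identical.
#'
#' @param config an [RCANConfig-class]
#' @param seed integer seed for weight initialization.
#' @return an object of class \code{RCANModel} (list of parameter arrays
#'   plus the configuration)
#' @export
buildRcan <- function(config = rcanConfig(), seed = 1L) {
  stopifnot(is(config, "RCANConfig"))
  K <- config@kernel; K2 <- K * K
  Fch <- config@featChannels
  C3 <- config@conv3dChannels
  D <- 7L * config@chunkSize
  Cr <- max(1L, Fch %/% config@reduction)
  params <- withSeed(seed, {
    p <- list(
      W3d = initConv(27L, C3), b3d = numeric(C3),
      W0 = initConv(C3 * D * K2, Fch), b0 = numeric(Fch),
      Wt = initConv(Fch * K2, Fch), bt = numeric(Fch),
      Wu = initConv(Fch * K2, 4L * Fch), bu = numeric(4L * Fch),
      Wf = initConv(Fch * K2, 3L * config@chunkSize),
      bf = numeric(3L * config@chunkSize))
    for (g in seq_len(config@nGroups)) {
      for (b in seq_len(config@nBlocks)) {
        tag <- sprintf("g%db%d", g, b)
        p[[paste0(tag, "W1")]] <- initConv(Fch * K2, Fch)
        p[[paste0(tag, "b1")]] <- numeric(Fch)
        p[[paste0(tag, "W2")]] <- initConv(Fch * K2, Fch)
        p[[paste0(tag, "b2")]] <- numeric(Fch)
        p[[paste0(tag, "Wd1")]] <- initConv(Fch, Cr, gain = 1)
        p[[paste0(tag, "bd1")]] <- numeric(Cr)
        p[[paste0(tag, "Wd2")]] <- initConv(Cr, Fch, gain = 1)
        p[[paste0(tag, "bd2")]] <- numeric(Fch)
      }
      p[[sprintf("g%dWg", g)]] <- initConv(Fch * K2, Fch)
      p[[sprintf("g%dbg", g)]] <- numeric(Fch)
    }
    p
  })
  structure(list(params = params, config = config), class = "RCANModel")
}

#' @export
print.RCANModel <- function(x, ...) {
  cfg <- x$config
  nPar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "RCANModel: %d groups x %d blocks, %d features (reduction %d), chunk %d, %d parameters\n",
    cfg@nGroups, cfg@nBlocks, cfg@featChannels, cfg@reduction,
    cfg@chunkSize, nPar))
  invisible(x)
}

# Full forward pass. `x` is a (7*chunkSize, H, W) array. Returns the output
# (3*chunkSize, 2H, 2W) array and, when keepCache, every intermediate
# needed by rcanBackward.
rcanForward <- function(model, x, keepCache = FALSE) {
  p <- model$params
  cfg <- model$config
  D <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  if (D != 7L * cfg@chunkSize)
    stop(sprintf("input must have %d channels (7 x chunkSize), got %d",
      7L * cfg@chunkSize, D))
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("H and W must be divisible by 4")
  HW <- H * W
  K <- cfg@kernel
  ctx <- makeConvCtx(H, W, K)
  ctx2 <- makeConvCtx(2L * H, 2L * W, K)
  ctx3 <- makeConv3Ctx(D, H, W)
  C3 <- cfg@conv3dChannels
  cache <- if (keepCache) list(ctx = ctx, ctx2 = ctx2, ctx3 = ctx3) else NULL

  vol <- aperm(x, c(1, 2, 3))          # (D, H, W), d fastest in memory
  c3 <- conv3dForward(vol, p$W3d, p$b3d, ctx3)
  M2 <- flatten3dTo2d(c3$Y, D, HW, C3)
  h0 <- conv2dForward(M2, p$W0, p$b0, ctx)
  f <- h0$Y
  if (keepCache) cache$c3 <- c3; if (keepCache) cache$M2 <- M2
  if (keepCache) cache$h0 <- h0
  f0 <- f
  gcaches <- vector("list", cfg@nGroups)
  for (g in seq_len(cfg@nGroups)) {
    r <- f
    bcaches <- vector("list", cfg@nBlocks)
    for (b in seq_len(cfg@nBlocks)) {
      tag <- sprintf("g%db%d", g, b)
      cv1 <- conv2dForward(r, p[[paste0(tag, "W1")]],
        p[[paste0(tag, "b1")]], ctx)
      rl <- reluForward(cv1$Y)
      cv2 <- conv2dForward(rl$Y, p[[paste0(tag, "W2")]],
        p[[paste0(tag, "b2")]], ctx)
      ca <- caForward(cv2$Y, p[[paste0(tag, "Wd1")]],
        p[[paste0(tag, "bd1")]], p[[paste0(tag, "Wd2")]],
        p[[paste0(tag, "bd2")]])
      if (keepCache)
        bcaches[[b]] <- list(rIn = r, cv1 = cv1, rl = rl, cv2 = cv2, ca = ca)
      r <- r + ca$Y
    }
    cvg <- conv2dForward(r, p[[sprintf("g%dWg", g)]],
      p[[sprintf("g%dbg", g)]], ctx)
    if (keepCache)
      gcaches[[g]] <- list(blocks = bcaches, gIn = f, rOut = r, cvg = cvg)
    f <- f + cvg$Y
  }
  cvt <- conv2dForward(f, p$Wt, p$bt, ctx)
  ft <- cvt$Y + f0
  cvu <- conv2dForward(ft, p$Wu, p$bu, ctx)
  up <- pixelShuffleForward(cvu$Y, H, W)
  cvf <- conv2dForward(up, p$Wf, p$bf, ctx2)
  out <- aperm(array(cvf$Y, c(2L * H, 2L * W, 3L * cfg@chunkSize)),
    c(3, 1, 2))
  if (keepCache) {
    cache$groups <- gcaches
    cache$fAfterGroups <- f
    cache$cvt <- cvt; cache$ft <- ft; cache$cvu <- cvu; cache$up <- up
    cache$cvf <- cvf
    cache$dims <- c(D = D, H = H, W = W)
  }
  list(out = out, cache = cache)
}

# Backward pass from dOut (3*chunkSize, 2H, 2W); returns gradients named
# congruently with model$params.
rcanBackward <- function(model, cache, dOut) {
  p <- model$params
  cfg <- model$config
  D <- cache$dims["D"]; H <- cache$dims["H"]; W <- cache$dims["W"]
  HW <- H * W
  C3 <- cfg@conv3dChannels
  grads <- list()
  dYf <- matrix(aperm(dOut, c(2, 3, 1)), 4L * HW, 3L * cfg@chunkSize)
  bf <- conv2dBackward(dYf, cache$cvf, p$Wf, cache$ctx2, cfg@featChannels)
  grads$Wf <- bf$dW; grads$bf <- bf$db
  dcvu <- pixelShuffleBackward(bf$dX, H, W)
  bu <- conv2dBackward(dcvu, cache$cvu, p$Wu, cache$ctx, cfg@featChannels)
  grads$Wu <- bu$dW; grads$bu <- bu$db
  dft <- bu$dX
  bt <- conv2dBackward(dft, cache$cvt, p$Wt, cache$ctx, cfg@featChannels)
  grads$Wt <- bt$dW; grads$bt <- bt$db
  df <- bt$dX          # gradient into f after groups
  df0 <- dft           # long skip into f0
  for (g in rev(seq_len(cfg@nGroups))) {
    gc <- cache$groups[[g]]
    bg <- conv2dBackward(df, gc$cvg, p[[sprintf("g%dWg", g)]],
      cache$ctx, cfg@featChannels)
    grads[[sprintf("g%dWg", g)]] <- bg$dW
    grads[[sprintf("g%dbg", g)]] <- bg$db
    dr <- bg$dX
    for (b in rev(seq_len(cfg@nBlocks))) {
      tag <- sprintf("g%db%d", g, b)
      bc <- gc$blocks[[b]]
      ca <- caBackward(dr, bc$ca, bc$cv2$Y, p[[paste0(tag, "Wd1")]],
        p[[paste0(tag, "Wd2")]])
      grads[[paste0(tag, "Wd1")]] <- ca$dW1
      grads[[paste0(tag, "bd1")]] <- ca$db1
      grads[[paste0(tag, "Wd2")]] <- ca$dW2
      grads[[paste0(tag, "bd2")]] <- ca$db2
      b2 <- conv2dBackward(ca$dX, bc$cv2, p[[paste0(tag, "W2")]],
        cache$ctx, cfg@featChannels)
      grads[[paste0(tag, "W2")]] <- b2$dW
      grads[[paste0(tag, "b2")]] <- b2$db
      drl <- reluBackward(b2$dX, bc$rl)
      b1 <- conv2dBackward(drl, bc$cv1, p[[paste0(tag, "W1")]],
        cache$ctx, cfg@featChannels)
      grads[[paste0(tag, "W1")]] <- b1$dW
      grads[[paste0(tag, "b1")]] <- b1$db
      dr <- dr + b1$dX   # short skip
    }
    df <- df + dr        # group skip feeds the group input
  }
  dfin <- df + df0       # head output receives groups path + long skip
  b0 <- conv2dBackward(dfin, cache$h0, p$W0, cache$ctx, C3 * D)
  grads$W0 <- b0$dW; grads$b0 <- b0$db
  dY3 <- unflatten2dTo3d(b0$dX, D, HW, C3)
  b3 <- conv3dBackward(dY3, cache$c3, p$W3d, cache$ctx3)
  grads$W3d <- b3$dW; grads$b3d <- b3$db
  grads
}

# Mean-squared-error loss and parameter gradients for one chunk.
rcanLossGrad <- function(model, x, target) {
  fw <- rcanForward(model, x, keepCache = TRUE)
  diff <- fw$out - target
  loss <- mean(diff^2)
  grads <- rcanBackward(model, fw$cache, 2 * diff / length(diff))
  list(loss = loss, grads = grads)
}

#' Predict the forward pass of an RCAN on one chunk
#'
#' @param model an \code{RCANModel} from [buildRcan()] or [trainRcan()].
#' @param x a \code{(7*chunkSize, H, W)} input array (H, W divisible by 4).
#' @return the \code{(3*chunkSize, 2H, 2W)} network output
#' @export
predictRcan <- function(model, x) {
  stopifnot(inherits(model, "RCANModel"))
  rcanForward(model, x)$out
}

#' Network inference on a full SIM stack
#'
#' Chunks the stack into consecutive groups of \code{chunkSize} planes
#' (edge-replicating the last plane when the count does not divide), min-max
#' normalizes each chunk's input to [0, 1], runs the network per chunk,
#' concatenates chunk outputs so that chunk channel k maps to global plane
#' \code{3*start + k}, and truncates negative values to zero.
#'
#' @param model an \code{RCANModel}.
#' @param stack a [SIMStack-class] (lateral size divisible by 4).
#' @return a [VolumeStack-class] of shape \code{(3*nPlanes, 2H, 2W)},
#'   non-negative
#' @export
inferRcan <- function(model, stack) {
  stopifnot(inherits(model, "RCANModel"), is(stack, "SIMStack"))
  cfg <- model$config
  arr <- stackData(stack)
  nPl <- dim(arr)[1]; H <- dim(arr)[3]; W <- dim(arr)[4]
  cs <- cfg@chunkSize
  nCh <- ceiling(nPl / cs)
  out <- array(0, c(3L * nPl, 2L * H, 2L * W))
  for (i in seq_len(nCh) - 1L) {
    planes <- pmin(i * cs + seq_len(cs), nPl)  # edge replication at the end
    x <- array(0, c(7L * cs, H, W))
    for (q in seq_len(cs))
      x[(q - 1L) * 7L + 1:7, , ] <- arr[planes[q], , , ]
    mn <- min(x); rg <- max(x) - mn
    if (rg > 0) x <- (x - mn) / rg
    y <- rcanForward(model, x)$out
    keepPlanes <- which(i * cs + seq_len(cs) <= nPl)
    for (q in keepPlanes) {
      gp <- 3L * (i * cs + q - 1L)
      out[gp + 1:3, , ] <- y[(q - 1L) * 3L + 1:3, , ]
    }
  }
  out[out < 0] <- 0
  new("VolumeStack", data = out,
    spacing = c(stack@config@dz / 3, samplePixel(stack@config) / 2,
      samplePixel(stack@config) / 2))
}

#' Input-frame masking ablation
#'
#' Zeroes one of the 7 SIM frames across all planes, re-runs inference and
#' reports the degradation: MSE and SSIM of the masked output against the
#' unmasked output, and (when a reference is supplied) of both outputs
#' against the high-resolution reference. Removing any single frame
#' deteriorates the reconstruction relative to the unmasked network.
#'
#' @param model an \code{RCANModel}.
#' @param stack a [SIMStack-class].
#' @param frameIndex frame to mask, 0..6.
#' @param reference optional [VolumeStack-class] ground truth.
#' @return list with \code{output} (masked [VolumeStack-class]),
#'   \code{vsUnmasked} and optionally \code{vsReference} metric rows
#' @export
ablateInputChannel <- function(model, stack, frameIndex, reference = NULL) {
  stopifnot(is(stack, "SIMStack"))
  if (length(frameIndex) != 1L || frameIndex < 0 || frameIndex > 6 ||
      frameIndex %% 1 != 0)
    stop("frameIndex must be a single integer in 0..6")
  full <- inferRcan(model, stack)
  arr <- stackData(stack)
  arr[, frameIndex + 1L, , ] <- 0
  masked <- inferRcan(model,
    new("SIMStack", data = arr, config = stack@config, units = stack@units))
  res <- list(output = masked,
    vsUnmasked = c(mse = imageMse(masked, full),
      ssim = imageSsim(stackData(masked), stackData(full))))
  if (!is.null(reference)) {
    res$vsReference <- rbind(
      unmasked = c(mse = imageMse(full, reference),
        ssim = imageSsim(stackData(full), stackData(reference))),
      masked = c(mse = imageMse(masked, reference),
        ssim = imageSsim(stackData(masked), stackData(reference))))
  }
  res
}
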