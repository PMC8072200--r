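# Training loop: Adam over per-chunk MSE, componentwise gradient clipping at
# +/-0.1, learning-rate schedule combining a plateau reduction with a 1%
# decay every 5 epochs, and best-validation checkpointing.

#' Train an RCAN on chunk pairs
#'
#' Minimizes the mean squared error between network output and
#' high-resolution target over the training chunks, one Adam step per chunk
#' per epoch. The learning rate starts at \code{lr} (default 1e-6, the
#' published schedule; toy problems typically need a larger value), is
#' multiplied by \code{plateauFactor} when the validation loss has not
#' improved for \code{plateauPatience} epochs, and is additionally decreased
#' by 1% every 5 epochs for late fine-tuning. Every gradient component is
#' clipped to \code{[-clip, clip]} before the update. The best-validation
#' parameter set is checkpointed and returned. Fully seeded (shuffling is
#' the only stochastic element).
#'
#' @param model an \code{RCANModel} from [buildRcan()].
#' @param trainPairs,valPairs lists of normalized [ChunkPair-class].
#' @param epochs training epochs.
#' @param lr starting learning rate (default 1e-6).
#' @param plateauFactor,plateauPatience plateau policy: multiply the rate by
#'   \code{plateauFactor} (default 0.5) after \code{plateauPatience}
#'   (default 10) epochs without validation improvement.
#' @param decayEvery,decayFactor periodic decay (defaults: x0.99 every 5
#'   epochs).
#' @param clip componentwise gradient clip bound (default 0.1).
#' @param seed integer seed for shuffling.
#' @return a list: \code{model} (best-validation checkpoint), \code{state}
#'   (per-epoch \code{trainLoss}, \code{valLoss}, \code{lrTrace}, the best
#'   validation loss, and \code{maxClippedGrad}, the largest absolute
#'   gradient component observed after clipping)
#' @export
trainRcan <- function(model, trainPairs, valPairs = list(), epochs = 50L,
                      lr = 1e-6, plateauFactor = 0.5, plateauPatience = 10L,
                      decayEvery = 5L, decayFactor = 0.99, clip = 0.1,
                      seed = 1L) {
  stopifnot(inherits(model, "RCANModel"))
  if (!length(trainPairs)) stop("trainPairs must be non-empty")
  params <- model$params
  mAdam <- lapply(params, function(p) p * 0)
  vAdam <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
  step <- 0L
  trainLoss <- valLoss <- lrTrace <- numeric(epochs)
  bestVal <- Inf
  bestParams <- params
  sinceImprove <- 0L
  maxClipped <- 0
  evalSet <- function(pairs) {
    if (!length(pairs)) return(NA_real_)
    mean(vapply(pairs, function(ch) {
      out <- rcanForward(list(params = params, config = model$config),
        chunkInput(ch))$out
      mean((out - chunkTarget(ch))^2)
    }, numeric(1)))
  }
  orders <- withSeed(seed, lapply(seq_len(epochs), function(e)
    sample(length(trainPairs))))
  for (e in seq_len(epochs)) {
    if (e %% decayEvery == 0L) lr <- lr * decayFactor
    lrTrace[e] <- lr
    losses <- numeric(length(trainPairs))
    for (i in seq_along(orders[[e]])) {
      ch <- trainPairs[[orders[[e]][i]]]
      lg <- rcanLossGrad(list(params = params, config = model$config),
        chunkInput(ch), chunkTarget(ch))
      if (!is.finite(lg$loss))
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d, step %d", e, i))
      losses[i] <- lg$loss
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in names(params)) {
        g <- pmin(pmax(lg$grads[[nm]], -clip), clip)
        mx <- max(abs(g))
        if (mx > maxClipped) maxClipped <- mx
        mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g
        vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g * g
        params[[nm]] <- params[[nm]] -
          lr * (mAdam[[nm]] / bc1) / (sqrt(vAdam[[nm]] / bc2) + epsAdam)
      }
    }
    trainLoss[e] <- mean(losses)
    valLoss[e] <- evalSet(valPairs)
    monitor <- if (is.na(valLoss[e])) trainLoss[e] else valLoss[e]
    if (monitor < bestVal - 1e-12) {
      bestVal <- monitor
      bestParams <- params
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove >= plateauPatience) {
        lr <- lr * plateauFactor
        sinceImprove <- 0L
      }
    }
  }
  list(
    model = structure(list(params = bestParams, config = model$config),
      class = "RCANModel"),
    finalModel = structure(list(params = params, config = model$config),
      class = "RCANModel"),
    state = list(trainLoss = trainLoss, valLoss = valLoss,
      lrTrace = lrTrace, bestValLoss = bestVal,
      maxClippedGrad = maxClipped, clip = clip, epochs = epochs))
}
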