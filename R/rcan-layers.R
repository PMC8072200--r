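# Neural-network primitives for the modified residual channel attention
# network: 2D/3D convolutions via im2col and BLAS matrix products, channel
# attention, 2x sub-pixel (pixel-shuffle) upsampling, with hand-written
# backward passes. Feature maps are (H*W, C) matrices, column-major over the
# (y, x) plane; volumes for the input 3D convolution are (D, H, W) arrays.
# Gradient correctness is established by finite-difference checks in the
# test suite.

# Precomputed geometry for a KxK 'same' zero-padded convolution on an HxW
# grid: linear indices into the padded plane for every kernel offset.
makeConvCtx <- function(H, W, K) {
  half <- (K - 1L) %/% 2L
  padH <- H + 2L * half; padW <- W + 2L * half
  y <- rep(seq_len(H), W); x <- rep(seq_len(W), each = H)
  IDX <- matrix(0L, H * W, K * K)
  o <- 0L
  for (ox in 0:(K - 1L)) for (oy in 0:(K - 1L)) {
    o <- o + 1L
    IDX[, o] <- (y + oy) + (x + ox - 1L) * padH
  }
  interior <- (y + half) + (x + half - 1L) * padH
  list(H = H, W = W, K = K, half = half, padHW = padH * padW,
    IDX = IDX, interior = interior)
}

im2col <- function(X, ctx) {
  Cin <- ncol(X)
  K2 <- ctx$K^2
  Xpad <- matrix(0, ctx$padHW, Cin)
  Xpad[ctx$interior, ] <- X
  P <- matrix(0, nrow(X), K2 * Cin)
  for (o in seq_len(K2))
    P[, (o - 1L) * Cin + seq_len(Cin)] <- Xpad[ctx$IDX[, o], , drop = FALSE]
  P
}

col2im <- function(dP, ctx, Cin) {
  K2 <- ctx$K^2
  dXpad <- matrix(0, ctx$padHW, Cin)
  for (o in seq_len(K2)) {
    idx <- ctx$IDX[, o]
    dXpad[idx, ] <- dXpad[idx, , drop = FALSE] +
      dP[, (o - 1L) * Cin + seq_len(Cin), drop = FALSE]
  }
  dXpad[ctx$interior, , drop = FALSE]
}

conv2dForward <- function(X, Wm, b, ctx) {
  P <- im2col(X, ctx)
  Y <- P %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, P = P)
}

conv2dBackward <- function(dY, cache, Wm, ctx, Cin) {
  list(dW = crossprod(cache$P, dY), db = colSums(dY),
    dX = col2im(dY %*% t(Wm), ctx, Cin))
}

# 3x3x3 'same' convolution over a single-channel (D, H, W) volume.
makeConv3Ctx <- function(D, H, W) {
  padD <- D + 2L; padH <- H + 2L; padW <- W + 2L
  d <- rep(seq_len(D), H * W)
  y <- rep(rep(seq_len(H), each = D), W)
  x <- rep(seq_len(W), each = D * H)
  IDX <- matrix(0L, D * H * W, 27L)
  o <- 0L
  for (ox in 0:2) for (oy in 0:2) for (od in 0:2) {
    o <- o + 1L
    IDX[, o] <- (d + od) + (y + oy - 1L) * padD +
      (x + ox - 1L) * padD * padH
  }
  interior <- (d + 1L) + y * padD + x * padD * padH
  list(D = D, H = H, W = W, padN = padD * padH * padW,
    IDX = IDX, interior = interior)
}

conv3dForward <- function(vol, Wm, b, ctx) {
  v <- as.vector(vol)
  vpad <- numeric(ctx$padN)
  vpad[ctx$interior] <- v
  P <- matrix(0, length(v), 27L)
  for (o in 1:27) P[, o] <- vpad[ctx$IDX[, o]]
  Y <- P %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, P = P)   # Y: (D*H*W, C3), rows ordered d fastest, then y, x
}

conv3dBackward <- function(dY, cache, Wm, ctx) {
  dP <- dY %*% t(Wm)
  dvpad <- numeric(ctx$padN)
  for (o in 1:27) {
    idx <- ctx$IDX[, o]
    dvpad[idx] <- dvpad[idx] + dP[, o]
  }
  list(dW = crossprod(cache$P, dY), db = colSums(dY),
    dVol = array(dvpad[ctx$interior], c(ctx$D, ctx$H, ctx$W)))
}

# Interleave the 3D-conv output (D*H*W, C3) into 2D feature maps (H*W, D*C3)
# (columns ordered depth fastest within each 3D-conv channel).
flatten3dTo2d <- function(Y, D, HW, C3) {
  matrix(aperm(array(Y, c(D, HW, C3)), c(2, 1, 3)), HW, D * C3)
}

unflatten2dTo3d <- function(dM, D, HW, C3) {
  matrix(aperm(array(dM, c(HW, D, C3)), c(2, 1, 3)), D * HW, C3)
}

reluForward <- function(X) list(Y = pmax(X, 0), mask = X > 0)
reluBackward <- function(dY, cache) dY * cache$mask

# Squeeze-and-excitation channel attention: global average pooling, a
# bottleneck dense pair (relu, sigmoid) and per-channel rescaling.
caForward <- function(X, W1, b1, W2, b2) {
  s <- colMeans(X)
  h <- as.vector(s %*% W1) + b1
  hr <- pmax(h, 0)
  z <- 1 / (1 + exp(-(as.vector(hr %*% W2) + b2)))
  list(Y = X * rep(z, each = nrow(X)), s = s, h = h, hr = hr, z = z)
}

caBackward <- function(dY, cache, X, W1, W2) {
  n <- nrow(X)
  z <- cache$z
  dXdirect <- dY * rep(z, each = n)
  dz <- colSums(dY * X)
  dpre2 <- dz * z * (1 - z)
  dhr <- as.vector(dpre2 %*% t(W2))
  dh <- dhr * (cache$h > 0)
  ds <- as.vector(dh %*% t(W1))
  dX <- dXdirect + matrix(ds / n, n, length(ds), byrow = TRUE)
  list(dX = dX,
    dW1 = outer(cache$s, dh), db1 = dh,
    dW2 = outer(cache$hr, dpre2), db2 = dpre2)
}

# 2x sub-pixel upsampling: (H*W, 4C) -> (2H*2W, C). Input channel
# 4*(c-1) + (dy*2 + dx + 1) feeds output pixel (2y+dy, 2x+dx) of channel c.
pixelShuffleForward <- function(X, H, W) {
  C <- ncol(X) %/% 4L
  H2 <- 2L * H
  y <- rep(seq_len(H), W) - 1L; x <- rep(seq_len(W), each = H) - 1L
  Y <- matrix(0, 4L * H * W, C)
  for (c in seq_len(C)) for (dy in 0:1) for (dx in 0:1) {
    oidx <- (2L * y + dy + 1L) + (2L * x + dx) * H2
    Y[oidx, c] <- X[, 4L * (c - 1L) + dy * 2L + dx + 1L]
  }
  Y
}

pixelShuffleBackward <- function(dY, H, W) {
  C <- ncol(dY)
  H2 <- 2L * H
  y <- rep(seq_len(H), W) - 1L; x <- rep(seq_len(W), each = H) - 1L
  dX <- matrix(0, H * W, 4L * C)
  for (c in seq_len(C)) for (dy in 0:1) for (dx in 0:1) {
    oidx <- (2L * y + dy + 1L) + (2L * x + dx) * H2
    dX[, 4L * (c - 1L) + dy * 2L + dx + 1L] <- dY[oidx, c]
  }
  dX
}
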