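# Low-level 1-D network layers operating on [N, L, C] arrays, each with an
# explicit forward returning a cache and a matching backward. Convolutions
# are evaluated as im2col matrix products so the heavy lifting is BLAS;
# padding is folded into the gather indices rather than materialized.

conv_out_len <- function(L, k, stride, pad) {
  (L + 2L * pad - k) %/% stride + 1L
}

# Gather matrix (N*Lout, k*Cin) without materializing a padded copy of X.
im2col <- function(X, k, stride, pad, Lout) {
  d <- dim(X)
  cin <- d[3]
  cols <- array(0, c(d[1], Lout, k * cin))
  for (t in seq_len(k)) {
    src <- t - pad + stride * (0:(Lout - 1L))
    ok <- src >= 1L & src <= d[2]
    cols[, which(ok), ((t - 1L) * cin + 1L):(t * cin)] <-
      X[, src[ok], , drop = FALSE]
  }
  dim(cols) <- c(d[1] * Lout, k * cin)
  cols
}

# W: (k*cin) x cout matrix; biasless (convs are always followed by BN here).
conv1d_fwd <- function(X, W, k, stride, pad) {
  d <- dim(X)
  Lout <- conv_out_len(d[2], k, stride, pad)
  cols <- im2col(X, k, stride, pad, Lout)
  Y <- cols %*% W
  dim(Y) <- c(d[1], Lout, ncol(W))
  list(out = Y, cache = list(cols = cols, W = W, k = k, stride = stride,
                             pad = pad, dimX = d, Lout = Lout))
}

conv1d_bwd <- function(dY, cache) {
  d <- cache$dimX
  cout <- ncol(cache$W)
  dYm <- dY
  dim(dYm) <- c(d[1] * cache$Lout, cout)
  dW <- crossprod(cache$cols, dYm)
  dcols <- dYm %*% t(cache$W)
  dim(dcols) <- c(d[1], cache$Lout, cache$k * d[3])
  dX <- array(0, d)
  for (t in seq_len(cache$k)) {
    src <- t - cache$pad + cache$stride * (0:(cache$Lout - 1L))
    ok <- src >= 1L & src <= d[2]
    blk <- ((t - 1L) * d[3] + 1L):(t * d[3])
    dX[, src[ok], ] <- dX[, src[ok], , drop = FALSE] +
      dcols[, which(ok), blk, drop = FALSE]
  }
  list(dX = dX, dW = dW)
}

# Per-channel affine transform of an (m x C) matrix, vectorized via column
# recycling: cheaper than sweep() at these sizes.
scale_cols <- function(Xm, s, b = NULL) {
  m <- nrow(Xm)
  Y <- Xm * rep(s, each = m)
  if (!is.null(b)) Y <- Y + rep(b, each = m)
  Y
}

bn_fwd <- function(X, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  m <- d[1] * d[2]
  Xm <- X
  dim(Xm) <- c(m, d[3])
  if (training) {
    mu <- colMeans(Xm)
    va <- pmax(colMeans(Xm * Xm) - mu^2, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- rmean
    va <- rvar
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- scale_cols(Xm, invstd, -mu * invstd)
  Y <- scale_cols(xhat, gamma, beta)
  dim(Y) <- d
  list(out = Y, rmean = rmean, rvar = rvar,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    training = training))
}

bn_bwd <- function(dY, cache) {
  d <- cache$d
  m <- d[1] * d[2]
  dYm <- dY
  dim(dYm) <- c(m, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$training) {
    # dX = invstd/m * (m*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
    s <- cache$gamma * cache$invstd
    dXm <- scale_cols(dYm, s, -(dbeta * cache$gamma) * cache$invstd / m) -
      scale_cols(cache$xhat, (dgamma * cache$gamma) * cache$invstd / m)
    dim(dXm) <- d
  } else {
    dXm <- scale_cols(dYm, cache$gamma * cache$invstd)
    dim(dXm) <- d
  }
  list(dX = dXm, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  list(out = pmax(X, 0), cache = X > 0)
}

# guided = TRUE additionally zeroes negative incoming gradients
# (guided backpropagation).
relu_bwd <- function(dY, mask, guided = FALSE) {
  g <- dY * mask
  if (guided) g <- g * (dY > 0)
  g
}

maxpool_fwd <- function(X, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(X)
  Lout <- conv_out_len(d[2], k, stride, pad)
  best <- array(-Inf, c(d[1], Lout, d[3]))
  arg <- array(0L, c(d[1], Lout, d[3]))
  for (t in seq_len(k)) {
    src <- t - pad + stride * (0:(Lout - 1L))
    ok <- src >= 1L & src <= d[2]
    slice <- array(-Inf, c(d[1], Lout, d[3]))
    slice[, which(ok), ] <- X[, src[ok], , drop = FALSE]
    upd <- slice > best
    best[upd] <- slice[upd]
    arg[upd] <- t
  }
  list(out = best, cache = list(arg = arg, k = k, stride = stride,
                                pad = pad, dimX = d, Lout = Lout))
}

maxpool_bwd <- function(dY, cache) {
  d <- cache$dimX
  dX <- array(0, d)
  for (t in seq_len(cache$k)) {
    src <- t - cache$pad + cache$stride * (0:(cache$Lout - 1L))
    ok <- src >= 1L & src <= d[2]
    contrib <- dY * (cache$arg == t)
    dX[, src[ok], ] <- dX[, src[ok], , drop = FALSE] +
      contrib[, which(ok), , drop = FALSE]
  }
  dX
}

gap_fwd <- function(X) {
  d <- dim(X)
  out <- matrix(0, d[1], d[3])
  for (l in seq_len(d[2])) out <- out + X[, l, ]
  list(out = out / d[2], cache = d)
}

gap_bwd <- function(dY, d) {
  dX <- array(0, d)
  for (l in seq_len(d[2])) dX[, l, ] <- dY / d[2]
  dX
}
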