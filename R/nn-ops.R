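# Primitive differentiable layers used by the U-Net.
#
# Activations are stored as (B*H*W) x C matrices with row r = b*H*W + j*H + i
# (0-based, image-row index i fastest), one column per channel.  Convolutions
# are im2col gathers (C++ kernels) followed by BLAS matrix products; all
# backward passes are hand-derived and verified by numerical gradient checks
# in the test suite.

conv3_fwd <- function(X, W, b, H, Wd, B) {
  col <- im2col3(X, H, Wd, B)
  Y <- col %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, X = X)
}

conv3_bwd <- function(dY, cache, W, H, Wd, B) {
  col <- im2col3(cache$X, H, Wd, B)
  dW <- crossprod(col, dY)
  db <- colSums(dY)
  dX <- col2im3(tcrossprod(dY, W), H, Wd, B)
  list(dX = dX, dW = dW, db = db)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

relu_bwd <- function(dY, cache) dY * cache$mask

# Batch normalization over the batch-and-spatial dimension (rows), one
# statistic per channel (column).  Biased variance is used both for the
# normalization and for the running estimates.
bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v[v < 0] <- 0
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (X - rep(mu, each = n)) * rep(inv_sd, each = n)
  Y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(Y = Y, xhat = xhat, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dY, cache, gamma) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  scale <- rep(gamma * cache$inv_sd, each = n)
  dX <- scale * (dY - rep(dbeta / n, each = n) -
                   xhat * rep(dgamma / n, each = n))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Index vectors mapping each output pixel of a 2x2 max-pool (or the four
# quadrant offsets of a 2x2 stride-2 transposed convolution) to input rows.
# q enumerates the (di, dj) in {0,1}^2 corner of each 2x2 block.
pool_indices <- function(H, W, B) {
  h <- H %/% 2L
  w <- W %/% 2L
  io <- rep(seq_len(h), times = w)
  jo <- rep(seq_len(w), each = h)
  base_b <- rep((seq_len(B) - 1L) * H * W, each = h * w)
  idx <- vector("list", 4L)
  q <- 1L
  for (dj in 0:1) {
    for (di in 0:1) {
      ii <- 2L * (io - 1L) + di + 1L
      jj <- 2L * (jo - 1L) + dj + 1L
      idx[[q]] <- rep(ii + (jj - 1L) * H, times = B) + base_b
      q <- q + 1L
    }
  }
  idx
}

pool_fwd <- function(X, idx) {
  M <- lapply(idx, function(k) X[k, , drop = FALSE])
  Y <- pmax(M[[1]], M[[2]], M[[3]], M[[4]])
  # first-match tie-breaking so each output credits exactly one input
  m1 <- M[[1]] == Y
  m2 <- (M[[2]] == Y) & !m1
  m3 <- (M[[3]] == Y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(Y = Y, masks = list(m1, m2, m3, m4), n_in = nrow(X))
}

pool_bwd <- function(dY, cache, idx, C) {
  dX <- matrix(0, cache$n_in, C)
  for (q in 1:4) dX[idx[[q]], ] <- dY * cache$masks[[q]]
  dX
}

# 2x2 stride-2 transposed convolution.  W has shape C_in x (4*C_out): block q
# holds the weights feeding quadrant q of each output 2x2 block.
up_fwd <- function(X, W, b, idx_out, C_out) {
  Y4 <- X %*% W
  n_out <- 4L * nrow(X)
  Y <- matrix(0, n_out, C_out)
  for (q in 1:4) {
    Y[idx_out[[q]], ] <- Y4[, ((q - 1L) * C_out + 1L):(q * C_out), drop = FALSE]
  }
  Y <- Y + rep(b, each = n_out)
  list(Y = Y, X = X)
}

up_bwd <- function(dY, cache, W, idx_out, C_out) {
  dY4 <- matrix(0, nrow(cache$X), 4L * C_out)
  for (q in 1:4) {
    dY4[, ((q - 1L) * C_out + 1L):(q * C_out)] <- dY[idx_out[[q]], , drop = FALSE]
  }
  list(dX = tcrossprod(dY4, W),
       dW = crossprod(cache$X, dY4),
       db = colSums(dY))
}

# Flatten (B*HW) x C activations to B x (HW*C) feature rows (feature index
# f = p + (c-1)*HW) and back.
flatten_fwd <- function(X, HW, B) {
  C <- ncol(X)
  A <- array(X, dim = c(HW, B, C))
  matrix(aperm(A, c(2L, 1L, 3L)), nrow = B, ncol = HW * C)
}

flatten_bwd <- function(dF, HW, B) {
  C <- ncol(dF) %/% HW
  A <- array(dF, dim = c(B, HW, C))
  matrix(aperm(A, c(2L, 1L, 3L)), nrow = B * HW, ncol = C)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Binary cross-entropy between probabilities and binary targets
#'
#' Mean of \code{-[y log p + (1 - y) log(1 - p)]} over all elements, with
#' probabilities clamped to \code{[eps, 1 - eps]} to avoid \code{log(0)}.
#'
#' @param p numeric vector/matrix of probabilities in \[0, 1\].
#' @param y numeric vector/matrix of binary targets, same shape as \code{p}.
#' @param eps clamping constant (default \code{1e-7}).
#' @return scalar loss.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
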