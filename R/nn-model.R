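# U-Net with a dense head: maps a padded 2x32x32 scattering-matrix tensor to
# a 108x108 pixel-wise tumor probability map.
#
# Topology for depth = 3 (the default): three resolution levels (32, 16, 8)
# with channel widths base, 2*base, 4*base; each level is a block of
# convs_per_block [3x3 conv -> ReLU -> batch-norm] stages; 2x2 max-pooling
# between encoder levels; 2x2 stride-2 transposed convolutions and skip
# concatenations on the way up; the full-resolution decoder output is
# flattened and passed through one dense layer with a sigmoid to out_pixels^2
# probabilities.

.geom_cache <- new.env(parent = emptyenv())

pool_idx_cached <- function(H, W, B) {
  key <- paste(H, W, B, sep = "_")
  if (is.null(.geom_cache[[key]])) {
    .geom_cache[[key]] <- pool_indices(H, W, B)
  }
  .geom_cache[[key]]
}

#' Network architecture configuration
#'
#' Defaults reproduce the reference architecture: a three-level U-Net whose
#' blocks use three 3x3 padded convolutions, each followed by a ReLU and a
#' batch normalization, with a single dense layer mapping the flattened
#' decoder output to a 108x108 probability map through a sigmoid.
#'
#' @param depth number of resolution levels (default 3).
#' @param convs_per_block convolutions per block (default 3).
#' @param base_channels channel width at full resolution; doubles per level.
#' @param input_size spatial size of the (padded) input tensor, default 32.
#' @param in_channels input channels (real and imaginary parts), default 2.
#' @param out_pixels output map side length, default 108 (so the dense layer
#'   has 11664 output units).
#' @param dense_bias_prior prior probability used to initialize the dense
#'   bias at its logit; tumor pixels are rare, so a small value (default
#'   0.02) starts training from near-empty maps.
#' @param channels optional integer vector of per-level channel widths
#'   (length \code{depth}), overriding the doubling rule.  Widening only the
#'   coarse levels buys representational capacity where the spatial grid is
#'   small while keeping the dense head (whose input is
#'   \code{input_size^2 * channels[1]}) and the full-resolution convolutions
#'   cheap.
#' @return a \code{model_config} list.
#' @export
model_config <- function(depth = 3L, convs_per_block = 3L, base_channels = 32L,
                         input_size = 32L, in_channels = 2L, out_pixels = 108L,
                         dense_bias_prior = 0.02, channels = NULL) {
  if (input_size %% 2L^(depth - 1L) != 0L) {
    stop("input_size must be divisible by 2^(depth - 1) for ", depth,
         " resolution levels")
  }
  if (is.null(channels)) {
    channels <- base_channels * 2L^(seq_len(depth) - 1L)
  }
  stopifnot(length(channels) == depth, all(channels >= 1))
  structure(list(depth = as.integer(depth),
                 convs_per_block = as.integer(convs_per_block),
                 base_channels = as.integer(base_channels),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 out_pixels = as.integer(out_pixels),
                 dense_bias_prior = dense_bias_prior,
                 channels = as.integer(channels)),
            class = "model_config")
}

level_channels <- function(config, l) config$channels[l]

#' Build an untrained network
#'
#' Allocates and initializes all parameters (He initialization for
#' convolutional and transposed-convolutional weights, Xavier-scaled for the
#' dense layer, unit gamma / zero beta for batch-norm) plus the batch-norm
#' running statistics.
#'
#' @param config a [model_config()].
#' @param seed integer seed controlling weight initialization.
#' @return a \code{tumor_net} object: list with \code{config}, flat parameter
#'   list \code{theta}, batch-norm state \code{bn_state}, and \code{n_params}.
#' @export
build_model <- function(config = model_config(), seed = 0L) {
  with_seed(seed, {
    th <- list()
    bn <- list()
    he <- function(nin, nout, fan) {
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / fan)), nin, nout)
    }
    add_block <- function(prefix, l, C_in, C_out, K) {
      for (k in seq_len(K)) {
        cin <- if (k == 1L) C_in else C_out
        th[[sprintf("%s%dc%d_W", prefix, l, k)]] <<- he(9L * cin, C_out, 9L * cin)
        th[[sprintf("%s%dc%d_b", prefix, l, k)]] <<- numeric(C_out)
        th[[sprintf("%s%db%d_g", prefix, l, k)]] <<- rep(1, C_out)
        th[[sprintf("%s%db%d_be", prefix, l, k)]] <<- numeric(C_out)
        bn[[sprintf("%s%db%d", prefix, l, k)]] <<-
          list(mean = numeric(C_out), var = rep(1, C_out))
      }
    }
    depth <- config$depth
    K <- config$convs_per_block
    for (l in seq_len(depth)) {
      C_in <- if (l == 1L) config$in_channels else level_channels(config, l - 1L)
      add_block("e", l, C_in, level_channels(config, l), K)
    }
    for (l in seq_len(depth - 1L)) {
      C_lo <- level_channels(config, l)
      th[[sprintf("u%d_W", l)]] <- he(level_channels(config, l + 1L), 4L * C_lo,
                                      level_channels(config, l + 1L))
      th[[sprintf("u%d_b", l)]] <- numeric(C_lo)
      add_block("d", l, 2L * C_lo, C_lo, K)
    }
    n_feat <- config$input_size^2 * config$channels[1L]
    n_out <- config$out_pixels^2
    th$fc_W <- matrix(stats::rnorm(n_feat * n_out, sd = sqrt(1 / n_feat)),
                      n_feat, n_out)
    th$fc_b <- rep(stats::qlogis(config$dense_bias_prior), n_out)
    model <- structure(list(config = config, theta = th, bn_state = bn,
                            n_params = sum(vapply(th, length, 1L))),
                       class = "tumor_net")
    model
  })
}

#' @export
print.tumor_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<tumor_net> depth %d, %d convs/block, channels %s, %s -> %dx%d map, %s parameters\n",
    cfg$depth, cfg$convs_per_block, paste(cfg$channels, collapse = "/"),
    paste0(cfg$in_channels, "x", cfg$input_size, "x", cfg$input_size),
    cfg$out_pixels, cfg$out_pixels, format(x$n_params, big.mark = ",")))
  invisible(x)
}

block_fwd <- function(th, bn, prefix, l, A, H, B, K, training) {
  blk <- vector("list", K)
  for (k in seq_len(K)) {
    nm <- sprintf("%s%dc%d", prefix, l, k)
    bnm <- sprintf("%s%db%d", prefix, l, k)
    cv <- conv3_fwd(A, th[[paste0(nm, "_W")]], th[[paste0(nm, "_b")]], H, H, B)
    rl <- relu_fwd(cv$Y)
    st <- bn[[bnm]]
    bo <- bn_fwd(rl$Y, th[[paste0(bnm, "_g")]], th[[paste0(bnm, "_be")]],
                 st$mean, st$var, training)
    if (training) bn[[bnm]] <- list(mean = bo$run_mean, var = bo$run_var)
    A <- bo$Y
    if (!training) {
      cv$X <- NULL; rl$mask <- NULL; bo$xhat <- NULL
    }
    blk[[k]] <- list(conv = cv, relu = rl, bn = bo)
  }
  list(A = A, blk = blk, bn = bn)
}

block_bwd <- function(dA, blk, th, grads, prefix, l, H, B, K) {
  for (k in rev(seq_len(K))) {
    nm <- sprintf("%s%dc%d", prefix, l, k)
    bnm <- sprintf("%s%db%d", prefix, l, k)
    bb <- bn_bwd(dA, blk[[k]]$bn, th[[paste0(bnm, "_g")]])
    grads[[paste0(bnm, "_g")]] <- bb$dgamma
    grads[[paste0(bnm, "_be")]] <- bb$dbeta
    dA <- relu_bwd(bb$dX, blk[[k]]$relu)
    cb <- conv3_bwd(dA, blk[[k]]$conv, th[[paste0(nm, "_W")]], H, H, B)
    grads[[paste0(nm, "_W")]] <- cb$dW
    grads[[paste0(nm, "_b")]] <- cb$db
    dA <- cb$dX
  }
  list(dA = dA, grads = grads)
}

# Forward pass.  X: (B*s*s) x in_channels activation matrix.  Returns the
# B x out_pixels^2 probability matrix, the layer caches (training mode only)
# and the possibly updated batch-norm running statistics.
model_forward <- function(model, X, B, training = FALSE) {
  cfg <- model$config
  th <- model$theta
  bn <- model$bn_state
  depth <- cfg$depth
  K <- cfg$convs_per_block
  cache <- list(enc = vector("list", depth),
                dec = vector("list", max(depth - 1L, 0L)),
                up = vector("list", max(depth - 1L, 0L)))
  skips <- vector("list", depth)
  H <- cfg$input_size
  A <- X
  for (l in seq_len(depth)) {
    r <- block_fwd(th, bn, "e", l, A, H, B, K, training)
    A <- r$A; bn <- r$bn
    cache$enc[[l]] <- list(convs = r$blk, H = H)
    if (l < depth) {
      skips[[l]] <- A
      po <- pool_fwd(A, pool_idx_cached(H, H, B))
      if (!training) po$masks <- NULL
      cache$enc[[l]]$pool <- po
      A <- po$Y
      H <- H %/% 2L
    }
  }
  for (l in rev(seq_len(depth - 1L))) {
    C_lo <- level_channels(cfg, l)
    Hout <- 2L * H
    idx_out <- pool_idx_cached(Hout, Hout, B)
    uo <- up_fwd(A, th[[sprintf("u%d_W", l)]], th[[sprintf("u%d_b", l)]],
                 idx_out, C_lo)
    if (!training) uo$X <- NULL
    cache$up[[l]] <- uo
    A <- cbind(uo$Y, skips[[l]])
    H <- Hout
    r <- block_fwd(th, bn, "d", l, A, H, B, K, training)
    A <- r$A; bn <- r$bn
    cache$dec[[l]] <- list(convs = r$blk, H = H)
  }
  HW <- H * H
  Fm <- flatten_fwd(A, HW, B)
  Z <- Fm %*% th$fc_W + rep(th$fc_b, each = B)
  P <- sigmoid(Z)
  if (training) {
    cache$flat <- list(HW = HW, B = B)
    cache$dense_X <- Fm
  } else {
    cache <- NULL
  }
  list(prob = P, cache = cache, bn_state = bn)
}

# Backward pass from dZ = dLoss/d(pre-sigmoid logits).  Returns the gradient
# as a flat list parallel to model$theta.
model_backward <- function(model, cache, dZ) {
  cfg <- model$config
  th <- model$theta
  depth <- cfg$depth
  K <- cfg$convs_per_block
  B <- cache$flat$B
  grads <- list()
  grads$fc_W <- crossprod(cache$dense_X, dZ)
  grads$fc_b <- colSums(dZ)
  dA <- flatten_bwd(tcrossprod(dZ, th$fc_W), cache$flat$HW, B)
  dskips <- vector("list", depth)
  for (l in seq_len(depth - 1L)) {
    H <- cache$dec[[l]]$H
    r <- block_bwd(dA, cache$dec[[l]]$convs, th, grads, "d", l, H, B, K)
    grads <- r$grads
    C_lo <- level_channels(cfg, l)
    dcat <- r$dA
    dup <- dcat[, seq_len(C_lo), drop = FALSE]
    dskips[[l]] <- dcat[, C_lo + seq_len(C_lo), drop = FALSE]
    ub <- up_bwd(dup, cache$up[[l]], th[[sprintf("u%d_W", l)]],
                 pool_idx_cached(H, H, B), C_lo)
    grads[[sprintf("u%d_W", l)]] <- ub$dW
    grads[[sprintf("u%d_b", l)]] <- ub$db
    dA <- ub$dX
  }
  for (l in rev(seq_len(depth))) {
    H <- cache$enc[[l]]$H
    if (l < depth) {
      C <- level_channels(cfg, l)
      dA <- pool_bwd(dA, cache$enc[[l]]$pool, pool_idx_cached(H, H, B), C)
      dA <- dA + dskips[[l]]
    }
    r <- block_bwd(dA, cache$enc[[l]]$convs, th, grads, "e", l, H, B, K)
    grads <- r$grads
    dA <- r$dA
  }
  grads
}
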