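# Training loop: Adam on pixel-wise binary cross-entropy, early stopping on
# validation BCE, fully seeded.  Inputs are the padded scattering-matrix
# tensors standardized by the dataset's global |S| standard deviation;
# targets are the flattened binary tumor masks.

#' Training configuration
#'
#' Defaults follow the reference training recipe: BCE loss, Adam with
#' learning rate 0.00123, mini-batches of 500 profiles, early stopping on
#' validation BCE.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch budget.
#' @param patience epochs without validation improvement before stopping.
#' @param seed seed controlling weight init and shuffling.
#' @param augment use the dihedral symmetry of the ring geometry (rotations
#'   by multiples of the antenna spacing and reflections, which act on a
#'   sample as an exact antenna permutation of S and a rotation/reflection
#'   of the mask) as lossless training-data augmentation.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is halved (plateau schedule on the initial rate).
#' @param min_lr floor for the scheduled learning rate.
#' @return a \code{train_config} list.
#' @export
train_config <- function(learning_rate = 0.00123, batch_size = 500L,
                         max_epochs = 60L, patience = 5L, seed = 0L,
                         augment = TRUE, lr_patience = 2L,
                         min_lr = learning_rate / 16) {
  list(loss = "bce", optimizer = "adam",
       learning_rate = learning_rate, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       seed = as.integer(seed), augment = isTRUE(augment),
       lr_patience = as.integer(lr_patience), min_lr = min_lr)
}

adam_init <- function(theta) {
  list(m = lapply(theta, function(p) p * 0),
       v = lapply(theta, function(p) p * 0),
       t = 0L)
}

# One Adam step, updating theta and the moment estimates in place (they are
# owned exclusively by the training loop; checkpoints deep-copy).
adam_step <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    adam_update_inplace(theta[[nm]], grads[[nm]],
                        state$m[[nm]], state$v[[nm]],
                        lr, beta1, beta2, eps, c1, c2)
  }
  list(theta = theta, state = state)
}

# Assemble the (B*s*s) x 2 network input for a set of records, and the
# B x out^2 target matrix.  inputs: precomputed (s*s*N) x 2 matrix with one
# s*s block per record; masks_flat: out^2 x N matrix.
gather_batch <- function(inputs, ids, s2, rowmaps = NULL, transforms = NULL) {
  if (is.null(rowmaps)) {
    rows <- rep((ids - 1L) * s2, each = s2) + rep(seq_len(s2), length(ids))
  } else {
    rows <- unlist(lapply(seq_along(ids), function(k) {
      (ids[k] - 1L) * s2 + rowmaps[[transforms[k]]]
    }), use.names = FALSE)
  }
  inputs[rows, , drop = FALSE]
}

# Exact dihedral symmetry of the acquisition: with antennas evenly spaced on
# a ring centered on the pixel grid, reflecting the phantom across either
# grid axis or rotating it by 180 degrees permutes the antennas, so the
# transformed sample's scattering matrix is S[q, q] for an (involutive)
# antenna permutation q, and its mask is an exact pixel permutation.  Used
# as lossless training-data augmentation.
antenna_permutation <- function(n_ant, transform) {
  a <- 0:(n_ant - 1L)
  ap <- switch(transform,
               id = a,
               flip_col = (n_ant - a) %% n_ant,   # mirror across the row axis
               flip_row = (n_ant / 2L + n_ant - a) %% n_ant, # across col axis
               rot180 = (a + n_ant / 2L) %% n_ant)
  ap + 1L
}

# The full dihedral symmetry group of the ring: rotations by any multiple of
# the antenna spacing (2 pi / n_ant) and reflections.  Each group element
# acts on a sample as an exact circular antenna permutation of S and a
# rotation/reflection of the mask about the grid center (nearest-neighbor
# resampled for non-right angles; sub-pixel target error only, and pixels
# rotated in from outside the grid are empty because the breast never
# reaches the corners).  2 * n_ant lossless-input transforms in total.
#
# Row index maps (length s^2) act on a padded s x s input block; pixel index
# maps (length out_px^2, NA = source outside the grid) act on a flattened
# mask.
augmentation_maps <- function(n_ant, s, out_px) {
  base <- matrix(seq_len(s * s), s, s)
  n_tr <- 2L * n_ant
  rowmaps <- vector("list", n_tr)
  maskmaps <- vector("list", n_tr)
  c0 <- (out_px - 1) / 2
  ij <- expand.grid(i = 0:(out_px - 1L), j = 0:(out_px - 1L))
  t <- 0L
  for (f in c(0L, 1L)) {
    for (k in 0:(n_ant - 1L)) {
      t <- t + 1L
      a <- 0:(n_ant - 1L)
      q <- (((if (f == 1L) -a else a) - k) %% n_ant) + 1L
      M <- base
      M[1L + seq_len(n_ant), 1L + seq_len(n_ant)] <- base[1L + q, 1L + q]
      rowmaps[[t]] <- as.vector(M)
      # mask source pixel: invert the flip, then rotate back by -Delta
      j1 <- if (f == 1L) out_px - 1L - ij$j else ij$j
      ang <- -2 * pi * k / n_ant
      si <- round(c0 + cos(ang) * (ij$i - c0) - sin(ang) * (j1 - c0))
      sj <- round(c0 + sin(ang) * (ij$i - c0) + cos(ang) * (j1 - c0))
      idx <- si + out_px * sj + 1L
      idx[si < 0 | si >= out_px | sj < 0 | sj >= out_px] <- NA_integer_
      maskmaps[[t]] <- as.integer(idx)
    }
  }
  list(n = n_tr, rowmaps = rowmaps, maskmaps = maskmaps)
}

# Per-entry input standardization.  Each scattering-matrix entry (r, t) is
# centered by its training-set mean and scaled by its training-set standard
# deviation (real and imaginary parts separately, with a floor on the
# per-entry sd).  Removing the entry-wise mean strips the scattering
# structure shared by all breasts, so the network sees each sample as a
# deviation from the typical profile -- the scale on which a tumor lives.
standardize_stats <- function(smat, train_idx) {
  tr <- smat[, , train_idx, drop = FALSE]
  mu_re <- apply(Re(tr), c(1, 2), mean)
  mu_im <- apply(Im(tr), c(1, 2), mean)
  sd_re <- apply(Re(tr), c(1, 2), stats::sd)
  sd_im <- apply(Im(tr), c(1, 2), stats::sd)
  floor_re <- 0.05 * sqrt(mean(sd_re^2))
  floor_im <- 0.05 * sqrt(mean(sd_im^2))
  list(mu_re = mu_re, mu_im = mu_im,
       sd_re = pmax(sd_re, floor_re), sd_im = pmax(sd_im, floor_im))
}

# Precompute standardized padded inputs for all records of a dataset.
prepare_inputs <- function(smat, stats) {
  n <- dim(smat)[3]
  na <- dim(smat)[1]
  s <- na + 2L
  s2 <- s * s
  inner <- as.vector(outer(2:(na + 1L), (2:(na + 1L) - 1L) * s, "+"))
  X <- matrix(0, s2 * n, 2L)
  for (i in seq_len(n)) {
    S <- smat[, , i]
    off <- (i - 1L) * s2
    X[off + inner, 1L] <- (Re(S) - stats$mu_re) / stats$sd_re
    X[off + inner, 2L] <- (Im(S) - stats$mu_im) / stats$sd_im
  }
  X
}

batched_bce <- function(model, X, Yflat, ids, s2, batch) {
  tot <- 0
  cnt <- 0
  for (chunk in split(ids, ceiling(seq_along(ids) / batch))) {
    Xb <- gather_batch(X, chunk, s2)
    out <- model_forward(model, Xb, length(chunk), training = FALSE)
    Yb <- t(Yflat[, chunk, drop = FALSE]) + 0
    tot <- tot + bce_loss(out$prob, Yb) * length(chunk)
    cnt <- cnt + length(chunk)
  }
  tot / cnt
}

#' Train the tumor-probability network
#'
#' Minimizes pixel-wise BCE between predicted maps and binary tumor masks on
#' the training split, evaluates validation BCE each epoch, and returns the
#' parameters of the epoch with minimal validation loss (early stopping).
#'
#' @param dataset an \code{mwi_dataset} with train/val splits.
#' @param config network architecture from [model_config()].
#' @param train_cfg training configuration from [train_config()].
#' @param verbose print per-epoch losses.
#' @return an \code{mwi_fit}: trained model, training history, best epoch /
#'   validation BCE, standardization scale, and the run configuration.
#' @export
train_model <- function(dataset, config = model_config(),
                        train_cfg = train_config(), verbose = FALSE) {
  train_ids <- which(dataset$split == "train")
  val_ids <- which(dataset$split == "val")
  if (length(train_ids) == 0L) stop("empty training split")
  if (length(val_ids) == 0L) stop("empty validation split")

  na <- dim(dataset$smatrix)[1]
  s <- na + 2L
  s2 <- s * s
  stopifnot(config$input_size == s)
  out2 <- config$out_pixels^2
  stopifnot(dim(dataset$tumor_mask)[1] == config$out_pixels)

  stats <- standardize_stats(dataset$smatrix, train_ids)
  X <- prepare_inputs(dataset$smatrix, stats)
  Yflat <- matrix(as.vector(dataset$tumor_mask), out2,
                  dim(dataset$tumor_mask)[3])

  model <- build_model(config, seed = train_cfg$seed)
  opt <- adam_init(model$theta)
  history <- data.frame(epoch = integer(0), train_bce = numeric(0),
                        val_bce = numeric(0))
  deep_copy <- function(lst) lapply(lst, function(p) p + 0)
  best_val <- Inf
  best_theta <- deep_copy(model$theta)
  best_bn <- model$bn_state
  best_epoch <- 0L
  wait <- 0L
  lr_wait <- 0L
  lr <- train_cfg$learning_rate

  aug <- if (train_cfg$augment) {
    augmentation_maps(na, s, config$out_pixels)
  }

  with_seed(derive_seed(train_cfg$seed, "shuffle"), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      perm <- sample(train_ids)
      batches <- split(perm, ceiling(seq_along(perm) / train_cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        if (is.null(aug)) {
          Xb <- gather_batch(X, b, s2)
          Yb <- t(Yflat[, b, drop = FALSE]) + 0
        } else {
          tr <- sample.int(aug$n, length(b), replace = TRUE)
          Xb <- gather_batch(X, b, s2, aug$rowmaps, tr)
          Yb <- matrix(0, length(b), out2)
          for (k in seq_along(b)) {
            map <- aug$maskmaps[[tr[k]]]
            y <- Yflat[map, b[k]]
            y[is.na(map)] <- 0
            Yb[k, ] <- y
          }
        }
        out <- model_forward(model, Xb, length(b), training = TRUE)
        model$bn_state <- out$bn_state
        loss <- bce_loss(out$prob, Yb)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (learning rate too high or degenerate inputs)")
        }
        dZ <- (out$prob - Yb) / length(Yb)
        grads <- model_backward(model, out$cache, dZ)
        upd <- adam_step(model$theta, grads, opt, lr)
        model$theta <- upd$theta
        opt <- upd$state
        ep_loss <- ep_loss + loss * length(b)
      }
      ep_loss <- ep_loss / length(perm)
      val_loss <- batched_bce(model, X, Yflat, val_ids, s2,
                              max(train_cfg$batch_size, 100L))
      history <- rbind(history, data.frame(epoch = epoch, train_bce = ep_loss,
                                           val_bce = val_loss, lr = lr))
      if (verbose) {
        message(sprintf("epoch %d: train BCE %.5f, val BCE %.5f (lr %.2e)",
                        epoch, ep_loss, val_loss, lr))
      }
      if (val_loss < best_val) {
        best_val <- val_loss
        best_theta <- deep_copy(model$theta)
        best_bn <- model$bn_state
        best_epoch <- epoch
        wait <- 0L
        lr_wait <- 0L
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
        if (wait >= train_cfg$patience) break
        if (lr_wait >= train_cfg$lr_patience && lr / 2 >= train_cfg$min_lr) {
          lr <- lr / 2
          lr_wait <- 0L
        }
      }
    }
  })
  model$theta <- best_theta
  model$bn_state <- best_bn
  structure(list(model = model, history = history,
                 best_epoch = best_epoch, best_val_bce = best_val,
                 stats = stats, scale = dataset$manifest$smatrix_scale,
                 config = config, train_cfg = train_cfg),
            class = "mwi_fit")
}

#' @export
print.mwi_fit <- function(x, ...) {
  cat(sprintf(
    "<mwi_fit> best val BCE %.5f at epoch %d/%d; %s parameters\n",
    x$best_val_bce, x$best_epoch, nrow(x$history),
    format(x$model$n_params, big.mark = ",")))
  invisible(x)
}

#' Predict tumor probability maps from scattering matrices
#'
#' Applies the standardization recorded at training time, pads each matrix
#' to the network input tensor, and runs the network in evaluation mode.
#'
#' @param fit an \code{mwi_fit} from [train_model()].
#' @param smatrix complex n x n matrix, or n x n x N array of them.
#' @param batch_size evaluation batch size.
#' @return a 108 x 108 probability matrix for a single input, else a
#'   108 x 108 x N array.
#' @export
predict_maps <- function(fit, smatrix, batch_size = 200L) {
  if (is.null(fit$stats)) {
    stop("fit carries no standardization statistics; refusing to predict on ",
         "unnormalized input")
  }
  single <- length(dim(smatrix)) == 2L
  if (single) smatrix <- array(smatrix, dim = c(dim(smatrix), 1L))
  n <- dim(smatrix)[3]
  s <- dim(smatrix)[1] + 2L
  s2 <- s * s
  op <- fit$model$config$out_pixels
  maps <- array(0, dim = c(op, op, n))
  X <- prepare_inputs(smatrix, fit$stats)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    B <- length(chunk)
    Xb <- gather_batch(X, chunk, s2)
    out <- model_forward(fit$model, Xb, B, training = FALSE)
    for (k in seq_along(chunk)) {
      maps[, , chunk[k]] <- matrix(out$prob[k, ], op, op)
    }
  }
  if (single) maps[, , 1L] else maps
}

#' @export
predict.mwi_fit <- function(object, newdata, ...) {
  predict_maps(object, newdata, ...)
}
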