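# A dataset-shaped stand-in with random scattering matrices, used where the
# tests only need tensors of the right shape (not learnable physics).
fake_dataset <- function(n = 40L, seed = 1L, empty_masks = FALSE) {
  set.seed(seed)
  smat <- array(complex(real = rnorm(900 * n), imaginary = rnorm(900 * n)),
                dim = c(30, 30, n))
  masks <- array(FALSE, dim = c(108, 108, n))
  if (!empty_masks) {
    for (k in seq(1, n, by = 2)) {
      ci <- sample(20:88, 1)
      cj <- sample(20:88, 1)
      masks[ci + (-2:2), cj + (-2:2), k] <- TRUE
    }
  }
  split <- rep("train", n)
  split[seq(1, n, by = 5)] <- "val"
  structure(list(smatrix = smat, tumor_mask = masks, split = split,
                 healthy = apply(masks, 3, sum) == 0,
                 density_class = rep(1:4, length.out = n),
                 manifest = list(smatrix_scale = stats::sd(Mod(smat)),
                                 pixel_size_cm = 15 / 108)),
            class = "mwi_dataset")
}

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_config()
  model <- build_model(cfg, seed = 42L)
  set.seed(7)
  B <- 3L
  X <- matrix(rnorm(B * 64 * 2), B * 64, 2)
  Y <- matrix(rbinom(B * 16, 1, 0.3), B, 16)
  loss_fn <- function(m) {
    out <- model_forward(m, X, B, training = TRUE)
    bce_loss(out$prob, Y)
  }
  out <- model_forward(model, X, B, training = TRUE)
  grads <- model_backward(model, out$cache, (out$prob - Y) / length(Y))
  eps <- 1e-6
  worst <- 0
  for (nm in names(model$theta)) {
    th <- model$theta[[nm]]
    for (i in sample(length(th), min(3, length(th)))) {
      m2 <- model
      m2$theta[[nm]][i] <- th[i] + eps
      l1 <- loss_fn(m2)
      m2$theta[[nm]][i] <- th[i] - eps
      l0 <- loss_fn(m2)
      gnum <- (l1 - l0) / (2 * eps)
      rel <- abs(gnum - grads[[nm]][i]) /
        max(1e-8, abs(gnum) + abs(grads[[nm]][i]))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("forward pass yields valid probability maps of 11664 pixels", {
  cfg <- model_config(base_channels = 1L)
  model <- build_model(cfg, seed = 1L)
  X0 <- matrix(0, 2 * 32 * 32, 2)
  out <- model_forward(model, X0, 2L, training = FALSE)
  expect_equal(dim(out$prob), c(2L, 11664L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  # eval mode is deterministic
  out2 <- model_forward(model, X0, 2L, training = FALSE)
  expect_identical(out$prob, out2$prob)
})

test_that("prediction is standardized, batch-invariant and range-valid", {
  ds <- fake_dataset(8, seed = 2)
  cfg <- model_config(base_channels = 1L)
  fit <- structure(list(model = build_model(cfg, 3L),
                        stats = mwiseg:::standardize_stats(ds$smatrix, 1:8)),
                   class = "mwi_fit")
  maps <- predict_maps(fit, ds$smatrix)
  expect_equal(dim(maps), c(108L, 108L, 8L))
  expect_true(all(maps >= 0 & maps <= 1))
  one <- predict_maps(fit, ds$smatrix[, , 3])
  expect_equal(dim(one), c(108L, 108L))
  expect_equal(one, maps[, , 3], tolerance = 1e-12)
  fit$stats <- NULL
  expect_error(predict_maps(fit, ds$smatrix), "statistics")
})

test_that("reported BCE equals the hand-computed cross-entropy", {
  set.seed(9)
  p <- matrix(runif(200, 0.01, 0.99), 10, 20)
  y <- matrix(rbinom(200, 1, 0.4), 10, 20)
  byhand <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bce_loss(p, y), byhand, tolerance = 1e-6)
  # clamping keeps the loss finite at the boundaries
  expect_true(is.finite(bce_loss(matrix(c(0, 1), 1, 2), matrix(c(1, 0), 1, 2))))
})

test_that("training reduces the loss on small random problems", {
  drops <- vapply(1:3, function(seed) {
    ds <- fake_dataset(40, seed = seed)
    fit <- train_model(ds, model_config(base_channels = 1L),
                       train_config(batch_size = 10L, max_epochs = 2L,
                                    patience = 2L, seed = seed))
    diff(fit$history$train_bce) < 0
  }, TRUE)
  expect_gte(sum(drops), 2)
})

test_that("an all-healthy training set drives predictions toward zero", {
  ds <- fake_dataset(30, seed = 4, empty_masks = TRUE)
  # start from an uninformative prior so convergence is the model's doing
  fit <- train_model(ds, model_config(base_channels = 1L,
                                      dense_bias_prior = 0.5),
                     train_config(batch_size = 10L, max_epochs = 15L,
                                  patience = 15L, seed = 4L))
  maps <- predict_maps(fit, ds$smatrix[, , 1:5])
  expect_lt(mean(maps), 0.05)
})

test_that("checkpoint serialization round-trips exactly", {
  fit <- small_fit()
  path <- tempfile(fileext = ".rds")
  saveRDS(fit, path)
  fit2 <- readRDS(path)
  ds <- small_dataset()
  val_ids <- which(ds$split == "val")
  m1 <- predict_maps(fit, ds$smatrix[, , val_ids])
  m2 <- predict_maps(fit2, ds$smatrix[, , val_ids])
  expect_identical(m1, m2)
  expect_identical(fit2$best_val_bce, fit$best_val_bce)
})

test_that("a trained toy model beats a permuted-weights control on soft-Dice", {
  fit <- small_fit()
  ds <- small_dataset()
  ids <- which(ds$split == "train" & !ds$healthy)
  maps <- predict_maps(fit, ds$smatrix[, , ids])
  ctrl <- fit
  perm <- with_seed(1, sample(length(ctrl$model$theta$fc_W)))
  ctrl$model$theta$fc_W <- matrix(ctrl$model$theta$fc_W[perm],
                                  nrow(ctrl$model$theta$fc_W))
  maps_ctrl <- predict_maps(ctrl, ds$smatrix[, , ids])
  d_fit <- mean(vapply(seq_along(ids), function(k) {
    soft_dice(maps[, , k], ds$tumor_mask[, , ids[k]] + 0)
  }, 1))
  d_ctrl <- mean(vapply(seq_along(ids), function(k) {
    soft_dice(maps_ctrl[, , k], ds$tumor_mask[, , ids[k]] + 0)
  }, 1))
  expect_gt(d_fit, d_ctrl)
})
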