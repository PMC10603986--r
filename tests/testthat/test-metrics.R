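test_that("derived classification metrics reproduce the reference confusion matrix", {
  counts <- list(TP = 7993, FN = 3, FP = 5, TN = 7999)
  m <- classification_metrics(counts)
  expect_equal(m$rounded$accuracy, 0.9995)
  expect_equal(m$rounded$sensitivity, 0.9996)
  expect_equal(m$rounded$specificity, 0.9994)
  expect_equal(m$rounded$precision, 0.9994)
  expect_equal(m$rounded$f1, 0.9995)
  expect_equal(counts$FP + counts$FN, 8)                 # total errors
  expect_equal(counts$TP + counts$FN, 7996)              # actual positives
  expect_equal(with(counts, TP + FN + FP + TN), 16000)
})

test_that("degenerate and hand-computed confusion cases behave", {
  m0 <- classification_metrics(list(TP = 0, FN = 0, FP = 0, TN = 10))
  expect_equal(m0$accuracy, 1)
  expect_equal(m0$specificity, 1)
  expect_true(is.na(m0$sensitivity))
  expect_true("sensitivity" %in% m0$undefined)

  m1 <- classification_metrics(list(TP = 1, FN = 1, FP = 1, TN = 1))
  expect_equal(unlist(m1[c("accuracy", "sensitivity", "specificity",
                           "precision", "f1")]),
               c(accuracy = 0.5, sensitivity = 0.5, specificity = 0.5,
                 precision = 0.5, f1 = 0.5))
})

test_that("profile classification uses a strict 15% threshold", {
  z <- matrix(0, 108, 108)
  expect_false(classify_profile(z))
  z[40, 60] <- 0.16
  expect_true(classify_profile(z))
  expect_false(classify_profile(matrix(0.15, 108, 108)))
})

test_that("probability center of mass discretizes half-up on 0-based indices", {
  m <- matrix(0, 108, 108)
  m[11, 21] <- 0.7                       # 0-based (10, 20)
  expect_equal(prob_center_of_mass(m), c(10, 20))

  m2 <- matrix(0, 108, 108)
  m2[50:52, 50:52] <- 0.3                # symmetric plateau at 0-based (50,50)
  expect_equal(prob_center_of_mass(m2), c(50, 50))

  m3 <- matrix(0, 108, 108)
  m3[1, 1] <- 0.2                        # (0,0)
  m3[1, 5] <- 0.6                        # (0,4); weighted col = 3.0
  expect_equal(prob_center_of_mass(m3), c(0, 3))

  expect_null(prob_center_of_mass(matrix(0, 108, 108)))
})

test_that("center distances convert pixels to cm with the printed pixel size", {
  expect_equal(center_distance(c(5, 5), c(5, 5))$px, 0)
  d <- center_distance(c(5, 5), c(8, 9))
  expect_equal(d$px, 5)
  expect_equal(d$cm, 0.695)
  expect_equal(center_distance(c(0, 0), c(0, 1))$cm, 0.139)
  # bounded by the grid diagonal
  expect_lte(center_distance(c(0, 0), c(107, 107))$px, 107 * sqrt(2))
})

test_that("soft-Dice matches identities, the worked case, and symmetry", {
  set.seed(2)
  I <- matrix(rbinom(100, 1, 0.3), 10, 10)
  expect_equal(soft_dice(I, I), 1)
  J <- matrix(0, 10, 10)
  J[I == 0] <- 1
  J[1, 1] <- 0
  expect_equal(soft_dice(I, J), 0)                       # disjoint supports
  expect_equal(soft_dice(0.5 * I, I), 0.8)               # 2(.5k)/(.25k + k)
  expect_equal(soft_dice(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  A <- matrix(runif(64), 8, 8)
  B <- matrix(runif(64), 8, 8)
  expect_equal(soft_dice(A, B), soft_dice(B, A))
  p <- sample(64)
  expect_equal(soft_dice(matrix(A[p], 8), matrix(B[p], 8)), soft_dice(A, B))
})

test_that("NCC matches identities, anti-correlation, and affine invariance", {
  set.seed(3)
  I <- matrix(rbinom(100, 1, 0.4), 10, 10)
  expect_equal(ncc(I, I), 1)
  expect_equal(ncc(I, 1 - I), -1)
  cb <- matrix(c(1, -1, -1, 1), 2, 2)                    # orthogonal 2x2 case
  g <- matrix(c(1, 1, -1, -1), 2, 2)
  expect_equal(ncc(cb, g), 0)
  A <- matrix(runif(100), 10, 10)
  expect_equal(ncc(3 * A + 2, I), ncc(A, I))
  expect_true(is.na(ncc(matrix(1, 10, 10), I)))
})

test_that("restricted NRMSE evaluates only reference-or-detected pixels", {
  ref <- matrix(0, 20, 20)
  ref[5:6, 5:6] <- 1                                     # 4 tumor pixels
  expect_equal(nrmse_restricted(ref, ref), 0)
  expect_equal(nrmse_restricted(matrix(0, 20, 20), ref), 1)
  est <- matrix(0, 20, 20)
  est[5:6, 5:6] <- 0.5
  expect_equal(nrmse_restricted(est, ref), 0.5)
  expect_true(is.na(nrmse_restricted(matrix(0, 20, 20), matrix(0, 20, 20))))
  # monotone improvement as the estimate approaches the reference
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
    nrmse_restricted(w * ref + (1 - w) * est, ref)
  }, 1)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("connected-component labeling distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE                                        # diagonal touch
  m[5, 5] <- TRUE
  expect_equal(n_components(m, 8), 2)
  expect_equal(n_components(m, 4), 3)
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0)
  ring <- matrix(FALSE, 7, 7)
  ring[2:6, 2:6] <- TRUE
  ring[3:5, 3:5] <- FALSE
  expect_equal(n_components(ring, 8), 1)
})

test_that("single-tumor subset keeps one-component masks and balances classes", {
  one <- matrix(FALSE, 20, 20); one[3:5, 3:5] <- TRUE
  two <- one; two[15:16, 15:16] <- TRUE
  masks <- list(); cls <- integer(0)
  for (k in 1:4) {
    masks <- c(masks, rep(list(one), k + 1), list(two))
    cls <- c(cls, rep(k, k + 2))
  }
  sel <- single_tumor_subset(masks, cls, seed = 1)
  expect_true(all(vapply(masks[sel], function(m) n_components(m, 8) == 1, TRUE)))
  expect_true(all(table(cls[sel]) == 2))                 # min class count
  expect_error(single_tumor_subset(list(two), 1L), "single-tumor|class")
})

test_that("oracle and null predictors produce the expected evaluation reports", {
  ds <- small_dataset()
  ids <- which(ds$split == "test")
  oracle <- array(0, dim = c(108, 108, length(ids)))
  for (k in seq_along(ids)) oracle[, , k] <- ds$tumor_mask[, , ids[k]] + 0
  rep_o <- evaluate_model(oracle, ds, split = "test")
  expect_equal(rep_o$metrics$accuracy, 1)
  expect_equal(rep_o$roc_auc, 1)
  expect_true(all(rep_o$center_distances$distance_px == 0))
  expect_true(all(rep_o$similarity$soft_dice == 1))
  expect_true(check_report(rep_o))

  null_maps <- array(0, dim = c(108, 108, length(ids)))
  rep_n <- evaluate_model(null_maps, ds, split = "test")
  expect_equal(rep_n$metrics$sensitivity, 0)
  expect_equal(rep_n$metrics$specificity, 1)
  expect_true(check_report(rep_n))
  h <- distance_histogram(rep_o)
  expect_true(all(h$count >= 0))
})
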