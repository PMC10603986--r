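# Full evaluation of a trained model on a dataset split: confusion counts
# and derived classification metrics plus ROC-AUC over all profiles,
# center-of-mass localization distances on the balanced single-tumor subset,
# and pixel-wise similarity metrics on the malignant profiles.

#' Evaluate a trained model on a dataset split
#'
#' Predicts probability maps for every profile of the split and computes the
#' three evaluation tiers: (1) profile classification via the any-pixel
#' threshold rule, with confusion counts, derived metrics and ROC-AUC over
#' max-pixel scores; (2) tumor-center distances on the single-connected-tumor
#' subset balanced across density classes; (3) soft-Dice, NCC and restricted
#' NRMSE on the malignant profiles, with means and standard deviations.
#'
#' @param fit an \code{mwi_fit}, or a precomputed 108 x 108 x N map array
#'   (useful for oracle/baseline evaluations).
#' @param dataset an \code{mwi_dataset}.
#' @param split which split to evaluate ("test", "val", "train" or "all").
#' @param threshold classification threshold (default 0.15).
#' @param subset_seed seed for the class-balancing down-sampling of the
#'   single-tumor subset.
#' @return an \code{eval_report}.
#' @export
evaluate_model <- function(fit, dataset, split = "test", threshold = 0.15,
                           subset_seed = 0L) {
  ids <- if (identical(split, "all")) seq_along(dataset$split)
  else which(dataset$split == split)
  if (length(ids) == 0L) stop("empty evaluation split: ", split)

  maps <- if (inherits(fit, "mwi_fit")) {
    predict_maps(fit, dataset$smatrix[, , ids, drop = FALSE])
  } else {
    stopifnot(is.array(fit), dim(fit)[3] == length(ids))
    fit
  }
  masks <- lapply(seq_along(ids), function(k) dataset$tumor_mask[, , ids[k]])
  truth <- !dataset$healthy[ids]
  scores <- apply(maps, 3, max)
  predicted <- scores > threshold

  counts <- confusion_counts(predicted, truth)
  metrics <- classification_metrics(counts)
  roc_auc <- if (length(unique(truth)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  } else NA_real_

  # tier 2: localization on the balanced single-tumor subset
  px_exact <- dataset$manifest$pixel_size_cm %||% (15 / 108)
  tum_local <- which(truth)
  subset_rel <- integer(0)
  centers <- data.frame(index = integer(0), distance_px = numeric(0),
                        distance_cm = numeric(0))
  n_no_detection <- 0L
  if (length(tum_local) > 0L) {
    st <- tryCatch(
      single_tumor_subset(masks[tum_local],
                          dataset$density_class[ids][tum_local],
                          seed = subset_seed),
      error = function(e) integer(0))
    subset_rel <- tum_local[st]
    for (k in subset_rel) {
      est <- prob_center_of_mass(maps[, , k])
      if (is.null(est)) {
        n_no_detection <- n_no_detection + 1L
        next
      }
      ref <- prob_center_of_mass(masks[[k]] + 0)
      d <- center_distance(est, ref, px_exact)
      centers <- rbind(centers, data.frame(index = ids[k],
                                           distance_px = d$px,
                                           distance_cm = d$cm))
    }
  }

  # tier 3: pixel-wise similarity on malignant profiles
  sim <- data.frame(index = ids[tum_local],
                    soft_dice = NA_real_, ncc = NA_real_, nrmse = NA_real_)
  for (k in seq_along(tum_local)) {
    m <- maps[, , tum_local[k]]
    ref <- masks[[tum_local[k]]] + 0
    sim$soft_dice[k] <- soft_dice(m, ref)
    sim$ncc[k] <- ncc(m, ref)
    sim$nrmse[k] <- nrmse_restricted(m, ref, threshold)
  }
  summarize <- function(v) {
    list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
         n = sum(!is.na(v)), n_undefined = sum(is.na(v)))
  }

  structure(list(
    split = split,
    threshold = threshold,
    n_profiles = length(ids),
    counts = counts,
    metrics = metrics,
    roc_auc = roc_auc,
    scores = scores,
    truth = truth,
    center_distances = centers,
    n_single_tumor = length(subset_rel),
    n_no_detection = n_no_detection,
    similarity = sim,
    summary = list(
      soft_dice = summarize(sim$soft_dice),
      ncc = summarize(sim$ncc),
      nrmse = summarize(sim$nrmse),
      center_distance_cm = summarize(centers$distance_cm),
      center_distance_px = summarize(centers$distance_px)
    ),
    pixel_size_cm = px_exact
  ), class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval_report> %s split, %d profiles (threshold %.2f)\n",
              x$split, x$n_profiles, x$threshold))
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d\n",
              x$counts$TP, x$counts$FN, x$counts$FP, x$counts$TN))
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f  precision %.4f  F1 %.4f\n",
              m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1))
  cat(sprintf("  ROC-AUC %.4f\n", x$roc_auc))
  if (nrow(x$center_distances) > 0) {
    cat(sprintf("  center distance (n=%d single-tumor): mean %.2f cm, median %.2f cm, %d no-detection\n",
                nrow(x$center_distances), mean(x$center_distances$distance_cm),
                stats::median(x$center_distances$distance_cm),
                x$n_no_detection))
  }
  s <- x$summary
  cat(sprintf("  soft-Dice %.3f +/- %.3f   NCC %.3f +/- %.3f   NRMSE %.3f +/- %.3f\n",
              s$soft_dice$mean, s$soft_dice$sd, s$ncc$mean, s$ncc$sd,
              s$nrmse$mean, s$nrmse$sd))
  invisible(x)
}

#' Internal consistency check of an evaluation report
#'
#' Recomputes the derived classification metrics from the confusion counts
#' and the summary statistics from the per-profile values; TRUE when
#' everything agrees to \code{tol}.
#'
#' @param report an \code{eval_report}.
#' @param tol numeric tolerance.
#' @return logical.
#' @export
check_report <- function(report, tol = 1e-9) {
  m2 <- classification_metrics(report$counts)
  ok <- TRUE
  for (nm in c("accuracy", "sensitivity", "specificity", "precision", "f1")) {
    a <- report$metrics[[nm]]
    b <- m2[[nm]]
    ok <- ok && (is.na(a) == is.na(b)) && (is.na(a) || abs(a - b) < tol)
  }
  total <- with(report$counts, TP + FP + TN + FN)
  ok <- ok && total == report$n_profiles
  for (nm in c("soft_dice", "ncc", "nrmse")) {
    v <- report$similarity[[nm]]
    s <- report$summary[[nm]]
    if (s$n > 0) ok <- ok && abs(mean(v, na.rm = TRUE) - s$mean) < tol
    ok <- ok && s$n == sum(!is.na(v))
  }
  if (nrow(report$center_distances) > 0) {
    s <- report$summary$center_distance_cm
    ok <- ok && abs(mean(report$center_distances$distance_cm) - s$mean) < tol
  }
  ok
}

#' Histogram data of center-localization distances
#'
#' Bin counts of the Euclidean center distances (in pixels) of an
#' evaluation report, suitable for plotting or CSV export.
#'
#' @param report an \code{eval_report}.
#' @param binwidth_px bin width in pixels.
#' @return data.frame with bin_left_px, bin_right_px, count.
#' @export
distance_histogram <- function(report, binwidth_px = 1) {
  d <- report$center_distances$distance_px
  if (length(d) == 0L) {
    return(data.frame(bin_left_px = numeric(0), bin_right_px = numeric(0),
                      count = integer(0)))
  }
  breaks <- seq(0, ceiling(max(d) / binwidth_px) * binwidth_px + binwidth_px,
                by = binwidth_px)
  h <- hist(d, breaks = breaks, plot = FALSE)
  data.frame(bin_left_px = h$breaks[-length(h$breaks)],
             bin_right_px = h$breaks[-1], count = h$counts)
}

#' Random-center localization baseline
#'
#' For each selected profile, draws a uniformly random pixel inside the
#' breast support and measures its distance to the reference tumor center:
#' the chance-level baseline against which localization is judged.
#'
#' @param dataset an \code{mwi_dataset}.
#' @param indices dataset record indices (absolute).
#' @param seed RNG seed.
#' @return data.frame with index, distance_px, distance_cm.
#' @export
random_center_baseline <- function(dataset, indices, seed = 0L) {
  px <- dataset$manifest$pixel_size_cm %||% (15 / 108)
  with_seed(seed, {
    out <- data.frame(index = indices, distance_px = NA_real_,
                      distance_cm = NA_real_)
    n <- dim(dataset$labels)[1]
    for (r in seq_along(indices)) {
      i <- indices[r]
      support <- which(dataset$labels[, , i] > 0L)
      pick <- support[sample.int(length(support), 1L)]
      est <- c((pick - 1L) %% n, (pick - 1L) %/% n)
      ref <- prob_center_of_mass(dataset$tumor_mask[, , i] + 0)
      d <- center_distance(est, ref, px)
      out$distance_px[r] <- d$px
      out$distance_cm[r] <- d$cm
    }
    out
  })
}
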