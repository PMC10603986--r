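# Three-tier evaluation of tumor probability maps:
#   1. profile classification (any pixel above the 15% threshold),
#   2. tumor-center localization (probability-weighted center of mass,
#      Euclidean distance in pixels and cm),
#   3. pixel-wise similarity (soft-Dice, NCC, NRMSE restricted to the union
#      of reference tumor pixels and detected pixels).

round_half_up <- function(x) floor(x + 0.5)

#' Label connected components of a binary mask
#'
#' Iterative flood fill with 4- or 8-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  n <- nrow(mask)
  p <- ncol(mask)
  lab <- matrix(0L, n, p)
  if (connectivity == 8L) {
    nb <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    while (length(frontier) > 0L) {
      i <- (frontier - 1L) %% n + 1L
      j <- (frontier - 1L) %/% n + 1L
      nxt <- integer(0)
      for (q in seq_len(nrow(nb))) {
        ii <- i + nb[q, 1]
        jj <- j + nb[q, 2]
        ok <- ii >= 1L & ii <= n & jj >= 1L & jj <= p
        cand <- (jj[ok] - 1L) * n + ii[ok]
        cand <- cand[mask[cand] & lab[cand] == 0L]
        if (length(cand) > 0L) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

n_components <- function(mask, connectivity = 8L) {
  max(label_components(mask, connectivity))
}

#' Classify a profile from its tumor probability map
#'
#' A profile is called tumorous when any pixel strictly exceeds the
#' threshold (default 15%).
#'
#' @param map numeric probability matrix in \[0, 1\].
#' @param threshold classification threshold.
#' @return logical; TRUE = tumorous.
#' @export
classify_profile <- function(map, threshold = 0.15) {
  max(map) > threshold
}

#' Confusion counts for profile classification
#'
#' @param predicted logical vector (TRUE = called malignant).
#' @param truth logical vector (TRUE = malignant reference).
#' @return a \code{confusion_counts} list with TP, FP, TN, FN.
#' @export
confusion_counts <- function(predicted, truth) {
  structure(list(TP = sum(predicted & truth),
                 FP = sum(predicted & !truth),
                 TN = sum(!predicted & !truth),
                 FN = sum(!predicted & truth)),
            class = "confusion_counts")
}

#' Derived classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1, each also
#' reported rounded to 4 decimals.  A zero denominator yields NA for that
#' metric (flagged in \code{undefined}) rather than an error.
#'
#' @param counts a \code{confusion_counts} (or list with TP, FP, TN, FN).
#' @return list with exact values, \code{rounded} (4 dp), and
#'   \code{undefined} (names of metrics with zero denominators).
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(accuracy = safe(TP + TN, TP + TN + FP + FN),
              sensitivity = safe(TP, TP + FN),
              specificity = safe(TN, TN + FP),
              precision = safe(TP, TP + FP),
              f1 = safe(2 * TP, 2 * TP + FP + FN))
  out$undefined <- names(out)[vapply(out, function(x) is.na(x[1]), TRUE)]
  out$rounded <- lapply(out[c("accuracy", "sensitivity", "specificity",
                              "precision", "f1")], round, digits = 4)
  out
}

#' Probability-weighted center of mass of a map
#'
#' Center of mass with tumor probability as the mass, discretized to the
#' nearest pixel index (half-up rounding per axis).  Indices are 0-based
#' (row, column), matching the package-wide pixel convention.
#'
#' @param map numeric matrix of probabilities (or a binary mask).
#' @param eps minimum total mass; below it the map is treated as containing
#'   no detection and NULL is returned.
#' @return integer vector c(i, j), 0-based, or NULL if total mass < eps.
#' @export
prob_center_of_mass <- function(map, eps = 1e-9) {
  total <- sum(map)
  if (total < eps) return(NULL)
  n <- nrow(map)
  i <- rowSums(map) %*% (seq_len(n) - 1) / total
  j <- colSums(map) %*% (seq_len(ncol(map)) - 1) / total
  c(round_half_up(i[1]), round_half_up(j[1]))
}

#' Euclidean distance between pixel centers
#'
#' @param est,ref 0-based (i, j) pixel index pairs.
#' @param pixel_size_cm pixel size; the cm distance uses the 3-decimal
#'   rounded pixel size (0.139 cm for the default grid) as the reporting
#'   convention, while callers keep the exact 15/108 value internally.
#' @return list with \code{px} and \code{cm}.
#' @export
center_distance <- function(est, ref, pixel_size_cm = 15 / 108) {
  px <- sqrt(sum((est - ref)^2))
  list(px = px, cm = px * round(pixel_size_cm, 3))
}

#' Select the single-tumor evaluation subset
#'
#' Indices of profiles whose reference mask has exactly one 8-connected
#' tumor component, balanced across the four density classes by seeded
#' down-sampling to the smallest class count.
#'
#' @param masks list of logical reference masks (or 3D array).
#' @param density_class integer vector of density classes.
#' @param seed seed for the down-sampling.
#' @return integer vector of selected indices.
#' @export
single_tumor_subset <- function(masks, density_class, seed = 0L) {
  if (is.array(masks) && length(dim(masks)) == 3L) {
    masks <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  }
  eligible <- which(vapply(masks, function(m) {
    sum(m) > 0L && n_components(m, 8L) == 1L
  }, TRUE))
  if (length(eligible) == 0L) stop("no single-tumor profiles available")
  cls <- density_class[eligible]
  counts <- table(factor(cls, levels = 1:4))
  if (any(counts == 0L)) {
    stop("density class(es) ", paste(names(counts)[counts == 0L], collapse = ", "),
         " have no eligible single-tumor profiles")
  }
  m <- min(counts)
  with_seed(seed, {
    sel <- unlist(lapply(1:4, function(k) {
      pool <- eligible[cls == k]
      sort(pool[sample.int(length(pool), m)])
    }))
  })
  sort(sel)
}

#' Soft-Dice overlap between two images
#'
#' 2 * sum(I1 * I2) / (sum(I1^2) + sum(I2^2)); defined as 0 when both images
#' are identically zero.
#'
#' @param i1,i2 numeric matrices of equal shape.
#' @return value in \[0, 1\] for non-negative inputs.
#' @export
soft_dice <- function(i1, i2) {
  stopifnot(all(dim(i1) == dim(i2)))
  den <- sum(i1^2) + sum(i2^2)
  if (den == 0) return(0)
  2 * sum(i1 * i2) / den
}

#' Normalized cross-correlation between two images
#'
#' Pearson-style correlation over all pixels (mean-centered, normalized by
#' the product of centered norms).  NA when either image is constant.
#'
#' @param i1,i2 numeric matrices of equal shape.
#' @return value in \[-1, 1\], or NA for a constant image.
#' @export
ncc <- function(i1, i2) {
  stopifnot(all(dim(i1) == dim(i2)))
  a <- i1 - mean(i1)
  b <- i2 - mean(i2)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Restricted normalized root-mean-square error
#'
#' RMSE between the estimated map and the binary reference, restricted to
#' the union of reference tumor pixels and pixels the map detects (above the
#' classification threshold), normalized by the reference data range (1 for
#' any non-empty binary mask).  This keeps the metric from being dominated
#' by the many correctly-empty background pixels.  NA when the restricted
#' set is empty (healthy profile with no detection).
#'
#' @param est numeric probability map.
#' @param ref binary reference mask (logical or 0/1).
#' @param threshold detection threshold for the estimated map.
#' @return non-negative value, or NA.
#' @export
nrmse_restricted <- function(est, ref, threshold = 0.15) {
  stopifnot(all(dim(est) == dim(ref)))
  ref <- ref + 0
  set <- ref == 1 | est > threshold
  if (!any(set)) return(NA_real_)
  rng <- max(ref) - min(ref)
  if (rng == 0) rng <- 1
  sqrt(mean((est[set] - ref[set])^2)) / rng
}
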