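# Randomized 2D breast phantoms on a 15x15 cm slice rasterized at 7.2
# pixels/cm (108x108).  Six tissue classes are used:
#   0 background (immersion medium), 1 skin, 2 adipose, 3 transitional,
#   4 fibro-glandular, 5 tumor.
# A phantom's density class (1..4) is the band of its glandular fraction
# g = #{labels 3,4} / #{labels 1..5}.

TISSUE_BACKGROUND <- 0L
TISSUE_SKIN <- 1L
TISSUE_ADIPOSE <- 2L
TISSUE_TRANSITIONAL <- 3L
TISSUE_FIBROGLANDULAR <- 4L
TISSUE_TUMOR <- 5L

#' Phantom generator parameters
#'
#' Morphology and sampling defaults for the randomized breast slices: the
#' breast outline is a harmonically perturbed ellipse with a 2-pixel skin
#' rim; the fibro-glandular region is the top quantile of a smoothed random
#' field biased toward the breast center, with a transitional band beneath
#' it; tumors are perturbed ellipses.  All lengths in cm on the 15x15 cm
#' domain.
#'
#' @param grid_n raster size (108 pixels = 7.2 px/cm).
#' @param domain_cm physical side length of the slice.
#' @param breast_radius_range_cm range of the mean outline radius.
#' @param center_jitter_cm max offset of the breast center from the domain
#'   center.
#' @param ellipticity_range range of the minor/major axis ratio.
#' @param outline_harmonic_amp max amplitude of outline harmonics k = 2..5.
#' @param skin_px skin rim thickness in pixels.
#' @param coarse_field_n side of the coarse Gaussian field that is
#'   bilinearly upsampled to form the glandular texture.
#' @param centrality_weight weight of the center-bias added to the texture.
#' @param transitional_fraction fraction of the glandular-complex pixels
#'   labeled transitional rather than fibro-glandular.
#' @param density_thresholds glandular-fraction cut points between the four
#'   density classes.
#' @param class_target_bands sampling band of the target glandular fraction
#'   per density class (kept inside the class band so that tumor insertion
#'   rarely moves a phantom across a class boundary).
#' @param tumor_radius_range_cm tumor equivalent-radius sampling range.
#' @param tumor_count_probs probabilities of 1, 2, 3 tumors per diseased
#'   phantom.
#' @param retry_budget rejection-sampling attempts before giving up.
#' @return list of parameters.
#' @export
phantom_params <- function(grid_n = 108L,
                           domain_cm = 15,
                           breast_radius_range_cm = c(3.0, 4.8),
                           center_jitter_cm = 0.8,
                           ellipticity_range = c(0.85, 1.0),
                           outline_harmonic_amp = 0.05,
                           skin_px = 2L,
                           coarse_field_n = 9L,
                           centrality_weight = 0.8,
                           transitional_fraction = 0.3,
                           density_thresholds = c(0.10, 0.25, 0.50),
                           class_target_bands = list(c(0.02, 0.09),
                                                     c(0.13, 0.22),
                                                     c(0.28, 0.46),
                                                     c(0.53, 0.70)),
                           tumor_radius_range_cm = c(0.3, 1.0),
                           tumor_count_probs = c(0.7, 0.2, 0.1),
                           retry_budget = 25L) {
  as.list(environment())
}

#' Tissue dielectric table
#'
#' Complex relative permittivity per tissue class at the operating frequency,
#' with a per-class multiplicative jitter fraction.  Values follow published
#' breast-tissue dielectric ranges around 1 GHz with an exp(+j omega t) time
#' convention, so loss appears as a negative imaginary part; the immersion
#' background is lossless and never jittered.  The tumor permittivity sits
#' moderately above the fibro-glandular mean: that deliberately subtle
#' contrast is what makes tumor-vs-gland discrimination the hard part of the
#' problem.
#'
#' @param frequency_hz operating frequency (metadata only; the table is
#'   single-frequency).
#' @param jitter_fraction per-pixel multiplicative jitter applied to tissue
#'   (not background) permittivities.
#' @return data.frame with columns class, name, permittivity, jitter.
#' @export
tissue_dielectric_table <- function(frequency_hz = 1e9, jitter_fraction = 0.05) {
  tab <- data.frame(
    class = 0:5,
    name = c("background", "skin", "adipose", "transitional",
             "fibroglandular", "tumor"),
    permittivity = c(complex(real = 10, imaginary = 0),
                     complex(real = 36, imaginary = -4),
                     complex(real = 5, imaginary = -0.5),
                     complex(real = 20, imaginary = -2),
                     complex(real = 45, imaginary = -5),
                     complex(real = 55, imaginary = -6)),
    jitter = c(0, rep(jitter_fraction, 5)),
    stringsAsFactors = FALSE
  )
  stopifnot(Re(tab$permittivity[tab$name == "tumor"]) >
              Re(tab$permittivity[tab$name == "fibroglandular"]))
  attr(tab, "frequency_hz") <- frequency_hz
  tab
}

# Binary 8-neighborhood erosion.
erode8 <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  out <- m
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      sh <- matrix(FALSE, n, p)
      ri <- max(1L, 1L - di):min(n, n - di)
      rj <- max(1L, 1L - dj):min(p, p - dj)
      sh[ri, rj] <- m[ri + di, rj + dj]
      out <- out & sh
    }
  }
  out
}

# 1D linear-interpolation matrix from an n_in-point grid onto n_out pixel
# centers spanning the same extent.
interp_matrix <- function(n_out, n_in) {
  t <- (seq_len(n_out) - 0.5) / n_out * (n_in - 1) + 1
  i0 <- pmin(floor(t), n_in - 1)
  w <- t - i0
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), i0)] <- 1 - w
  M[cbind(seq_len(n_out), i0 + 1)] <- M[cbind(seq_len(n_out), i0 + 1)] + w
  M
}

# Pixel-center coordinates in cm; rows index i (0-based), columns j.
pixel_coords <- function(grid_n, domain_cm) {
  px <- domain_cm / grid_n
  u <- ((seq_len(grid_n) - 1) + 0.5) * px
  list(u = u, px = px)
}

# Radius function of a harmonically perturbed outline.
outline_radius <- function(theta, r0, amps, phases) {
  pert <- rep(1, length(theta))
  for (k in seq_along(amps)) {
    pert <- pert + amps[k] * cos((k + 1) * theta + phases[k])
  }
  r0 * pert
}

#' Classify breast density from a label map
#'
#' The glandular fraction g = #\{labels 3, 4\} / #\{labels 1..5\} is mapped
#' to one of four density classes by the thresholds (defaults 0.10 / 0.25 /
#' 0.50): class 1 for g < 0.10 up to class 4 for g >= 0.50.
#'
#' @param label_map integer matrix with values in 0..5.
#' @param thresholds increasing cut points of length 3.
#' @return integer density class in 1..4.
#' @export
classify_density <- function(label_map, thresholds = c(0.10, 0.25, 0.50)) {
  support <- sum(label_map >= TISSUE_SKIN)
  if (support == 0L) stop("empty breast support")
  g <- sum(label_map == TISSUE_TRANSITIONAL |
             label_map == TISSUE_FIBROGLANDULAR) / support
  findInterval(g, thresholds) + 1L
}

glandular_fraction <- function(label_map) {
  sum(label_map == TISSUE_TRANSITIONAL | label_map == TISSUE_FIBROGLANDULAR) /
    sum(label_map >= TISSUE_SKIN)
}

#' Assign complex permittivities to a tissue-label map
#'
#' Each pixel receives its class-mean permittivity multiplied by
#' (1 + jitter * u) with u ~ U(-1, 1) drawn per pixel; background pixels get
#' exactly the background value (its jitter is zero by construction).
#'
#' @param label_map integer matrix with values in 0..5.
#' @param table dielectric table from [tissue_dielectric_table()].
#' @param rng_seed integer seed.
#' @return complex matrix of the same shape.
#' @export
assign_dielectrics <- function(label_map, table = tissue_dielectric_table(),
                               rng_seed = 0L) {
  stopifnot(all(label_map %in% 0:5))
  with_seed(rng_seed, {
    eps <- table$permittivity[match(as.vector(label_map), table$class)]
    jit <- table$jitter[match(as.vector(label_map), table$class)]
    u <- stats::runif(length(eps), -1, 1)
    out <- eps * (1 + jit * u)
    matrix(out, nrow(label_map), ncol(label_map))
  })
}

new_breast_phantom <- function(label_map, permittivity_map, density_class,
                               grid_n, domain_cm) {
  structure(list(label_map = label_map,
                 permittivity_map = permittivity_map,
                 density_class = as.integer(density_class),
                 tumor_mask = label_map == TISSUE_TUMOR,
                 pixel_size_cm = domain_cm / grid_n,
                 domain_cm = domain_cm),
            class = "breast_phantom")
}

#' @export
print.breast_phantom <- function(x, ...) {
  cat(sprintf(
    "<breast_phantom> %dx%d (%.3f cm/px), density class %d, glandular fraction %.3f, %d tumor px\n",
    nrow(x$label_map), ncol(x$label_map), x$pixel_size_cm, x$density_class,
    glandular_fraction(x$label_map), sum(x$tumor_mask)))
  invisible(x)
}

# Draw a breast label map (no tumor) targeting glandular fraction g_target.
# Returns NULL when the interior is too small to honor the target.
draw_label_map <- function(params, g_target) {
  n <- params$grid_n
  pc <- pixel_coords(n, params$domain_cm)
  half <- params$domain_cm / 2
  cx <- half + stats::runif(1, -1, 1) * params$center_jitter_cm
  cy <- half + stats::runif(1, -1, 1) * params$center_jitter_cm
  r0 <- stats::runif(1, params$breast_radius_range_cm[1],
                     params$breast_radius_range_cm[2])
  ey <- stats::runif(1, params$ellipticity_range[1], params$ellipticity_range[2])
  amps <- stats::runif(4, -1, 1) * params$outline_harmonic_amp
  phases <- stats::runif(4, 0, 2 * pi)

  U <- matrix(pc$u, n, n)        # row coordinate (cm)
  V <- matrix(pc$u, n, n, byrow = TRUE)
  qx <- U - cx
  qy <- (V - cy) / ey
  rho <- sqrt(qx^2 + qy^2)
  theta <- atan2(qy, qx)
  redge <- outline_radius(theta, r0, amps, phases)
  mask <- rho < redge

  core <- mask
  for (k in seq_len(params$skin_px)) core <- erode8(core)
  if (sum(core) < 400L) return(NULL)

  labels <- matrix(TISSUE_BACKGROUND, n, n)
  labels[mask] <- TISSUE_ADIPOSE
  labels[mask & !core] <- TISSUE_SKIN

  # glandular texture: smoothed Gaussian field plus center bias
  m <- params$coarse_field_n
  M <- interp_matrix(n, m)
  fld <- M %*% matrix(stats::rnorm(m * m), m, m) %*% t(M)
  fld <- fld / stats::sd(fld)
  centrality <- pmax(0, 1 - rho / redge)
  fld <- fld + params$centrality_weight * centrality

  n_support <- sum(mask)
  k_gl <- round(g_target * n_support)
  core_idx <- which(core)
  if (k_gl > length(core_idx) || k_gl < 1L) return(NULL)
  ord <- core_idx[order(fld[core_idx], decreasing = TRUE)]
  gl_idx <- ord[seq_len(k_gl)]
  k_fib <- round((1 - params$transitional_fraction) * k_gl)
  labels[gl_idx] <- TISSUE_TRANSITIONAL
  if (k_fib >= 1L) labels[gl_idx[seq_len(k_fib)]] <- TISSUE_FIBROGLANDULAR
  labels
}

# Rasterize one perturbed-ellipse tumor of equivalent radius r_cm centered at
# pixel (ci, cj); returns the pixel index set (before clipping to tissue).
rasterize_tumor <- function(n, px, ci, cj, r_cm) {
  s <- stats::runif(1, 0.75, 1.3)
  a <- r_cm * s
  b <- r_cm / s
  phi <- stats::runif(1, 0, pi)
  bamp <- stats::runif(2, 0, 0.12)
  bpha <- stats::runif(2, 0, 2 * pi)
  r_px <- ceiling(max(a, b) * 1.35 / px)
  ii <- max(1L, ci - r_px):min(n, ci + r_px)
  jj <- max(1L, cj - r_px):min(n, cj + r_px)
  du <- (ii - ci) * px
  dv <- (jj - cj) * px
  DU <- matrix(du, length(ii), length(jj))
  DV <- matrix(dv, length(ii), length(jj), byrow = TRUE)
  xr <- (DU * cos(phi) + DV * sin(phi)) / a
  yr <- (-DU * sin(phi) + DV * cos(phi)) / b
  rr <- sqrt(xr^2 + yr^2)
  th <- atan2(yr, xr)
  edge <- 1 + bamp[1] * cos(2 * th + bpha[1]) + bamp[2] * cos(3 * th + bpha[2])
  inside <- rr <= edge
  sub <- which(inside, arr.ind = TRUE)
  (jj[sub[, 2]] - 1L) * n + ii[sub[, 1]]
}

#' Insert randomized tumors into a phantom
#'
#' Tumors are perturbed ellipses (harmonic boundary roughening, randomized
#' axis ratio and orientation) with equivalent radii drawn from
#' \code{radius_range_cm}, centered on interior tissue pixels (adipose,
#' transitional or fibro-glandular; never skin or background) and clipped to
#' that interior.  Tumor pixels overwrite previous labels and the
#' permittivity map is re-drawn for the affected pixels.
#'
#' @param phantom a \code{breast_phantom}.
#' @param rng_seed integer seed.
#' @param n_tumors number of tumors to place (>= 1); components may merge.
#' @param radius_range_cm equivalent-radius range, within \[0.2, 1.5\] cm.
#' @param table dielectric table used to re-assign permittivities.
#' @param retry_budget placement attempts per tumor.
#' @return the modified \code{breast_phantom}.
#' @export
insert_tumors <- function(phantom, rng_seed, n_tumors,
                          radius_range_cm = c(0.3, 1.0),
                          table = tissue_dielectric_table(),
                          retry_budget = 50L) {
  stopifnot(n_tumors >= 1L,
            radius_range_cm[1] >= 0.2, radius_range_cm[2] <= 1.5)
  with_seed(rng_seed, {
    labels <- phantom$label_map
    n <- nrow(labels)
    px <- phantom$pixel_size_cm
    interior <- labels == TISSUE_ADIPOSE | labels == TISSUE_TRANSITIONAL |
      labels == TISSUE_FIBROGLANDULAR
    for (t in seq_len(n_tumors)) {
      placed <- FALSE
      for (attempt in seq_len(retry_budget)) {
        r_cm <- stats::runif(1, radius_range_cm[1], radius_range_cm[2])
        cand <- which(interior)
        if (length(cand) == 0L) break
        cpix <- cand[sample.int(length(cand), 1L)]
        ci <- (cpix - 1L) %% n + 1L
        cj <- (cpix - 1L) %/% n + 1L
        pix <- rasterize_tumor(n, px, ci, cj, r_cm)
        pix <- pix[interior[pix] | labels[pix] == TISSUE_TUMOR]
        if (length(pix) >= max(3, 0.5 * pi * (r_cm / px)^2)) {
          labels[pix] <- TISSUE_TUMOR
          interior[pix] <- FALSE
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("tumor placement failed after ", retry_budget,
                        " attempts (interior too small)")
    }
    changed <- labels != phantom$label_map
    eps <- phantom$permittivity_map
    eps_new <- assign_dielectrics(labels, table,
                                  rng_seed = sample.int(2147483646L, 1L))
    eps[changed] <- eps_new[changed]
    out <- phantom
    out$label_map <- labels
    out$permittivity_map <- eps
    out$tumor_mask <- labels == TISSUE_TUMOR
    out
  })
}

#' Generate a randomized breast phantom
#'
#' Draws a breast outline, fills it with a skin rim, adipose tissue and a
#' glandular complex whose pixel count is chosen so the glandular fraction
#' lands in the band of \code{density_class}, optionally inserts tumors,
#' and assigns jittered complex permittivities.  Rejection sampling (with a
#' documented retry budget) guarantees that the returned phantom's measured
#' density class equals the requested one even after tumor insertion.
#' Identical seed and parameters give a bit-identical phantom.
#'
#' @param rng_seed integer seed.
#' @param density_class requested class in 1..4.
#' @param with_tumor logical; if TRUE, 1-3 tumors are inserted (count drawn
#'   from \code{params$tumor_count_probs}).
#' @param params generator parameters from [phantom_params()].
#' @param table dielectric table from [tissue_dielectric_table()].
#' @return a \code{breast_phantom}.
#' @export
generate_phantom <- function(rng_seed, density_class, with_tumor = FALSE,
                             params = phantom_params(),
                             table = tissue_dielectric_table()) {
  stopifnot(density_class %in% 1:4)
  with_seed(rng_seed, {
    band <- params$class_target_bands[[density_class]]
    for (attempt in seq_len(params$retry_budget)) {
      g_target <- stats::runif(1, band[1], band[2])
      labels <- draw_label_map(params, g_target)
      if (is.null(labels)) next
      eps <- assign_dielectrics(labels, table,
                                rng_seed = sample.int(2147483646L, 1L))
      ph <- new_breast_phantom(labels, eps, density_class,
                               params$grid_n, params$domain_cm)
      if (with_tumor) {
        n_t <- sample.int(length(params$tumor_count_probs), 1L,
                          prob = params$tumor_count_probs)
        ph <- tryCatch(
          insert_tumors(ph, rng_seed = sample.int(2147483646L, 1L),
                        n_tumors = n_t,
                        radius_range_cm = params$tumor_radius_range_cm,
                        table = table),
          error = function(e) NULL)
        if (is.null(ph)) next
      }
      if (classify_density(ph$label_map, params$density_thresholds) ==
          density_class) {
        ph$density_class <- as.integer(density_class)
        return(ph)
      }
    }
    stop("phantom generation failed after ", params$retry_budget,
         " attempts for density class ", density_class)
  })
}
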