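# Balanced phantom + scattering-matrix dataset generation.
#
# Profiles are evenly distributed over the four density classes and mixed
# 1:1 healthy:tumorous (configurable), with a stratified train/val/test
# split.  Everything is derived deterministically from one seed.

#' Generate a balanced microwave-imaging dataset
#'
#' Generates \code{n_profiles} breast phantoms (balanced over the four
#' density classes and, within each class, over healthy/tumorous states),
#' solves the forward problem for each on \code{solver_grid}, and assigns a
#' stratified train/validation/test split.  The manifest records every
#' parameter plus the training-set standardization scale (global standard
#' deviation of |S|) used by the network.
#'
#' @param n_profiles total number of profiles; must allow exact class/health
#'   balance (divisible by 8 at the default healthy fraction).
#' @param healthy_fraction fraction of healthy profiles per class.
#' @param split train/validation/test fractions summing to 1.
#' @param seed master seed; all per-record seeds derive from it.
#' @param solver_grid MoM grid (divisor of 108; default 54).
#' @param array antenna geometry from [antenna_array()].
#' @param params phantom generator parameters.
#' @param table dielectric table.
#' @param noise_snr_db if non-NULL, additive white Gaussian noise at this
#'   SNR (dB, relative to the per-matrix RMS) is applied to the scattering
#'   matrices; the default is noiseless.
#' @param out_path optional path; the dataset is saved as RDS with a JSON
#'   manifest alongside.
#' @param verbose print progress.
#' @return an \code{mwi_dataset}: label maps, tumor masks, scattering
#'   matrices, density classes, health states, split assignment, manifest.
#' @export
generate_dataset <- function(n_profiles, healthy_fraction = 0.5,
                             split = c(0.8, 0.1, 0.1), seed = 1L,
                             solver_grid = 54L, array = antenna_array(),
                             params = phantom_params(),
                             table = tissue_dielectric_table(array$frequency_hz),
                             noise_snr_db = NULL,
                             out_path = NULL, verbose = FALSE) {
  stopifnot(abs(sum(split) - 1) < 1e-9, n_profiles >= 8L)
  if (n_profiles %% 4L != 0L) stop("n_profiles must be divisible by 4")
  n_class <- n_profiles %/% 4L
  n_healthy <- healthy_fraction * n_class
  if (abs(n_healthy - round(n_healthy)) > 1e-9) {
    stop("infeasible balance: healthy_fraction * n_profiles / 4 must be integral")
  }
  n_healthy <- as.integer(round(n_healthy))

  grid_n <- params$grid_n
  cells <- expand.grid(class = 1:4, healthy = c(TRUE, FALSE))
  plan <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    m <- if (cells$healthy[r]) n_healthy else n_class - n_healthy
    if (m == 0L) return(NULL)
    data.frame(class = cells$class[r], healthy = cells$healthy[r],
               cell_idx = seq_len(m))
  }))
  n <- nrow(plan)
  stopifnot(n == n_profiles)

  # stratified split: floor-allocate within each (class, health) cell, then
  # hand out the leftover slots deterministically so the global totals equal
  # round(split * n) exactly while every cell stays balanced within one
  # record per split
  plan$split <- NA_character_
  cell_rows <- lapply(seq_len(nrow(cells)), function(r) {
    which(plan$class == cells$class[r] & plan$healthy == cells$healthy[r])
  })
  cell_rows <- cell_rows[lengths(cell_rows) > 0L]
  m_c <- lengths(cell_rows)
  alloc <- vapply(m_c, function(m) floor(split[1:2] * m), numeric(2))
  alloc <- rbind(alloc, m_c - colSums(alloc))      # rows: train, val, test
  targets <- c(round(split[1] * n), round(split[2] * n))
  targets <- c(targets, n - sum(targets))
  for (k in 1:2) {                                 # top up train, then val
    short <- targets[k] - sum(alloc[k, ])
    while (short > 0L && any(alloc[3L, ] > 0L)) {
      for (c in which(alloc[3L, ] > 0L)) {
        if (short <= 0L) break
        alloc[k, c] <- alloc[k, c] + 1L
        alloc[3L, c] <- alloc[3L, c] - 1L
        short <- short - 1L
      }
    }
  }
  for (c in seq_along(cell_rows)) {
    rows <- cell_rows[[c]]
    lab <- rep(c("train", "val", "test"), times = alloc[, c])
    perm <- with_seed(derive_seed(seed, paste0("split_", c)),
                      sample.int(length(rows)))
    plan$split[rows] <- lab[order(perm)]
  }

  labels <- array(0L, dim = c(grid_n, grid_n, n))
  tumor_mask <- array(FALSE, dim = c(grid_n, grid_n, n))
  na <- array$n_antennas
  smat <- array(0 + 0i, dim = c(na, na, n))
  mom_operator(array, solver_grid)   # warm the geometry cache once

  for (i in seq_len(n)) {
    ph_seed <- derive_seed(seed, sprintf("phantom_%d_%d_%d", plan$class[i],
                                         plan$healthy[i], plan$cell_idx[i]))
    ph <- generate_phantom(ph_seed, plan$class[i],
                           with_tumor = !plan$healthy[i],
                           params = params, table = table)
    labels[, , i] <- ph$label_map
    tumor_mask[, , i] <- ph$tumor_mask
    chi <- build_contrast(ph, array, solver_grid)
    S <- solve_forward(chi, array)$values
    if (!is.null(noise_snr_db)) {
      S <- S + with_seed(derive_seed(seed, paste0("noise_", i)), {
        sigma <- sqrt(mean(Mod(S)^2)) * 10^(-noise_snr_db / 20) / sqrt(2)
        matrix(complex(real = stats::rnorm(na * na, sd = sigma),
                       imaginary = stats::rnorm(na * na, sd = sigma)), na, na)
      })
    }
    smat[, , i] <- S
    if (verbose && i %% 100L == 0L) {
      message("  generated ", i, "/", n, " profiles")
    }
  }

  train_idx <- which(plan$split == "train")
  scale_idx <- if (length(train_idx) > 0L) train_idx else seq_len(n)
  smatrix_scale <- stats::sd(Mod(smat[, , scale_idx]))

  manifest <- list(
    version = "0.1.0",
    seed = seed,
    n_profiles = n_profiles,
    healthy_fraction = healthy_fraction,
    split_fractions = split,
    solver_grid = as.integer(solver_grid),
    grid_n = grid_n,
    pixel_size_cm = params$domain_cm / grid_n,
    frequency_hz = array$frequency_hz,
    n_antennas = array$n_antennas,
    ring_radius_cm = array$ring_radius_cm,
    background_permittivity = array$background_permittivity,
    noise_snr_db = noise_snr_db,
    smatrix_scale = smatrix_scale,
    dielectric_table = data.frame(class = table$class, name = table$name,
                                  eps_real = Re(table$permittivity),
                                  eps_imag = Im(table$permittivity),
                                  jitter = table$jitter),
    phantom_params = params[setdiff(names(params), "class_target_bands")],
    split_counts = as.list(table(plan$split))
  )

  ds <- structure(list(labels = labels, tumor_mask = tumor_mask,
                       smatrix = smat,
                       density_class = as.integer(plan$class),
                       healthy = plan$healthy,
                       split = plan$split,
                       manifest = manifest),
                  class = "mwi_dataset")
  if (!is.null(out_path)) write_dataset(ds, out_path)
  ds
}

#' @export
print.mwi_dataset <- function(x, ...) {
  cat(sprintf(
    "<mwi_dataset> %d profiles (%d healthy / %d tumorous), grid %d, solver %d, splits %s\n",
    length(x$healthy), sum(x$healthy), sum(!x$healthy),
    x$manifest$grid_n, x$manifest$solver_grid,
    paste(names(table(x$split)), table(x$split), sep = ":", collapse = " ")))
  invisible(x)
}

#' Save a dataset with its JSON manifest
#'
#' @param dataset an \code{mwi_dataset}.
#' @param path RDS output path; the manifest is written to
#'   \code{paste0(path, ".manifest.json")}.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  jsonlite::write_json(dataset$manifest,
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a dataset saved by [write_dataset()]
#' @param path RDS path.
#' @return the \code{mwi_dataset}.
#' @export
read_dataset <- function(path) readRDS(path)

#' Deterministic checksum of any R object
#'
#' MD5 of the object's serialized bytes; used to verify that re-running a
#' pipeline stage with the same seed reproduces its artifacts bit-exactly.
#'
#' @param x any serializable object.
#' @return character MD5 digest.
#' @export
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}
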