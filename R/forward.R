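# Method-of-moments forward solver for 2D TM-z scattering.
#
# Conventions (used consistently everywhere): time factor exp(+j omega t),
# outgoing waves are Hankel functions of the second kind, lossy permittivity
# has negative imaginary part, lengths in cm.  Transmitters are unit-strength
# line sources, so the incident field of antenna t is H0^(2)(k_b |r - r_t|).
#
# Discretization: pulse basis / point matching on square cells with the
# closed-form equivalent-circle self term (Richmond's rule).  For cell radius
# a and background wavenumber k:
#   off-diagonal coupling  C(rho) = (-j pi k a / 2) J1(ka) H0^(2)(k rho)
#   self term              C_self = (-j pi k a / 2) H1^(2)(ka) - 1
# and the linear system (I - C diag(chi)) E = E_inc is solved on the cells
# with nonzero contrast; the scattered field at receiver r is
# sum_n chi_n C(rho_rn) E_n.

SPEED_OF_LIGHT_CM_S <- 2.99792458e10

hankel2 <- function(x, nu = 0) {
  out <- complex(real = besselJ(x, nu), imaginary = -besselY(x, nu))
  dim(out) <- dim(x)
  out
}

#' Antenna ring geometry for the multi-view multi-static acquisition
#'
#' Antennas are evenly spaced on a circle enclosing the imaging domain; each
#' antenna transmits in turn while all antennas receive, giving an
#' n_antennas x n_antennas complex scattering matrix per phantom.
#'
#' @param n_antennas number of antennas (default 30).
#' @param ring_radius_cm ring radius from the domain center (default 9 cm,
#'   circumscribing the 15x15 cm slice).
#' @param center domain center in cm.
#' @param frequency_hz operating frequency (default 1 GHz).
#' @param background_permittivity relative permittivity of the lossless
#'   immersion medium (real; default 10).
#' @return an \code{antenna_array} object.
#' @export
antenna_array <- function(n_antennas = 30L, ring_radius_cm = 9,
                          center = c(7.5, 7.5), frequency_hz = 1e9,
                          background_permittivity = 10) {
  stopifnot(n_antennas >= 3L, Im(background_permittivity) == 0)
  ang <- 2 * pi * (seq_len(n_antennas) - 1L) / n_antennas
  structure(list(n_antennas = as.integer(n_antennas),
                 ring_radius_cm = ring_radius_cm,
                 center = center,
                 frequency_hz = frequency_hz,
                 background_permittivity = Re(background_permittivity),
                 x = center[1] + ring_radius_cm * cos(ang),
                 y = center[2] + ring_radius_cm * sin(ang)),
            class = "antenna_array")
}

background_wavenumber <- function(array) {
  2 * pi * array$frequency_hz * sqrt(array$background_permittivity) /
    SPEED_OF_LIGHT_CM_S
}

.mom_cache <- new.env(parent = emptyenv())

# Precomputed geometry-dependent quantities for a solver grid: the Green
# coupling table over all lattice offsets, receiver couplings and incident
# fields for every cell.  Cached, since they are shared by every phantom
# solved with the same geometry.
mom_operator <- function(array, solver_grid, domain_cm = 15) {
  key <- paste(array$n_antennas, array$ring_radius_cm, array$frequency_hz,
               array$background_permittivity, solver_grid, domain_cm,
               sep = "_")
  hit <- .mom_cache[[key]]
  if (!is.null(hit)) return(hit)

  g <- as.integer(solver_grid)
  d <- domain_cm / g
  a <- d / sqrt(pi)                    # equivalent-circle cell radius
  k <- background_wavenumber(array)
  coup <- function(rho) {
    (-0.5i * pi * k * a) * besselJ(k * a, 1) * hankel2(k * rho, 0)
  }
  u <- ((seq_len(g) - 1) + 0.5) * d
  cx <- matrix(u, g, g)
  cy <- matrix(u, g, g, byrow = TRUE)

  # coupling by lattice offset (delta_i, delta_j); center entry = self term
  off <- d * (-(g - 1L):(g - 1L))
  DI <- matrix(off, 2L * g - 1L, 2L * g - 1L)
  DJ <- matrix(off, 2L * g - 1L, 2L * g - 1L, byrow = TRUE)
  RHO <- sqrt(DI^2 + DJ^2)
  Gtable <- matrix(0 + 0i, 2L * g - 1L, 2L * g - 1L)
  nz <- RHO > 0
  Gtable[nz] <- coup(RHO[nz])
  Gtable[g, g] <- (-0.5i * pi * k * a) * hankel2(k * a, 1) - 1

  # receiver-to-cell couplings and incident fields (unit line sources)
  Rrc <- sqrt(outer(array$x, as.vector(cx), "-")^2 +
                outer(array$y, as.vector(cy), "-")^2)
  Crx <- coup(Rrc)
  Einc <- t(hankel2(k * Rrc, 0))

  op <- list(grid_n = g, cell_cm = d, k = k, Gtable = Gtable,
             Crx = Crx, Einc = Einc, array = array, domain_cm = domain_cm)
  .mom_cache[[key]] <- op
  op
}

#' Contrast function on the solver grid
#'
#' Block-averages a 108x108 complex permittivity map down to the solver grid
#' and forms the contrast chi(r) = eps(r)/eps_b - 1.  Cells fully outside the
#' breast average to the background permittivity and therefore have exactly
#' zero contrast; boundary cells get area-weighted intermediate values.
#'
#' @param phantom a \code{breast_phantom}, or a complex permittivity matrix.
#' @param array the \code{antenna_array} (supplies the background medium).
#' @param solver_grid target grid size; must divide the map size.
#' @return complex \code{solver_grid} x \code{solver_grid} contrast matrix.
#' @export
build_contrast <- function(phantom, array, solver_grid) {
  eps <- if (inherits(phantom, "breast_phantom")) phantom$permittivity_map
  else phantom
  n <- nrow(eps)
  g <- as.integer(solver_grid)
  if (n %% g != 0L) {
    stop("solver_grid (", g, ") must divide the permittivity grid (", n, ")")
  }
  f <- n %/% g
  if (f > 1L) {
    A <- array(eps, dim = c(f, g, f, g))
    eps <- colMeans(aperm(A, c(1, 3, 2, 4)), dims = 2)
  }
  eps / array$background_permittivity - 1
}

#' Solve the forward scattering problem
#'
#' Assembles the MoM system on the cells with nonzero contrast, solves it for
#' all transmitters at once (dense LU), and evaluates the scattered field at
#' every receiver, giving the full multi-view multi-static scattering matrix
#' S\[r, t\] = scattered field at receiver r when antenna t transmits.
#'
#' @param contrast complex contrast matrix from [build_contrast()].
#' @param array the \code{antenna_array}.
#' @param domain_cm physical side length of the imaging domain.
#' @return a \code{scattering_matrix} object.
#' @export
solve_forward <- function(contrast, array, domain_cm = 15) {
  g <- nrow(contrast)
  op <- mom_operator(array, g, domain_cm)
  chi <- as.vector(contrast)
  idx <- which(Mod(chi) > 0)
  na <- array$n_antennas
  if (length(idx) == 0L) {
    S <- matrix(0 + 0i, na, na)
  } else {
    N <- length(idx)
    ri <- (idx - 1L) %% g
    ci <- (idx - 1L) %/% g
    lin <- outer(ri, ri, "-") + g + (outer(ci, ci, "-") + g - 1L) * (2L * g - 1L)
    A <- -matrix(op$Gtable[lin], N, N) * rep(chi[idx], each = N)
    diag(A) <- diag(A) + 1
    Et <- tryCatch(solve(A, op$Einc[idx, , drop = FALSE]),
                   error = function(e) {
                     stop("MoM system solve failed (",
                          conditionMessage(e), "); the system may be singular")
                   })
    S <- op$Crx[, idx, drop = FALSE] %*% (chi[idx] * Et)
  }
  structure(list(values = S, frequency_hz = array$frequency_hz,
                 array = array),
            class = "scattering_matrix")
}

#' @export
print.scattering_matrix <- function(x, ...) {
  cat(sprintf("<scattering_matrix> %dx%d complex, f = %.3g GHz, |S| rms = %.3g\n",
              nrow(x$values), ncol(x$values), x$frequency_hz / 1e9,
              sqrt(mean(Mod(x$values)^2))))
  invisible(x)
}

#' Pad a scattering matrix into the network input tensor
#'
#' Splits the complex matrix into real and imaginary channels, optionally
#' divides both by a dataset-level standardization scale, and pads each
#' channel with one ring of zeros (30x30 -> 32x32) for U-Net compatibility.
#'
#' @param S a \code{scattering_matrix} or a complex matrix.
#' @param scale standardization divisor (the training-set global standard
#'   deviation of |S|); 1 leaves values unscaled.
#' @return numeric array (n+2) x (n+2) x 2; channel 1 real, channel 2
#'   imaginary; border exactly zero.
#' @export
pad_smatrix <- function(S, scale = 1) {
  v <- if (inherits(S, "scattering_matrix")) S$values else S
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  n <- nrow(v)
  out <- array(0, dim = c(n + 2L, n + 2L, 2L))
  out[2:(n + 1L), 2:(n + 1L), 1L] <- Re(v) / scale
  out[2:(n + 1L), 2:(n + 1L), 2L] <- Im(v) / scale
  out
}

#' Crop a padded input tensor back to the complex scattering matrix
#'
#' Inverse of [pad_smatrix()] (up to the standardization scale).
#'
#' @param x array (n+2) x (n+2) x 2.
#' @param scale the scale used when padding.
#' @return complex n x n matrix.
#' @export
crop_padded <- function(x, scale = 1) {
  n <- dim(x)[1] - 2L
  (x[2:(n + 1L), 2:(n + 1L), 1L] +
     1i * x[2:(n + 1L), 2:(n + 1L), 2L]) * scale
}

#' Uniform dielectric cylinder permittivity map
#'
#' Rasterizes a homogeneous circular cylinder onto the pixel grid with
#' subpixel area weighting (permittivity mixes linearly by area), the
#' standard benchmark object for validating the MoM solver against the
#' analytic Mie series.
#'
#' @param grid_n raster size.
#' @param radius_cm cylinder radius.
#' @param eps_interior complex relative permittivity inside.
#' @param eps_background background relative permittivity.
#' @param center cylinder center in cm.
#' @param domain_cm domain side length.
#' @param supersample subpixel sampling factor per axis for area fractions.
#' @return complex \code{grid_n} x \code{grid_n} permittivity matrix.
#' @export
cylinder_permittivity <- function(grid_n = 108L, radius_cm = 2.5,
                                  eps_interior, eps_background,
                                  center = c(7.5, 7.5), domain_cm = 15,
                                  supersample = 4L) {
  n <- grid_n * supersample
  px <- domain_cm / n
  u <- ((seq_len(n) - 1) + 0.5) * px
  inside <- outer((u - center[1])^2, (u - center[2])^2, "+") <= radius_cm^2
  A <- array(inside, dim = c(supersample, grid_n, supersample, grid_n))
  cov <- colMeans(aperm(A, c(1, 3, 2, 4)), dims = 2)
  eps_background + (eps_interior - eps_background) * cov
}
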