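# Analytic eigenfunction (Mie-type) series for scattering of a line source
# by a homogeneous dielectric circular cylinder: the independent oracle used
# to validate the MoM solver.  Same conventions as the solver: exp(+j omega t),
# outgoing Hankel functions of the second kind, unit line-source incident
# field H0^(2)(k_b |r - r_s|).  Restricted to lossless (real) permittivities,
# which is all the validation geometry needs.

besselJd <- function(x, nu) {
  if (nu == 0) -besselJ(x, 1) else besselJ(x, nu - 1) - nu / x * besselJ(x, nu)
}

hankel2d <- function(x, nu) {
  h <- function(n) hankel2(x, n)
  if (nu == 0) -h(1) else h(nu - 1) - nu / x * h(nu)
}

# Modal scattering coefficient c_n of the dielectric cylinder (TM-z).
mie_coefficient <- function(n, k_b, k_i, radius_cm) {
  xb <- k_b * radius_cm
  xi <- k_i * radius_cm
  num <- k_i * besselJd(xi, n) * besselJ(xb, n) -
    k_b * besselJ(xi, n) * besselJd(xb, n)
  den <- k_b * besselJ(xi, n) * hankel2d(xb, n) -
    k_i * besselJd(xi, n) * hankel2(xb, n)
  num / den
}

#' Scattered field of a dielectric cylinder illuminated by a line source
#'
#' Exact eigenfunction series for a homogeneous circular cylinder centered at
#' \code{center}: the scattered field at \code{obs_pos} due to a unit line
#' source at \code{source_pos}, both outside the cylinder.  Serves as the
#' analytic oracle for the MoM solver.
#'
#' @param radius_cm cylinder radius.
#' @param eps_rel_interior real relative permittivity inside the cylinder.
#' @param eps_rel_background real background relative permittivity.
#' @param frequency_hz operating frequency.
#' @param source_pos,obs_pos 2-vectors (cm).
#' @param center cylinder center (cm).
#' @param n_terms number of azimuthal orders; default \code{ceil(k_i R) + 15}.
#' @param tol convergence requirement on the last term relative to the
#'   partial sum.
#' @return complex scalar scattered field.
#' @export
mie_cylinder_scattered_field <- function(radius_cm, eps_rel_interior,
                                         eps_rel_background, frequency_hz,
                                         source_pos, obs_pos,
                                         center = c(7.5, 7.5),
                                         n_terms = NULL, tol = 1e-12) {
  stopifnot(Im(eps_rel_interior) == 0, Im(eps_rel_background) == 0)
  k_b <- 2 * pi * frequency_hz * sqrt(eps_rel_background) / SPEED_OF_LIGHT_CM_S
  k_i <- 2 * pi * frequency_hz * sqrt(eps_rel_interior) / SPEED_OF_LIGHT_CM_S
  if (is.null(n_terms)) n_terms <- ceiling(k_i * radius_cm) + 15L

  ds <- source_pos - center
  do <- obs_pos - center
  rho_s <- sqrt(sum(ds^2))
  rho_o <- sqrt(sum(do^2))
  stopifnot(rho_s > radius_cm, rho_o > radius_cm)
  dphi <- atan2(do[2], do[1]) - atan2(ds[2], ds[1])

  total <- 0 + 0i
  last <- Inf
  for (n in 0:n_terms) {
    cn <- mie_coefficient(n, k_b, k_i, radius_cm)
    term <- cn * hankel2(k_b * rho_o, n) * hankel2(k_b * rho_s, n) *
      cos(n * dphi)
    if (n > 0) term <- 2 * term
    total <- total + term
    last <- Mod(term)
  }
  if (is.finite(Mod(total)) && Mod(total) > 0 && last > tol * Mod(total) &&
      last > tol) {
    stop("Mie series did not converge in ", n_terms,
         " terms (last term ", signif(last, 3), ")")
  }
  total
}

#' Full Mie-series scattering matrix for a centered cylinder
#'
#' Evaluates [mie_cylinder_scattered_field()] for every transmitter-receiver
#' pair of an antenna array.
#'
#' @param radius_cm cylinder radius.
#' @param eps_rel_interior,eps_rel_background real relative permittivities.
#' @param array an [antenna_array()].
#' @param center cylinder center (cm).
#' @param n_terms series length override.
#' @return complex n_antennas x n_antennas matrix (receivers x transmitters).
#' @export
mie_smatrix <- function(radius_cm, eps_rel_interior, eps_rel_background,
                        array, center = array$center, n_terms = NULL) {
  na <- array$n_antennas
  S <- matrix(0 + 0i, na, na)
  for (t in seq_len(na)) {
    for (r in seq_len(na)) {
      S[r, t] <- mie_cylinder_scattered_field(
        radius_cm, eps_rel_interior, eps_rel_background, array$frequency_hz,
        source_pos = c(array$x[t], array$y[t]),
        obs_pos = c(array$x[r], array$y[r]),
        center = center, n_terms = n_terms)
    }
  }
  S
}
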