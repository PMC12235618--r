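## Orientation-dependent frequency algebra for the Gd(III) central transition.
## Units: Hz (cyclic frequency) and seconds internally; angles are degrees at
## every interface and converted to radians on entry.

deg2rad <- function(x) x * pi / 180

#' Perpendicular dipolar hyperfine coupling from distance
#'
#' Point-dipole coupling constant |a_perp| = mu0 ge muB gn muN / (4 pi h r^3),
#' in cyclic-frequency units (Hz). For a 19F nucleus 10-13.3 Angstrom from
#' Gd(III) this evaluates to roughly 30-74 kHz.
#'
#' @param r Electron-nucleus distance (Angstrom, > 0). Vectorised.
#' @param nucleus A [nucleus_spec()].
#' @param ge Electron g-value; default 1.992 (Gd(III)).
#' @return Coupling |a_perp| in Hz.
#' @examples
#' a_perp_from_distance(13.3)  # ~31.5 kHz
#' @export
a_perp_from_distance <- function(r, nucleus = nucleus_spec("19F"), ge = 1.992) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("distance r must be positive and finite", call. = FALSE)
  }
  k <- physical_constants()
  r_m <- r * 1e-10
  k$mu0 * ge * k$muB * nucleus$gn * k$muN / (4 * pi * k$h * r_m^3)
}

#' Orientation-dependent dipolar splitting
#'
#' a(theta) = (3 cos^2 theta - 1) |a_perp|: +2 a_perp along the
#' electron-nucleus vector, -a_perp perpendicular to it, zero at the magic
#' angle 54.74 degrees.
#'
#' @param theta Angle between the field and the electron-nucleus vector
#'   (degrees). Vectorised.
#' @param a_perp Perpendicular coupling (Hz, >= 0).
#' @return Signed splitting a (Hz).
#' @export
dipolar_coupling <- function(theta, a_perp) {
  stopifnot(all(a_perp >= 0))
  (3 * cos(deg2rad(theta))^2 - 1) * a_perp
}

#' Cosine of the dipolar angle from frame orientations
#'
#' Dot product between the field direction (polar `xi`, azimuthal `phi` in the
#' chemical-shift frame) and the Gd-F unit vector (polar `gamma`, azimuthal
#' `rho` in the same frame):
#' cos(theta) = cos(rho) sin(gamma) cos(phi) sin(xi)
#'            + sin(rho) sin(gamma) sin(phi) sin(xi) + cos(gamma) cos(xi).
#'
#' @param orientation An [orientation()] (fields `xi`, `phi`, degrees);
#'   vector fields allowed.
#' @param gamma,rho Gd-F vector angles in the CS frame (degrees).
#' @return cos(theta), in \[-1, 1\].
#' @export
cos_theta <- function(orientation, gamma, rho) {
  xi <- deg2rad(orientation$xi)
  phi <- deg2rad(orientation$phi)
  g <- deg2rad(gamma)
  r <- deg2rad(rho)
  ct <- cos(r) * sin(g) * cos(phi) * sin(xi) +
    sin(r) * sin(g) * sin(phi) * sin(xi) +
    cos(g) * cos(xi)
  pmin(1, pmax(-1, ct))
}

#' Effective chemical shift along a field direction
#'
#' Secular orientation dependence of the anisotropic shift,
#' delta_eff = dxx (cos phi sin xi)^2 + dyy (sin phi sin xi)^2
#'           + dzz cos^2 xi (ppm),
#' i.e. the quadratic form of the traceless tensor in the squared direction
#' cosines of the field. Its uniform average over the sphere vanishes.
#'
#' @param orientation An [orientation()]; vector fields allowed.
#' @param tensor A [cs_tensor()].
#' @return Effective shift (ppm), bounded by the principal values.
#' @export
delta_eff <- function(orientation, tensor) {
  xi <- deg2rad(orientation$xi)
  phi <- deg2rad(orientation$phi)
  sx <- sin(xi)
  tensor$dxx * (cos(phi) * sx)^2 +
    tensor$dyy * (sin(phi) * sx)^2 +
    tensor$dzz * cos(xi)^2
}

#' Chemically shifted nuclear Larmor frequency
#'
#' nu_I = nu_ref (1 + delta * 1e-6), with delta in ppm.
#'
#' @param nu_ref Reference Larmor frequency (Hz, > 0).
#' @param delta Effective chemical shift (ppm). Vectorised.
#' @return Shifted Larmor frequency (Hz).
#' @export
larmor_shifted <- function(nu_ref, delta) {
  stopifnot(all(nu_ref > 0))
  nu_ref * (1 + delta * 1e-6)
}

#' Central-transition ENDOR frequency pair
#'
#' For the mS = -1/2 <-> +1/2 transition the two ENDOR branches sit at
#' nu_I -/+ a/2; their mean is nu_I and their difference is the splitting a.
#'
#' @param nu_I Nuclear Larmor frequency (Hz, > 0). Vectorised.
#' @param a Hyperfine splitting (Hz, signed).
#' @return A list with elements `low` = nu_I - a/2 and `high` = nu_I + a/2.
#' @export
endor_frequencies <- function(nu_I, a) {
  stopifnot(all(nu_I > 0))
  list(low = nu_I - a / 2, high = nu_I + a / 2)
}
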