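#' Physical constants (CODATA 2018)
#'
#' Returns the four fundamental constants entering the point-dipole hyperfine
#' coupling, as an immutable named list in SI units.
#'
#' @return A list of class `physical_constants` with elements
#'   `mu0` (vacuum magnetic permeability, T m/A), `muB` (Bohr magneton, J/T),
#'   `muN` (nuclear magneton, J/T) and `h` (Planck constant, J s).
#' @examples
#' physical_constants()$h
#' @export
physical_constants <- function() {
  structure(
    list(
      mu0 = 1.25663706212e-6,
      muB = 9.2740100783e-24,
      muN = 5.0507837461e-27,
      h   = 6.62607015e-34
    ),
    class = "physical_constants"
  )
}

#' Nucleus specification
#'
#' Bundles the nuclear g-factor and the reference Larmor frequency at the
#' working field. The built-in presets are the W-band (3.40 T) values for the
#' two nuclei of interest: 136.4 MHz for 19F and 144.9 MHz for 1H.
#'
#' @param label Isotope name. `"19F"` and `"1H"` are recognised presets; any
#'   other label requires `gn` and `larmor_ref` to be given explicitly.
#' @param gn Nuclear g-factor (dimensionless, > 0).
#' @param larmor_ref Reference Larmor frequency nu_I0 at the working field (Hz).
#' @return An object of class `nucleus_spec`.
#' @examples
#' nucleus_spec("19F")
#' nucleus_spec("1H")
#' @export
nucleus_spec <- function(label, gn = NULL, larmor_ref = NULL) {
  presets <- list(
    `19F` = list(gn = 5.257736,     larmor_ref = 136.4e6),
    `1H`  = list(gn = 5.5856946893, larmor_ref = 144.9e6)
  )
  if (is.null(gn) || is.null(larmor_ref)) {
    p <- presets[[label]]
    if (is.null(p)) {
      stop("unknown nucleus '", label,
           "'; supply gn and larmor_ref explicitly", call. = FALSE)
    }
    if (is.null(gn)) gn <- p$gn
    if (is.null(larmor_ref)) larmor_ref <- p$larmor_ref
  }
  stopifnot(is.numeric(gn), length(gn) == 1L, gn > 0,
            is.numeric(larmor_ref), length(larmor_ref) == 1L, larmor_ref > 0)
  structure(list(label = label, gn = gn, larmor_ref = larmor_ref),
            class = "nucleus_spec")
}

#' Electron-nucleus spin system
#'
#' Describes a Gd(III)-like paramagnetic centre dipolar-coupled to a single
#' nucleus at distance `r_GdF`. The default electron g-value 1.992 is the
#' Gd(III) value appropriate for the central transition, not the free-electron
#' 2.0023; the ~1% difference propagates directly into the distance calibration.
#'
#' @param r_GdF Electron-nucleus distance (Angstrom, > 0).
#' @param nucleus A [nucleus_spec()]; default 19F.
#' @param S Electron spin quantum number; one of 1/2, 3/2, 5/2, 7/2.
#' @param ge Electron g-value (dimensionless).
#' @return An object of class `spin_system`.
#' @examples
#' spin_system(r_GdF = 13.3)
#' @export
spin_system <- function(r_GdF, nucleus = nucleus_spec("19F"),
                        S = 7 / 2, ge = 1.992) {
  stopifnot(inherits(nucleus, "nucleus_spec"))
  if (!is.numeric(r_GdF) || length(r_GdF) != 1L || !is.finite(r_GdF) ||
      r_GdF <= 0) {
    stop("r_GdF must be a positive finite distance in Angstrom", call. = FALSE)
  }
  if (!isTRUE(S %in% c(1 / 2, 3 / 2, 5 / 2, 7 / 2))) {
    stop("S must be one of 1/2, 3/2, 5/2, 7/2", call. = FALSE)
  }
  stopifnot(is.numeric(ge), length(ge) == 1L, ge > 0)
  structure(list(S = S, ge = ge, nucleus = nucleus, r_GdF = r_GdF),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> S = %s/2, ge = %.4f, nucleus = %s, r = %.2f A\n",
              format(2 * x$S), x$ge, x$nucleus$label, x$r_GdF))
  invisible(x)
}

#' Anisotropic chemical-shift tensor with Gd-F vector orientation
#'
#' The traceless (anisotropic) part of the nuclear chemical-shift tensor,
#' given by its principal values in ppm, together with the orientation of the
#' electron-nucleus vector in the tensor principal-axis frame: `gamma` is the
#' polar and `rho` the azimuthal angle, both restricted to the canonical
#' octant \[0, 90\] degrees (the quadratic forms involved are invariant under
#' inversion and axis reflections, so this octant covers all distinguishable
#' orientations).
#'
#' @param dxx,dyy,dzz Principal values of the anisotropic shift (ppm); must
#'   sum to zero within 1e-9.
#' @param gamma Polar angle of the Gd-F vector in the CS frame (degrees,
#'   0-90).
#' @param rho Azimuthal angle (degrees, 0-90).
#' @return An object of class `cs_tensor`.
#' @examples
#' cs_tensor(98, -29, -69, gamma = 57, rho = 75)  # fluorobenzene-like 19F
#' @export
cs_tensor <- function(dxx, dyy, dzz, gamma, rho) {
  stopifnot(is.numeric(dxx), is.numeric(dyy), is.numeric(dzz),
            is.numeric(gamma), is.numeric(rho))
  if (abs(dxx + dyy + dzz) > 1e-9) {
    stop("anisotropic CS tensor must be traceless: dxx + dyy + dzz = ",
         format(dxx + dyy + dzz), call. = FALSE)
  }
  if (gamma < 0 || gamma > 90 || rho < 0 || rho > 90) {
    stop("gamma and rho must lie in the canonical octant [0, 90] degrees",
         call. = FALSE)
  }
  structure(list(dxx = dxx, dyy = dyy, dzz = dzz, gamma = gamma, rho = rho),
            class = "cs_tensor")
}

#' Magnetic-field orientation in the chemical-shift frame
#'
#' @param xi Polar angle of the field in the CS frame (degrees, 0-180).
#' @param phi Azimuthal angle (degrees, in \[0, 360)).
#' @return An object of class `orientation`.
#' @export
orientation <- function(xi, phi) {
  stopifnot(all(xi >= 0 & xi <= 180), all(phi >= 0 & phi < 360))
  structure(list(xi = xi, phi = phi), class = "orientation")
}
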