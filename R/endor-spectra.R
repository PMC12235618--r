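## Powder Mims-ENDOR forward model for the Gd(III) central transition and
## nonlinear least-squares spectrum fitting.
##
## The powder integral is evaluated on a fixed hemispheric (xi, phi) grid with
## sin(xi) trapezoidal weights. Line positions are deposited on a fine offset
## axis with *linear* binning (weight shared between the two neighbouring
## bins), which makes the accumulated profile continuous in the model
## parameters — a hard histogram would give a piecewise-constant objective
## that derivative-based fitting cannot descend. The profile is then convolved
## with a Gaussian of FWHM lw_fwhm and max-normalised.

#' Acquisition parameters for an ENDOR simulation
#'
#' @param tau Mims interpulse delay (s, > 0); default 2000 ns.
#' @param nu_ref Reference nuclear Larmor frequency (Hz); default 136.4 MHz
#'   (19F at 3.40 T).
#' @param lw_fwhm Gaussian convolution linewidth, FWHM (Hz, >= 0). Lumps RF
#'   excitation bandwidth and unresolved couplings.
#' @param grid_xi,grid_phi Powder-grid node counts (>= 32); defaults 181 x 361
#'   (0.5 degree steps in xi, 1 degree in phi).
#' @param apply_mims_weighting Weight orientations by the Mims response
#'   [mims_efficiency()]; on by default.
#' @param bin_hz Internal offset-axis bin width (Hz); default 500.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tau = 2000e-9, nu_ref = 136.4e6,
                               lw_fwhm = 10e3, grid_xi = 181, grid_phi = 361,
                               apply_mims_weighting = TRUE, bin_hz = 500) {
  stopifnot(tau > 0, nu_ref > 0, lw_fwhm >= 0,
            grid_xi >= 32, grid_phi >= 32, bin_hz > 0)
  structure(list(tau = tau, nu_ref = nu_ref, lw_fwhm = lw_fwhm,
                 grid_xi = as.integer(grid_xi),
                 grid_phi = as.integer(grid_phi),
                 apply_mims_weighting = isTRUE(apply_mims_weighting),
                 bin_hz = bin_hz),
            class = "acquisition_params")
}

#' ENDOR spectrum container
#'
#' @param offsets RF offsets nu - nu_I (Hz), monotone ascending.
#' @param intensities ENDOR efficiency (arbitrary units); normalised to unit
#'   maximum on construction.
#' @param meta Named list of acquisition/provenance metadata.
#' @return An object of class `endor_spectrum`.
#' @export
endor_spectrum <- function(offsets, intensities, meta = list()) {
  stopifnot(is.numeric(offsets), is.numeric(intensities),
            length(offsets) == length(intensities),
            !is.unsorted(offsets, strictly = TRUE))
  m <- max(intensities)
  if (!is.finite(m) || m <= 0) {
    stop("spectrum has no positive intensity", call. = FALSE)
  }
  structure(list(offsets = as.numeric(offsets),
                 intensities = as.numeric(intensities) / m,
                 meta = meta),
            class = "endor_spectrum")
}

#' @export
print.endor_spectrum <- function(x, ...) {
  cat(sprintf("<endor_spectrum> %d points, offsets [%.1f, %.1f] kHz\n",
              length(x$offsets), min(x$offsets) / 1e3, max(x$offsets) / 1e3))
  invisible(x)
}

#' Mims ENDOR response (blind-spot weighting)
#'
#' eta(a, tau) = (1 - cos(2 pi a tau)) / 2: zero exactly when a tau is an
#' integer (the blind spots, including the uncoupled a = 0 case) and maximal
#' when a tau is half-integer.
#'
#' @param a Hyperfine splitting (Hz, signed). Vectorised.
#' @param tau Mims interpulse delay (s, > 0).
#' @return Weight in \[0, 1\].
#' @export
mims_efficiency <- function(a, tau) {
  stopifnot(all(tau > 0))
  (1 - cos(2 * pi * a * tau)) / 2
}

## Precompute everything on the (xi, phi) grid that does not depend on the
## fitted parameters. Hemisphere xi in [0, 90], phi in [0, 360]; trapezoidal
## weights (endpoint halving makes the duplicated phi = 0/360 column exact).
powder_grid <- function(grid_xi, grid_phi) {
  xi <- seq(0, 90, length.out = grid_xi)
  phi <- seq(0, 360, length.out = grid_phi)
  wxi <- rep(1, grid_xi); wxi[c(1, grid_xi)] <- 0.5
  wphi <- rep(1, grid_phi); wphi[c(1, grid_phi)] <- 0.5
  xir <- xi * pi / 180
  phir <- phi * pi / 180
  list(
    sin_xi = rep(sin(xir), times = grid_phi),
    cos_xi = rep(cos(xir), times = grid_phi),
    sin_phi = rep(sin(phir), each = grid_xi),
    cos_phi = rep(cos(phir), each = grid_xi),
    w = as.vector(outer(wxi * sin(xir), wphi))
  )
}

## Deposit weights w at positions pos (Hz) onto a uniform axis by linear
## binning; returns the accumulated vector.
linear_bin <- function(pos, w, axis_min, bin, n_bins) {
  u <- (pos - axis_min) / bin
  i0 <- floor(u)
  frac <- u - i0
  idx <- c(i0 + 1, i0 + 2)           # 1-based left and right bins
  wt <- c(w * (1 - frac), w * frac)
  keep <- idx >= 1L & idx <= n_bins
  acc <- numeric(n_bins)
  if (any(keep)) {
    s <- rowsum(wt[keep], idx[keep])
    acc[as.integer(rownames(s))] <- s[, 1]
  }
  acc
}

## Gaussian convolution on a uniform axis (FWHM in Hz); zero-padded ends.
gauss_convolve <- function(y, bin, fwhm) {
  if (fwhm <= 0) return(y)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / bin))
  k <- stats::dnorm(seq(-half, half) * bin, sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  yp <- c(numeric(half), y, numeric(half))
  out <- stats::filter(yp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

## Core profile evaluation shared by simulation and fitting: intensities on a
## fixed uniform offset axis, NOT normalised.
powder_profile <- function(axis, grid, a_perp, tensor, gamma, rho,
                           nu_ref, tau, lw_fwhm, mims) {
  if (is.null(tensor)) {
    ct <- grid$cos_xi            # no CS frame: theta is the field polar angle
    center <- 0
  } else {
    g <- gamma * pi / 180
    r <- rho * pi / 180
    ct <- cos(r) * sin(g) * grid$cos_phi * grid$sin_xi +
      sin(r) * sin(g) * grid$sin_phi * grid$sin_xi +
      cos(g) * grid$cos_xi
    center <- nu_ref * 1e-6 *
      (tensor$dxx * (grid$cos_phi * grid$sin_xi)^2 +
         tensor$dyy * (grid$sin_phi * grid$sin_xi)^2 +
         tensor$dzz * grid$cos_xi^2)
  }
  a <- (3 * ct^2 - 1) * a_perp
  w <- grid$w
  if (mims) w <- w * mims_efficiency(a, tau)
  bin <- axis[2] - axis[1]
  n <- length(axis)
  acc <- linear_bin(center - a / 2, w, axis[1], bin, n) +
    linear_bin(center + a / 2, w, axis[1], bin, n)
  gauss_convolve(acc, bin, lw_fwhm)
}

#' Simulate a powder ENDOR spectrum
#'
#' Accumulates the central-transition doublet nu_I -/+ a/2 over a hemispheric
#' powder grid, with the dipolar splitting a(theta) from the point-dipole
#' coupling and, when `tensor` is given, the orientation-dependent Larmor
#' frequency from the chemical-shift anisotropy. Optional Mims blind-spot
#' weighting, Gaussian convolution at `lw_fwhm`, max-normalisation.
#'
#' Without CSA the spectrum is symmetric about zero offset; a resolved CSA
#' produces the characteristic asymmetric doublet with unequal branch heights.
#'
#' @param system A [spin_system()].
#' @param tensor A [cs_tensor()] or `NULL` for no resolved CSA.
#' @param acq An [acquisition_params()].
#' @return An [endor_spectrum()]; `meta` records the inputs.
#' @examples
#' sp <- simulate_powder_spectrum(spin_system(13.3), NULL,
#'                                acquisition_params(lw_fwhm = 15e3))
#' @export
simulate_powder_spectrum <- function(system, tensor = NULL,
                                     acq = acquisition_params()) {
  stopifnot(inherits(system, "spin_system"),
            inherits(acq, "acquisition_params"))
  if (!is.null(tensor)) stopifnot(inherits(tensor, "cs_tensor"))

  a_perp <- a_perp_from_distance(system$r_GdF, system$nucleus, system$ge)
  axis <- spectrum_axis(a_perp, tensor, acq)
  if (acq$lw_fwhm > 0 && acq$lw_fwhm < 2 * acq$bin_hz) {
    warning("lw_fwhm is below twice the bin width; increase grid/bin density")
  }
  grid <- powder_grid(acq$grid_xi, acq$grid_phi)
  y <- powder_profile(axis, grid, a_perp, tensor,
                      if (is.null(tensor)) 0 else tensor$gamma,
                      if (is.null(tensor)) 0 else tensor$rho,
                      acq$nu_ref, acq$tau, acq$lw_fwhm,
                      acq$apply_mims_weighting)
  if (max(y) <= 0) {
    stop("simulated spectrum is identically zero (all orientations in Mims ",
         "blind spots); change tau", call. = FALSE)
  }
  endor_spectrum(axis, y, meta = list(
    nucleus = system$nucleus$label, tau = acq$tau, nu_ref = acq$nu_ref,
    lw_fwhm = acq$lw_fwhm, r_GdF = system$r_GdF,
    mims_weighting = acq$apply_mims_weighting
  ))
}

## Offset axis wide enough for the doublet edges (2 a_perp), the CSA span and
## the convolution tails, rounded to whole bins and symmetric about zero.
spectrum_axis <- function(a_perp, tensor, acq) {
  span <- 1.25 * a_perp  # parallel edge at a_perp (offset a/2 with a = 2 a_perp)
  if (!is.null(tensor)) {
    span <- span + acq$nu_ref * 1e-6 *
      max(abs(c(tensor$dxx, tensor$dyy, tensor$dzz)))
  }
  span <- span + 4 * acq$lw_fwhm
  half_n <- ceiling(span / acq$bin_hz)
  seq(-half_n, half_n) * acq$bin_hz
}

#' Fit a measured or synthetic ENDOR spectrum
#'
#' Nonlinear least squares (NL2SOL via `nls(algorithm = "port")`) of the
#' powder forward model against a spectrum, varying any subset of
#' `r_GdF`, `gamma`, `rho`, `lw_fwhm`, `amplitude`. The CSA angles are box-
#' constrained to the canonical octant \[0, 90\] degrees; 1-sigma parameter
#' uncertainties come from the residual-variance-scaled covariance matrix.
#'
#' @param spectrum An [endor_spectrum()] to fit.
#' @param system0 A [spin_system()] holding the starting distance.
#' @param tensor0 A [cs_tensor()] with starting angles, or `NULL` to fit
#'   without CSA.
#' @param vary Character vector of parameter names to vary; subset of
#'   `c("r_GdF", "gamma", "rho", "lw_fwhm", "amplitude")`. `gamma`/`rho`
#'   require `tensor0`.
#' @param acq An [acquisition_params()] (grid, tau, linewidth start).
#' @return A list of class `spectrum_fit`: `params` (named vector of all five
#'   parameters, fitted or fixed), `sigmas`, `covariance`, `residual_norm`,
#'   `at_bound`, `fitted` (model intensities at the data offsets).
#' @export
fit_spectrum <- function(spectrum, system0, tensor0 = NULL,
                         vary = c("r_GdF", "lw_fwhm", "amplitude"),
                         acq = acquisition_params()) {
  stopifnot(inherits(spectrum, "endor_spectrum"),
            inherits(system0, "spin_system"))
  allowed <- c("r_GdF", "gamma", "rho", "lw_fwhm", "amplitude")
  stopifnot(all(vary %in% allowed))
  if (is.null(tensor0) && any(c("gamma", "rho") %in% vary)) {
    stop("cannot vary gamma/rho without a starting cs_tensor", call. = FALSE)
  }
  if (stats::sd(spectrum$intensities) == 0) {
    stop("degenerate (flat) spectrum", call. = FALSE)
  }

  grid <- powder_grid(acq$grid_xi, acq$grid_phi)
  nucleus <- system0$nucleus
  ge <- system0$ge
  has_csa <- !is.null(tensor0)

  full_start <- c(
    r_GdF = system0$r_GdF,
    gamma = if (has_csa) tensor0$gamma else 0,
    rho = if (has_csa) tensor0$rho else 0,
    lw_fwhm = acq$lw_fwhm,
    amplitude = 1
  )
  full_lower <- c(r_GdF = 3, gamma = 0, rho = 0,
                  lw_fwhm = max(acq$bin_hz, 1e2), amplitude = 1e-3)
  full_upper <- c(r_GdF = 40, gamma = 90, rho = 90,
                  lw_fwhm = 5e5, amplitude = 1e3)
  fixed <- full_start[setdiff(allowed, vary)]
  pn <- intersect(allowed, vary)  # canonical order

  ## model axis: fine uniform axis covering the data plus convolution margin,
  ## interpolated onto the data offsets
  offs <- spectrum$offsets
  pad <- 4 * max(full_upper[["lw_fwhm"]] / 10, acq$lw_fwhm, acq$bin_hz)
  half_n <- ceiling((max(abs(offs)) + pad) / acq$bin_hz)
  axis <- seq(-half_n, half_n) * acq$bin_hz

  eval_model <- function(x, r_GdF, gamma, rho, lw_fwhm, amplitude) {
    a_perp <- a_perp_from_distance(r_GdF, nucleus, ge)
    tens <- if (has_csa) {
      list(dxx = tensor0$dxx, dyy = tensor0$dyy, dzz = tensor0$dzz)
    } else NULL
    y <- powder_profile(axis, grid, a_perp, tens, gamma, rho,
                        acq$nu_ref, acq$tau, lw_fwhm,
                        acq$apply_mims_weighting)
    m <- max(y)
    if (m <= 0) return(rep(0, length(x)))
    amplitude * stats::approx(axis, y / m, xout = x, rule = 2)$y
  }
  model <- make_submodel(eval_model, fixed)

  ft <- fit_least_squares(offs, spectrum$intensities, model,
                          full_start[pn], full_lower[pn], full_upper[pn])

  params <- c(ft$par, fixed)[allowed]
  sigmas <- c(ft$sigma,
              stats::setNames(rep(0, length(fixed)), names(fixed)))[allowed]
  if (any(ft$at_bound)) {
    warning("fitted parameter(s) at bound: ",
            paste(names(ft$at_bound)[ft$at_bound], collapse = ", "))
  }
  structure(
    list(params = params, sigmas = sigmas, covariance = ft$cov,
         residual_norm = ft$residual_norm, at_bound = ft$at_bound,
         fitted = ft$fitted, method = ft$method, vary = pn),
    class = "spectrum_fit"
  )
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat("<spectrum_fit>\n")
  for (p in names(x$params)) {
    cat(sprintf("  %-9s %12.6g +/- %.3g%s\n", p, x$params[[p]],
                x$sigmas[[p]], if (p %in% x$vary) "" else " (fixed)"))
  }
  cat(sprintf("  residual norm %.4g\n", x$residual_norm))
  invisible(x)
}
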