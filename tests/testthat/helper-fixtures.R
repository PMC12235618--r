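# Shared fixtures. Coarser powder grids than the package default keep the
# slower spectrum tests inside the suite budget; grid-convergence is checked
# explicitly in test-endor-spectra.R.

f19 <- nucleus_spec("19F")

fast_acq <- function(...) {
  acquisition_params(grid_xi = 91, grid_phi = 181, ...)
}

gd1_tensor <- function(gamma = 57, rho = 75) {
  cs_tensor(98, -29, -69, gamma = gamma, rho = rho)
}

# Independent Cartesian oracle for the dipolar angle: explicit unit vectors,
# plain dot product.
cos_theta_cartesian <- function(xi, phi, gamma, rho) {
  d2r <- pi / 180
  b <- c(cos(phi * d2r) * sin(xi * d2r),
         sin(phi * d2r) * sin(xi * d2r),
         cos(xi * d2r))
  v <- c(cos(rho * d2r) * sin(gamma * d2r),
         sin(rho * d2r) * sin(gamma * d2r),
         cos(gamma * d2r))
  sum(b * v)
}
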