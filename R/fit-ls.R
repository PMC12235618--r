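## Shared nonlinear least-squares backend.
##
## Primary route is stats::nls(algorithm = "port"), i.e. the NL2SOL code, with
## box constraints and 1-sigma uncertainties from the residual-variance-scaled
## covariance. nls is known to abort on exactly-zero-residual problems and on
## structurally degenerate ones (e.g. a biexponential with one vanishing
## fraction); for those cases an L-BFGS-B fallback with a finite-difference
## Jacobian reproduces the same covariance convention.

fit_least_squares <- function(x, y, model, start, lower, upper) {
  pnames <- names(start)
  stopifnot(length(pnames) > 0, !is.null(pnames),
            identical(names(lower), pnames), identical(names(upper), pnames))

  fo <- stats::as.formula(
    paste0("y ~ model(x, ", paste(pnames, collapse = ", "), ")")
  )
  dat <- list(x = x, y = y)

  res <- tryCatch({
    fit <- stats::nls(fo, data = dat, start = as.list(start),
                      lower = lower, upper = upper, algorithm = "port",
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = FALSE))
    co <- summary(fit)$coefficients
    vc <- tryCatch(stats::vcov(fit), error = function(e) {
      matrix(NA_real_, length(pnames), length(pnames),
             dimnames = list(pnames, pnames))
    })
    list(par = stats::coef(fit), sigma = co[, "Std. Error"], cov = vc,
         fitted = stats::fitted(fit), converged = TRUE, method = "nl2sol")
  }, error = function(e) e)

  if (inherits(res, "error")) {
    res <- fit_ls_fallback(x, y, model, start, lower, upper,
                           message = conditionMessage(res))
  }

  res$residuals <- y - res$fitted
  res$residual_norm <- sqrt(sum(res$residuals^2))
  tol <- pmax(1e-8 * pmax(abs(res$par), 1e-30), 1e-12)
  res$at_bound <- (res$par <= lower + tol) | (res$par >= upper - tol)
  names(res$sigma) <- pnames
  res
}

fit_ls_fallback <- function(x, y, model, start, lower, upper, message = "") {
  pnames <- names(start)
  modelp <- function(x, p) do.call(model, c(list(x), as.list(p)))
  rss <- function(p) {
    r <- y - modelp(x, stats::setNames(p, pnames))
    sum(r * r)
  }
  opt <- stats::optim(unname(start), rss, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500,
                                     parscale = pmax(abs(start), 1e-3)))
  if (opt$convergence != 0 && opt$convergence != 52) {
    stop("least-squares fit failed to converge (", message,
         "; fallback code ", opt$convergence, "); last iterate: ",
         paste(sprintf("%s=%.6g", pnames, opt$par), collapse = ", "),
         call. = FALSE)
  }
  par <- stats::setNames(opt$par, pnames)
  fitted <- modelp(x, par)
  J <- fd_jacobian(function(p) modelp(x, p), par, lower, upper)
  n <- length(y)
  p <- length(par)
  dof <- max(n - p, 1)
  s2 <- sum((y - fitted)^2) / dof
  vc <- tryCatch(s2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vc) <- list(pnames, pnames)
  list(par = par, sigma = sqrt(pmax(diag(vc), 0)), cov = vc,
       fitted = fitted, converged = TRUE, method = "lbfgsb")
}

fd_jacobian <- function(f, par, lower, upper) {
  p <- length(par)
  f0 <- f(par)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    h <- max(1e-6 * abs(par[j]), 1e-9)
    up <- par
    dn <- par
    up[j] <- min(par[j] + h, upper[j])
    dn[j] <- max(par[j] - h, lower[j])
    J[, j] <- (f(up) - f(dn)) / (up[j] - dn[j])
  }
  J
}
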