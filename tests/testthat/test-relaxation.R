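# Stretched-exponential recovery fits, first moments, NSE decays, regression.

make_recovery <- function(T1e = 120e-6, beta = 0.8, A = 1, I0 = 1,
                          kind = "saturation", n = 24) {
  t <- 10^seq(log10(0.01 * T1e), log10(6 * T1e), length.out = n)
  endor_trace(t, I0 * (1 - A * exp(-(t / T1e)^beta)), kind = kind)
}

make_nse <- function(T2n, I0 = 1, tmax = 300e-6, n = 30) {
  t <- seq(0, tmax, length.out = n)
  endor_trace(t, I0 * exp(-2 * t / T2n), kind = "nse")
}

test_that("mean_T1e matches the numeric-integral oracle across beta", {
  # oracle: integrate exp(-(t/T)^beta) from 0 to infinity
  for (beta in seq(0.4, 1.5, by = 0.1)) {
    T1e <- 100e-6
    # u = t/T1e substitution keeps the integrand O(1) for quadrature
    oracle <- T1e * integrate(function(u) exp(-u^beta), 0, Inf,
                              rel.tol = 1e-10)$value
    expect_equal(mean_T1e(T1e, beta), oracle, tolerance = 1e-6)
  }
  expect_identical(mean_T1e(120e-6, 1), 120e-6)
  expect_equal(mean_T1e(120e-6, 0.5), 240e-6)
  expect_equal(mean_T1e(100e-6, 2 / 3), 132.934e-6, tolerance = 1e-5)
  expect_error(mean_T1e(1e-4, 0), "positive")
  expect_error(mean_T1e(1e-4, -1), "positive")
})

test_that("fit_recovery round-trips noiseless stretched-exponential traces", {
  f <- fit_recovery(make_recovery(T1e = 120e-6, beta = 0.8, A = 1))
  expect_equal(f$T1e, 120e-6, tolerance = 1e-6)
  expect_equal(f$beta, 0.8, tolerance = 1e-6)
  expect_equal(f$A, 1, tolerance = 1e-6)
  expect_equal(f$T1e_bar, mean_T1e(f$T1e, f$beta))

  # same trace, relative-noise objective: identical answer on noiseless data
  fr <- fit_recovery(make_recovery(), noise_model = "relative")
  expect_equal(fr$T1e, 120e-6, tolerance = 1e-6)
  expect_equal(fr$beta, 0.8, tolerance = 1e-6)
})

test_that("fit_recovery honours fixed parameters and inversion amplitudes", {
  # beta fixed to 1 on monoexponential data recovers the plain time constant
  mono <- make_recovery(T1e = 90e-6, beta = 1)
  f1 <- fit_recovery(mono, fix = c(beta = 1))
  expect_identical(f1$beta, 1)
  expect_equal(f1$T1e, 90e-6, tolerance = 1e-8)
  expect_identical(unname(f1$sigmas["beta"]), 0)

  # inversion recovery with A = 1.9 fits A > 1
  inv <- make_recovery(T1e = 100e-6, beta = 0.85, A = 1.9, kind = "inversion")
  fi <- fit_recovery(inv)
  expect_gt(fi$A, 1)
  expect_equal(fi$A, 1.9, tolerance = 1e-5)
  # relative model is undefined for sign-changing inversion traces
  expect_error(fit_recovery(inv, noise_model = "relative"), "positive")
})

test_that("fit_recovery is invariant under intensity rescaling", {
  tr <- make_recovery(T1e = 150e-6, beta = 0.7)
  f1 <- fit_recovery(tr)
  tr2 <- endor_trace(tr$t, 37.5 * tr$I, kind = "saturation")
  f2 <- fit_recovery(tr2)
  expect_equal(f2$T1e, f1$T1e, tolerance = 1e-9)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-9)
  expect_equal(f2$I0 / f1$I0, 37.5, tolerance = 1e-9)
})

test_that("fit_nse_mono recovers T2n and matches the log-linear slope", {
  f <- fit_nse_mono(make_nse(500e-6), window_max = 300e-6)
  expect_equal(f$T2n, 500e-6, tolerance = 1e-9)
  expect_equal(f$components$rate, 1 / 500e-6, tolerance = 1e-9)
  expect_identical(f$components$fraction, 1)

  # log-linear oracle: rate = -slope(ln I vs tau)/2
  tr <- make_nse(240e-6, tmax = 200e-6)
  lfit <- lm(log(tr$I) ~ tr$t)
  expect_equal(1 / fit_nse_mono(tr)$T2n, -coef(lfit)[[2]] / 2,
               tolerance = 1e-9)

  # windowing: unbiased on noiseless data for any window
  for (w in c(80e-6, 150e-6, 300e-6)) {
    expect_equal(fit_nse_mono(make_nse(500e-6), window_max = w)$T2n,
                 500e-6, tolerance = 1e-7)
  }
})

test_that("fit_nse_mono errors on degenerate inputs", {
  tr <- make_nse(500e-6)
  expect_error(fit_nse_mono(tr, window_max = 2e-6), "4 points")
  up <- endor_trace(tr$t, exp(2 * tr$t / 500e-6), kind = "nse")
  expect_error(fit_nse_mono(up), "non-decaying")
  sat <- make_recovery()
  expect_error(fit_nse_mono(sat), "NSE trace")
})

test_that("fit_nse_mono recovers a truncated noisy decay within 5% on average", {
  # 200 us window (the experimental maximum), 2% noise, 20 seeds
  T2n <- 300e-6
  set.seed(11)
  est <- replicate(20, {
    t <- seq(0, 200e-6, length.out = 20)
    I <- exp(-2 * t / T2n) + rnorm(20, 0, 0.02)
    fit_nse_mono(endor_trace(t, I, kind = "nse"))$T2n
  })
  expect_lt(abs(mean(est) / T2n - 1), 0.05)
})

test_that("fit_nse_biexp round-trips two components and the shared-rate refit", {
  t <- seq(0, 2000e-6, length.out = 60)
  kf <- 65e3; ks <- 0.6e3
  I <- 0.5 * exp(-2 * t * kf) + 0.5 * exp(-2 * t * ks)
  f <- fit_nse_biexp(endor_trace(t, I, kind = "nse"))
  expect_equal(f$components$rate[1], kf, tolerance = 1e-4)
  expect_equal(f$components$rate[2], ks, tolerance = 1e-4)
  expect_equal(f$components$fraction[1], 0.5, tolerance = 1e-4)
  expect_equal(sum(f$components$fraction), 1)
  expect_gt(f$components$rate[1], f$components$rate[2])

  # rates inside the observed 50-80 kHz / 0.3-1 kHz windows by construction
  expect_true(f$components$rate[1] > 50e3 && f$components$rate[1] < 80e3)
  expect_true(f$components$rate[2] > 0.3e3 && f$components$rate[2] < 1e3)

  # shared-rate refit across two fractions recovers 0.3 and 0.7
  for (frac in c(0.3, 0.7)) {
    Ii <- frac * exp(-2 * t * kf) + (1 - frac) * exp(-2 * t * ks)
    fs <- fit_nse_biexp(endor_trace(t, Ii, kind = "nse"),
                        shared_rates = c(kf, ks))
    expect_equal(fs$components$fraction[1], frac, tolerance = 0.02)
  }
})

test_that("fit_nse_biexp degenerates gracefully to a single population", {
  t <- seq(0, 2000e-6, length.out = 40)
  I <- exp(-2 * t * 0.6e3)  # f = 0: pure slow component
  fb <- suppressWarnings(fit_nse_biexp(endor_trace(t, I, kind = "nse")))
  fm <- fit_nse_mono(endor_trace(t, I, kind = "nse"), window_max = 2000e-6)
  dominant <- fb$components$rate[which.max(fb$components$fraction)]
  expect_equal(dominant, fm$components$rate[1], tolerance = 1e-3)
})

test_that("regress_rates fits exact and degenerate cases correctly", {
  x <- c(7e3, 12e3, 17e3, 22e3)
  r <- regress_rates(list(inv_T1e_bar = x, inv_T2n = 0.5 * x))
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-9)
  expect_equal(r$r_squared, 1)
  expect_identical(r$n, 4L)

  # two points: interpolating line
  r2 <- regress_rates(list(inv_T1e_bar = c(1e3, 2e3),
                           inv_T2n = c(4e2, 9e2)))
  expect_equal(r2$slope, 0.5)
  expect_equal(r2$intercept, -1e2)

  ro <- regress_rates(list(inv_T1e_bar = x, inv_T2n = 0.5 * x),
                      through_origin = TRUE)
  expect_equal(ro$slope, 0.5, tolerance = 1e-12)
  expect_identical(ro$intercept, 0)

  expect_error(regress_rates(list(inv_T1e_bar = 1e3, inv_T2n = 5e2)),
               "at least 2")
  expect_error(regress_rates(list(inv_T1e_bar = c(1e3, 1e3),
                                  inv_T2n = c(4e2, 5e2))), "degenerate")
  expect_error(regress_rates(list(inv_T1e_bar = c(-1, 2), inv_T2n = c(1, 2))),
               "positive")
})
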