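# Seeded generators: determinism, closed loops, generative relations.

test_that("the calibrated rate law passes through both anchors and stays in band", {
  law <- calibrate_t1e_law()
  expect_equal(law[["c"]] * 3.7^law[["n"]], 7e3, tolerance = 1e-12)
  expect_equal(law[["c"]] * 10^law[["n"]], 22e3, tolerance = 1e-12)
  cfg <- generator_config(seed = 1)
  rates <- cfg$t1e_law[["c"]] * cfg$temperatures^cfg$t1e_law[["n"]]
  expect_true(all(rates >= 7e3 - 1e-6 & rates <= 22e3 + 1e-6))
  # a law leaving the band is rejected
  expect_error(generator_config(seed = 1, t1e_law = c(7e3, 2)), "band")
  expect_error(generator_config(seed = 1, noise_frac = 0.5), "noise_frac")
  expect_error(generator_config(), "seed")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- generator_config(seed = 99)
  expect_identical(gen_recovery_traces(cfg, "saturation"),
                   gen_recovery_traces(cfg, "saturation"))
  expect_identical(gen_nse_19F(cfg), gen_nse_19F(cfg))
  expect_identical(gen_nse_1H(cfg, 0.1, 0.94e6), gen_nse_1H(cfg, 0.1, 0.94e6))
  sys <- spin_system(13.3)
  a <- gen_spectrum(sys, NULL, fast_acq(), noise_frac = 0.02, seed = 5)
  b <- gen_spectrum(sys, NULL, fast_acq(), noise_frac = 0.02, seed = 5)
  expect_identical(a, b)
  # different seed, different noise
  c2 <- gen_spectrum(sys, NULL, fast_acq(), noise_frac = 0.02, seed = 6)
  expect_false(identical(a$intensities, c2$intensities))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(gen_nse_19F(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("noiseless recovery traces close the loop through fit_recovery", {
  cfg <- generator_config(seed = 3, noise_frac = 0)
  rec <- gen_recovery_traces(cfg, "saturation")
  rates <- calibrate_t1e_law()[["c"]] *
    cfg$temperatures^calibrate_t1e_law()[["n"]]
  for (i in seq_along(rec)) {
    f <- fit_recovery(rec[[i]])
    expect_equal(f$beta, 0.8, tolerance = 1e-6)
    expect_equal(1 / f$T1e_bar, rates[i], tolerance = 1e-6)
    expect_equal(f$A, 1, tolerance = 1e-6)
  }
  inv <- gen_recovery_traces(cfg, "inversion")
  fi <- fit_recovery(inv[[1]])
  expect_gt(fi$A, 1.5)
})

test_that("default noisy recovery at 10 K lands in the 7-22 kHz band", {
  cfg <- generator_config(seed = 17)
  rec <- gen_recovery_traces(cfg, "saturation")
  f <- fit_recovery(rec[["10K"]])
  expect_gt(1 / f$T1e_bar, 7e3)
  expect_lt(1 / f$T1e_bar, 22e3 * 1.1)
})

test_that("19F NSE decays encode T2n = 2 T1e_bar exactly before noise", {
  cfg <- generator_config(seed = 4, noise_frac = 0)
  nse <- gen_nse_19F(cfg)
  rates <- calibrate_t1e_law()[["c"]] *
    cfg$temperatures^calibrate_t1e_law()[["n"]]
  fitted <- vapply(nse, function(tr) fit_nse_mono(tr)$T2n, 0)
  expect_equal(unname(fitted), unname(2 / rates), tolerance = 1e-9)
  # so the 19F decoherence rates sit at half the electron rates (3.5-11 kHz)
  expect_equal(unname(1 / fitted), unname(rates / 2), tolerance = 1e-9)

  # noiseless regression: exact generative line
  reg <- regress_rates(list(inv_T1e_bar = rates, inv_T2n = 1 / fitted))
  expect_equal(reg$slope, 0.5, tolerance = 1e-9)
  expect_equal(reg$intercept, 0, tolerance = 1e-3)
})

test_that("1H fast fraction is monotone in protonation with invariant rates", {
  cfg <- generator_config(seed = 8, noise_frac = 0)
  h2o <- seq(0, 0.2, by = 0.05)
  fracs <- numeric(length(h2o))
  rate_f <- numeric(length(h2o))
  rate_s <- numeric(length(h2o))
  for (i in seq_along(h2o)) {
    tr <- gen_nse_1H(cfg, h2o_frac = h2o[i], a_hf = 0.94e6)
    fit <- fit_nse_biexp(tr, shared_rates = c(65e3, 0.6e3))
    fracs[i] <- fit$components$fraction[1]
    free <- fit_nse_biexp(tr)
    rate_f[i] <- free$components$rate[1]
    rate_s[i] <- free$components$rate[2]
  }
  expect_true(all(diff(fracs) > 0))
  # component rates do not move with protonation
  expect_lt(diff(range(rate_f)) / mean(rate_f), 0.02)
  expect_lt(diff(range(rate_s)) / mean(rate_s), 0.02)

  # fast fraction decreases with the hyperfine coupling magnitude
  f_by_a <- vapply(c(0, 0.94e6, 1.44e6), function(a) {
    gen_nse_1H(cfg, h2o_frac = 0, a_hf = a)$meta$fast_fraction
  }, 0)
  expect_true(all(diff(f_by_a) < 0))

  # protonation raises the fitted fast fraction at a ~ 0
  f0 <- fit_nse_biexp(gen_nse_1H(cfg, 0, 0), shared_rates = c(65e3, 0.6e3))
  f10 <- fit_nse_biexp(gen_nse_1H(cfg, 0.10, 0), shared_rates = c(65e3, 0.6e3))
  expect_gt(f10$components$fraction[1], f0$components$fraction[1])
})

test_that("shared-rate refit across conditions recovers the generating rates", {
  # two-scale grid: dense early points resolve the 65 kHz component (decay
  # scale ~8 us), the sparse tail pins the 0.6 kHz component
  cfg <- generator_config(seed = 21, noise_frac = 0.01,
                          nse_grid = c(seq(0, 24e-6, length.out = 13),
                                       seq(100e-6, 2000e-6,
                                           length.out = 25)))
  conds <- list(c(0, 0), c(0, 0.94e6), c(0.1, 0), c(0.1, 0.94e6))
  kf <- ks <- numeric(length(conds))
  for (i in seq_along(conds)) {
    tr <- gen_nse_1H(cfg, h2o_frac = conds[[i]][1], a_hf = conds[[i]][2])
    fit <- fit_nse_biexp(tr)
    kf[i] <- fit$components$rate[1]
    ks[i] <- fit$components$rate[2]
  }
  # a single rate pair underlies all four conditions: the pooled (geometric
  # mean) estimate recovers it within 5%, and each condition is within 15%
  expect_lt(abs(exp(mean(log(kf))) / 65e3 - 1), 0.05)
  expect_lt(abs(exp(mean(log(ks))) / 0.6e3 - 1), 0.05)
  expect_true(all(abs(kf / 65e3 - 1) < 0.15))
  expect_true(all(abs(ks / 0.6e3 - 1) < 0.15))
})

test_that("biexponential fast fraction is monotone in the generating fraction", {
  # Spearman rho = 1 across generating fractions 0.1-0.9, several seeds
  t <- seq(0, 2000e-6, length.out = 50)
  for (seed in 1:5) {
    cfg <- generator_config(seed = seed, noise_frac = 0.01,
                            nse_grid = t)
    gen_f <- seq(0.1, 0.9, by = 0.2)
    fit_f <- vapply(gen_f, function(fv) {
      set.seed(seed * 1000 + round(fv * 100))
      I <- fv * exp(-2 * t * 65e3) + (1 - fv) * exp(-2 * t * 0.6e3) +
        rnorm(length(t), 0, 0.01)
      fit <- fit_nse_biexp(endor_trace(t, I, kind = "nse"),
                           shared_rates = c(65e3, 0.6e3))
      fit$components$fraction[1]
    }, 0)
    expect_equal(cor(gen_f, fit_f, method = "spearman"), 1,
                 tolerance = 1e-12)
  }
})

test_that("gen_spectrum with zero noise equals the deterministic simulation", {
  sys <- spin_system(13.3)
  acq <- fast_acq(lw_fwhm = 15e3)
  sp0 <- simulate_powder_spectrum(sys, NULL, acq)
  spn <- gen_spectrum(sys, NULL, acq, noise_frac = 0, seed = 1)
  expect_equal(spn$intensities, sp0$intensities)
  expect_equal(spn$offsets, sp0$offsets)

  # Gd4-like symmetric doublet with splitting ~ a_perp between branch maxima
  ap <- a_perp_from_distance(13.3)
  pk_hi <- sp0$offsets[sp0$offsets > 0][which.max(sp0$intensities[sp0$offsets > 0])]
  pk_lo <- sp0$offsets[sp0$offsets < 0][which.max(sp0$intensities[sp0$offsets < 0])]
  expect_equal(pk_hi - pk_lo, ap, tolerance = 0.25)
})
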