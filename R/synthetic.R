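## Seeded synthetic-data generators emulating the spectrometer data products:
## stretched-exponential recovery traces, 19F NSE decays tied to the electron
## T1e by the slow-relaxation limit, two-population 1H NSE decays, and noisy
## powder ENDOR spectra. All generators are pure functions of (config, seed).

## Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Calibrate a power-law temperature dependence of the electron rate
#'
#' Returns `(c, n)` such that 1/T1e_bar = c T^n passes through the two
#' anchor points, by default 7 kHz at 3.7 K and 22 kHz at 10 K — the span of
#' saturation-recovery rates observed for the Gd(III) model complexes over
#' 3.7-10 K.
#'
#' @param rate_lo,rate_hi Anchor rates (Hz).
#' @param temp_lo,temp_hi Anchor temperatures (K).
#' @return Named numeric vector `c(c = ..., n = ...)`.
#' @export
calibrate_t1e_law <- function(rate_lo = 7e3, rate_hi = 22e3,
                              temp_lo = 3.7, temp_hi = 10) {
  stopifnot(rate_hi > rate_lo, temp_hi > temp_lo, rate_lo > 0, temp_lo > 0)
  n <- log(rate_hi / rate_lo) / log(temp_hi / temp_lo)
  c(c = rate_lo / temp_lo^n, n = n)
}

#' Synthetic-data generator configuration
#'
#' The defaults encode the measured world: temperatures 3.7-10 K, electron
#' spin-lattice rates 1/T1e_bar spanning 7-22 kHz with stretch exponent
#' beta = 0.8, 2% Gaussian noise, NSE sampling truncated at 200 us, and a 1H
#' two-population model with fixed component rates of 65 kHz (fast) and
#' 0.6 kHz (slow).
#'
#' @param seed Integer seed; must be given explicitly (no implicit entropy).
#' @param temperatures Temperatures (K).
#' @param t1e_law Numeric `c(c, n)` of the rate law 1/T1e_bar = c T^n (Hz,
#'   K^-n); default from [calibrate_t1e_law()].
#' @param beta Stretch exponent of the recovery traces.
#' @param noise_frac Relative Gaussian noise sigma, in \[0, 0.2\].
#' @param nse_grid tau_RF sampling for NSE decays (s); default 20 linear
#'   points up to 200 us.
#' @param recovery_grid t_wait sampling (s), or `NULL` to auto-build 24
#'   log-spaced points up to 5 T1e at each temperature.
#' @param rate_band Plausibility band (Hz) the law must keep rates inside
#'   over `temperatures`.
#' @param proton_model Named list with `fast_rate`, `slow_rate` (Hz),
#'   `f0_scale` (fast fraction at a_hf = 0, no added protons), `a_decay`
#'   (hyperfine scale, Hz, controlling the decrease of the fast fraction with
#'   coupling), `h2o_slope` (fraction gained per unit H2O volume fraction).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             temperatures = c(3.7, 5, 7, 10),
                             t1e_law = calibrate_t1e_law(),
                             beta = 0.8,
                             noise_frac = 0.02,
                             nse_grid = seq(0, 200e-6, length.out = 20),
                             recovery_grid = NULL,
                             rate_band = c(7e3, 22e3),
                             proton_model = list(fast_rate = 65e3,
                                                 slow_rate = 0.6e3,
                                                 f0_scale = 0.55,
                                                 a_decay = 1e6,
                                                 h2o_slope = 2.5)) {
  if (missing(seed)) stop("seed must be set explicitly", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            noise_frac >= 0, noise_frac <= 0.2,
            beta > 0, all(temperatures > 0),
            length(t1e_law) == 2, all(t1e_law > 0))
  rates <- t1e_law[[1]] * temperatures^t1e_law[[2]]
  if (any(rates < rate_band[1] - 1e-6) || any(rates > rate_band[2] + 1e-6)) {
    stop("t1e_law yields rates outside the band [",
         rate_band[1], ", ", rate_band[2], "] Hz", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), temperatures = temperatures,
         t1e_law = c(c = t1e_law[[1]], n = t1e_law[[2]]), beta = beta,
         noise_frac = noise_frac, nse_grid = nse_grid,
         recovery_grid = recovery_grid, rate_band = rate_band,
         proton_model = proton_model),
    class = "generator_config"
  )
}

## 1/T1e_bar (Hz) at each configured temperature.
t1e_bar_rates <- function(config) {
  stats::setNames(
    config$t1e_law[["c"]] * config$temperatures^config$t1e_law[["n"]],
    paste0(config$temperatures, "K")
  )
}

#' Generate saturation/inversion recovery traces
#'
#' One trace per configured temperature, following
#' I = I0 (1 - A exp(-(t/T1e)^beta)) with T1e chosen so that the first-moment
#' mean [mean_T1e()] matches the configured rate law at that temperature.
#' A = 1 for saturation recovery; for inversion recovery A is drawn uniformly
#' from \[1.6, 2\]. Noise is multiplicative Gaussian of relative sigma
#' `noise_frac`.
#'
#' @param config A [generator_config()].
#' @param kind `"saturation"` or `"inversion"`.
#' @return A list of [endor_trace()] objects, named by temperature.
#' @export
gen_recovery_traces <- function(config, kind = c("saturation", "inversion")) {
  stopifnot(inherits(config, "generator_config"))
  kind <- match.arg(kind)
  rates <- t1e_bar_rates(config)
  beta <- config$beta
  with_rng_seed(config$seed + 101L, {
    out <- lapply(seq_along(config$temperatures), function(i) {
      tbar <- 1 / rates[[i]]
      T1e <- tbar * beta / gamma(1 / beta)
      grid <- config$recovery_grid
      if (is.null(grid)) {
        grid <- 10^seq(log10(0.01 * T1e), log10(5 * T1e), length.out = 24)
      }
      if (max(grid) < 2 * T1e) {
        warning("recovery grid shorter than 2*T1e at ",
                config$temperatures[i], " K")
      }
      A <- if (kind == "inversion") stats::runif(1, 1.6, 2.0) else 1.0
      I <- 1 - A * exp(-(grid / T1e)^beta)
      I <- I * (1 + stats::rnorm(length(I), 0, config$noise_frac))
      endor_trace(grid, I, kind = kind,
                  temperature = config$temperatures[i], nucleus = "e")
    })
    names(out) <- names(rates)
    out
  })
}

#' Generate 19F nuclear-spin-echo decays in the slow-relaxation limit
#'
#' Per temperature, sets T2n = 2 T1e_bar(T) from the configured rate law (the
#' slow-limit relation) and samples I = exp(-2 tau_RF / T2n) on the NSE grid
#' with additive Gaussian noise of sigma = `noise_frac` (relative to the
#' unit initial intensity). Paired with [gen_recovery_traces()] by
#' temperature.
#'
#' @param config A [generator_config()].
#' @return A list of [endor_trace()] objects, named by temperature.
#' @export
gen_nse_19F <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rates <- t1e_bar_rates(config)
  with_rng_seed(config$seed + 202L, {
    out <- lapply(seq_along(config$temperatures), function(i) {
      T2n <- 2 / rates[[i]]
      tau <- config$nse_grid
      I <- exp(-2 * tau / T2n) +
        stats::rnorm(length(tau), 0, config$noise_frac)
      endor_trace(tau, I, kind = "nse",
                  temperature = config$temperatures[i], nucleus = "19F")
    })
    names(out) <- names(rates)
    out
  })
}

#' Generate a two-population 1H nuclear-spin-echo decay
#'
#' Biexponential decay with component rates fixed by `config$proton_model`
#' (matrix protonation and hyperfine coupling move the *fractions*, never the
#' rates): the fast fraction is
#' f = f0_scale * exp(-|a_hf| / a_decay) + h2o_slope * h2o_frac, clipped to
#' \[0, 1\] — monotone increasing in `h2o_frac` and decreasing in `|a_hf|`.
#'
#' @param config A [generator_config()].
#' @param h2o_frac H2O volume fraction of the matrix, in \[0, 0.5\].
#' @param a_hf Proton hyperfine coupling (Hz, >= 0).
#' @return An [endor_trace()] of kind `"nse"`; the generating fraction and
#'   rates are recorded in `meta`.
#' @export
gen_nse_1H <- function(config, h2o_frac = 0, a_hf = 0) {
  stopifnot(inherits(config, "generator_config"),
            h2o_frac >= 0, h2o_frac <= 0.5, a_hf >= 0)
  pm <- config$proton_model
  f <- pm$f0_scale * exp(-abs(a_hf) / pm$a_decay) + pm$h2o_slope * h2o_frac
  f <- min(1, max(0, f))
  with_rng_seed(config$seed + 303L + round(1e3 * h2o_frac) +
                  round(a_hf / 1e4), {
    tau <- config$nse_grid
    I <- f * exp(-2 * tau * pm$fast_rate) +
      (1 - f) * exp(-2 * tau * pm$slow_rate) +
      stats::rnorm(length(tau), 0, config$noise_frac)
    endor_trace(tau, I, kind = "nse", nucleus = "1H",
                temperature = NA_real_)
  }) -> tr
  tr$meta$fast_fraction <- f
  tr$meta$fast_rate <- pm$fast_rate
  tr$meta$slow_rate <- pm$slow_rate
  tr$meta$h2o_frac <- h2o_frac
  tr$meta$a_hf <- a_hf
  tr
}

#' Generate a noisy synthetic ENDOR spectrum
#'
#' [simulate_powder_spectrum()] output plus additive Gaussian noise of
#' sigma = `noise_frac` times the maximum intensity.
#'
#' @param system A [spin_system()].
#' @param tensor A [cs_tensor()] or `NULL`.
#' @param acq An [acquisition_params()].
#' @param noise_frac Relative noise sigma.
#' @param seed Integer seed.
#' @return An [endor_spectrum()].
#' @export
gen_spectrum <- function(system, tensor = NULL, acq = acquisition_params(),
                         noise_frac = 0.02, seed = 1L) {
  sp <- simulate_powder_spectrum(system, tensor, acq)
  if (noise_frac > 0) {
    with_rng_seed(seed, {
      y <- sp$intensities + stats::rnorm(length(sp$intensities), 0, noise_frac)
      ## keep the container invariant (max-normalised, positive maximum)
      sp <- endor_spectrum(sp$offsets, y, meta = sp$meta)
    })
  }
  sp$meta$noise_frac <- noise_frac
  sp$meta$seed <- seed
  sp
}
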