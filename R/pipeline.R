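## End-to-end orchestration: generate (or ingest) traces and spectra, fit
## everything, regress decoherence rates against spin-lattice rates, compare
## with the limiting theories, and emit TSV tables plus a JSON summary.

#' Default analysis configuration
#'
#' The shipped defaults describe the measured world: W-band (3.40 T) 19F
#' reference Larmor frequency 136.4 MHz, Gd(III) ge = 1.992, S = 7/2,
#' temperatures 3.7-10 K with electron rates 7-22 kHz, 2% noise, tau = 2 us.
#'
#' @return A nested list mirroring the YAML config schema.
#' @export
default_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yml",
                              package = "fendor"))
}

config_to_objects <- function(cfg) {
  law <- if (!is.null(cfg$t1e_law)) {
    c(cfg$t1e_law$c, cfg$t1e_law$n)
  } else {
    calibrate_t1e_law()
  }
  gen <- generator_config(
    seed = cfg$seed,
    temperatures = as.numeric(unlist(cfg$temperatures)),
    t1e_law = law,
    beta = cfg$beta %||% 0.8,
    noise_frac = cfg$noise_frac %||% 0.02
  )
  nuc <- nucleus_spec(cfg$spin_system$nucleus %||% "19F",
                      larmor_ref = cfg$spin_system$nu_ref %||% NULL)
  sys <- spin_system(r_GdF = cfg$spin_system$r_GdF %||% 13.3,
                     nucleus = nuc,
                     S = cfg$spin_system$S %||% 3.5,
                     ge = cfg$spin_system$ge %||% 1.992)
  tensor <- if (!is.null(cfg$cs_tensor)) {
    cs_tensor(cfg$cs_tensor$dxx, cfg$cs_tensor$dyy, cfg$cs_tensor$dzz,
              cfg$cs_tensor$gamma, cfg$cs_tensor$rho)
  } else NULL
  acq <- acquisition_params(
    tau = cfg$acquisition$tau_ns %||% 2000 * 1e-9,
    nu_ref = nuc$larmor_ref,
    lw_fwhm = (cfg$acquisition$lw_khz %||% 15) * 1e3,
    grid_xi = cfg$acquisition$grid_xi %||% 181,
    grid_phi = cfg$acquisition$grid_phi %||% 361,
    apply_mims_weighting = cfg$acquisition$mims_weighting %||% TRUE
  )
  list(gen = gen, system = sys, tensor = tensor, acq = acq,
       through_origin = isTRUE(cfg$regression$through_origin),
       recovery_noise = cfg$recovery_noise_model %||% "relative",
       window_max = (cfg$nse_window_us %||% 200) * 1e-6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Generates the synthetic dataset described by the config, fits every
#' recovery trace (stretched exponential), computes first-moment means,
#' fits every NSE decay (monoexponential, early window), regresses 1/T2n on
#' 1/T1e_bar, simulates-and-fits the ENDOR spectrum, evaluates both limiting
#' decoherence theories per temperature, and writes TSV tables plus a JSON
#' summary under `out_dir`.
#'
#' @param config Path to a YAML config file, or an equivalent nested list.
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @return An object of class `analysis_report` (list with `relaxation`
#'   data.frame, `regression`, `spectrum_fit`, `theory` data.frame,
#'   `provenance`).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  ob <- config_to_objects(cfg)
  gen <- ob$gen

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  rec <- stage("generate", gen_recovery_traces(gen, "saturation"))
  nse <- stage("generate", gen_nse_19F(gen))

  rec_fits <- stage("fit-recovery", lapply(rec, fit_recovery,
                                           noise_model = ob$recovery_noise))
  nse_fits <- stage("fit-nse", lapply(nse, fit_nse_mono,
                                      window_max = ob$window_max))

  relax <- data.frame(
    temperature_K = gen$temperatures,
    T1e_us = vapply(rec_fits, function(f) f$T1e, 0) * 1e6,
    beta = vapply(rec_fits, function(f) f$beta, 0),
    T1e_bar_us = vapply(rec_fits, function(f) f$T1e_bar, 0) * 1e6,
    inv_T1e_bar_khz = 1e-3 / vapply(rec_fits, function(f) f$T1e_bar, 0),
    T2n_us = vapply(nse_fits, function(f) f$T2n, 0) * 1e6,
    inv_T2n_khz = 1e-3 / vapply(nse_fits, function(f) f$T2n, 0),
    sigma_T1e_us = vapply(rec_fits, function(f) f$sigmas[["T1e"]], 0) * 1e6,
    sigma_beta = vapply(rec_fits, function(f) f$sigmas[["beta"]], 0),
    sigma_T2n_us = vapply(nse_fits, function(f) f$sigmas[["T2n"]], 0) * 1e6,
    row.names = NULL
  )

  reg <- stage("regress", regress_rates(
    list(inv_T1e_bar = 1 / vapply(rec_fits, function(f) f$T1e_bar, 0),
         inv_T2n = 1 / vapply(nse_fits, function(f) f$T2n, 0)),
    through_origin = ob$through_origin
  ))

  spfit <- NULL
  if (!isFALSE(cfg$spectrum_enabled)) {
    sp <- stage("spectrum", gen_spectrum(ob$system, ob$tensor, ob$acq,
                                         noise_frac = gen$noise_frac,
                                         seed = gen$seed + 404L))
    vary <- if (is.null(ob$tensor)) c("r_GdF", "lw_fwhm", "amplitude")
            else c("r_GdF", "gamma", "rho", "lw_fwhm", "amplitude")
    spfit <- stage("spectrum", fit_spectrum(sp, ob$system, ob$tensor,
                                            vary = vary, acq = ob$acq))
  }

  a_perp <- a_perp_from_distance(ob$system$r_GdF, ob$system$nucleus,
                                 ob$system$ge)
  omega_I <- 2 * pi * ob$system$nucleus$larmor_ref
  theory <- data.frame(
    temperature_K = gen$temperatures,
    a_perp_khz = a_perp / 1e3,
    t2n_sbm_ns = vapply(rec_fits, function(f) {
      sbm_t2n(a_perp, ob$system$S, f$T1e_bar, omega_I)
    }, 0) * 1e9,
    t2n_slow_us = vapply(rec_fits, function(f) {
      slow_limit_t2n(f$T1e_bar)
    }, 0) * 1e6,
    regime = vapply(rec_fits, function(f) {
      classify_regime(a_perp, f$T1e_bar)
    }, ""),
    row.names = NULL
  )

  prov <- list(
    seed = gen$seed,
    config = cfg,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("fendor")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  report <- structure(
    list(relaxation = relax,
         regression = list(slope = reg$slope, intercept = reg$intercept,
                           r_squared = reg$r_squared, n = reg$n,
                           sigma_slope = reg$sigmas[["slope"]]),
         spectrum_fit = if (is.null(spfit)) NULL else {
           list(params = as.list(spfit$params),
                sigmas = as.list(spfit$sigmas),
                residual_norm = spfit$residual_norm)
         },
         theory = theory,
         provenance = prov),
    class = "analysis_report"
  )

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write an analysis report to disk
#'
#' Emits `relaxation.tsv`, `theory.tsv` and `summary.json` under `out_dir`.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table <- function(df, path) {
    df[] <- lapply(df, function(col) if (is.numeric(col)) fmt6(col) else col)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_table(report$relaxation, file.path(out_dir, "relaxation.tsv"))
  write_table(report$theory, file.path(out_dir, "theory.tsv"))
  jsonlite::write_json(
    list(regression = report$regression,
         spectrum_fit = report$spectrum_fit,
         provenance = report$provenance),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  regression: slope %.4f (+/- %.4f), intercept %.3g Hz, R^2 %.4f\n",
              x$regression$slope, x$regression$sigma_slope,
              x$regression$intercept, x$regression$r_squared))
  if (!is.null(x$spectrum_fit)) {
    cat(sprintf("  spectrum fit: r = %.3f A, lw = %.2f kHz\n",
                x$spectrum_fit$params$r_GdF,
                x$spectrum_fit$params$lw_fwhm / 1e3))
  }
  cat(sprintf("  %d temperatures, regime(s): %s\n",
              nrow(x$theory), paste(unique(x$theory$regime), collapse = ", ")))
  invisible(x)
}
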