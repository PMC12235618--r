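## Limiting theories of nuclear decoherence near a paramagnetic centre.

#' Solomon-Bloembergen-Morgan nuclear coherence time (fast-relaxation limit)
#'
#' Valid when the electron spin-lattice rate is fast compared with the
#' hyperfine coupling (1/T1e >> a_perp), in which case the hyperfine doublet
#' collapses and
#' 1/T2n = (2 pi a_perp)^2 S(S+1)/15 \[4 T1e + 3 T1e / (1 + omega_I^2 T1e^2)\].
#' Terms of order T2e/(1 + omega_e^2 T2e^2) are negligible at W-band and are
#' not carried.
#'
#' @param a_perp Perpendicular hyperfine coupling (Hz, cyclic frequency).
#' @param S Electron spin quantum number.
#' @param T1e Electron spin-lattice relaxation time (s).
#' @param omega_I Nuclear Larmor angular frequency (rad/s).
#' @return Predicted T2n (s).
#' @examples
#' sbm_t2n(70e3, 7/2, 143e-6, 2 * pi * 136.4e6)  # ~8.6 ns
#' @export
sbm_t2n <- function(a_perp, S, T1e, omega_I) {
  stopifnot(all(a_perp > 0), all(S > 0), all(T1e > 0), all(omega_I > 0))
  rate <- (2 * pi * a_perp)^2 * S * (S + 1) / 15 *
    (4 * T1e + 3 * T1e / (1 + omega_I^2 * T1e^2))
  1 / rate
}

#' Slow-relaxation-limit nuclear coherence time
#'
#' When 1/T1e << a_perp the doublet stays resolved and each component decays
#' with 1/T2n = 1/(2 T1e), i.e. T2n = 2 T1e exactly.
#'
#' @param T1e Electron spin-lattice relaxation time (s). Vectorised.
#' @return Predicted T2n (s).
#' @export
slow_limit_t2n <- function(T1e) {
  stopifnot(all(T1e > 0))
  2 * T1e
}

#' Classify the electron-relaxation regime relative to the hyperfine coupling
#'
#' "fast" when 1/T1e exceeds `factor` times a_perp, "slow" when it is below
#' a_perp/`factor`, "intermediate" otherwise (where no closed-form lineshape
#' theory is available).
#'
#' @param a_perp Hyperfine coupling (Hz).
#' @param T1e Electron spin-lattice time (s).
#' @param factor Order-of-magnitude threshold for ">>"; default 10.
#' @return One of `"fast"`, `"slow"`, `"intermediate"` (vectorised).
#' @export
classify_regime <- function(a_perp, T1e, factor = 10) {
  stopifnot(all(a_perp > 0), all(T1e > 0), factor > 1)
  rate <- 1 / T1e
  out <- rep("intermediate", length(rate))
  out[rate > factor * a_perp] <- "fast"
  out[rate < a_perp / factor] <- "slow"
  out
}

#' Theory predictions for one (a_perp, T1e) condition
#'
#' @inheritParams sbm_t2n
#' @param factor Regime threshold passed to [classify_regime()].
#' @return A list of class `theory_prediction`: `t2n_sbm`, `t2n_slow` (s),
#'   `regime`, and the diagnostic `ratio` = a_perp * T1e.
#' @export
theory_prediction <- function(a_perp, S, T1e, omega_I, factor = 10) {
  structure(
    list(
      t2n_sbm = sbm_t2n(a_perp, S, T1e, omega_I),
      t2n_slow = slow_limit_t2n(T1e),
      regime = classify_regime(a_perp, T1e, factor),
      ratio = a_perp * T1e
    ),
    class = "theory_prediction"
  )
}

#' Largest distance resolvable from the ENDOR doublet splitting
#'
#' Inverts the point-dipole relation at a given decoherence rate: the doublet
#' splitting 2 a_perp(r)/... remains resolvable while a_perp(r) exceeds the
#' intrinsic linewidth 1/T2n, so the bound is the r solving
#' a_perp(r) = rate, i.e. r = (K / rate)^(1/3) with K the dipolar constant.
#' At the 8 kHz end of the observed 19F decoherence-rate range this gives
#' about 21 Angstrom.
#'
#' @param rate Nuclear decoherence rate 1/T2n (Hz, > 0). Vectorised.
#' @param nucleus A [nucleus_spec()].
#' @param ge Electron g-value.
#' @return Distance (Angstrom).
#' @export
max_resolvable_distance <- function(rate, nucleus = nucleus_spec("19F"),
                                    ge = 1.992) {
  stopifnot(all(rate > 0))
  K <- a_perp_from_distance(1, nucleus, ge)  # Hz * Angstrom^3
  (K / rate)^(1 / 3)
}

#' Relative ENDOR sensitivity penalty between two distances
#'
#' ENDOR efficiency falls off as r^-6, so measuring at `r2` instead of `r1`
#' costs a factor (r2/r1)^6 in signal; this returns that penalty factor.
#'
#' @param r1 Reference distance (Angstrom).
#' @param r2 Target distance (Angstrom).
#' @return (r2/r1)^6, the SNR penalty at `r2` relative to `r1`.
#' @export
endor_snr_scaling <- function(r1, r2) {
  stopifnot(all(r1 > 0), all(r2 > 0))
  (r2 / r1)^6
}
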