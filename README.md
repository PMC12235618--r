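# fendor

Simulation and analysis of powder ^19^F/^1^H ENDOR spectra of Gd(III) spin
labels and of the nuclear decoherence that limits their resolution.

## Who this is for

Pulsed-EPR/ENDOR spectroscopists using Gd(III) labels for short-range
(10–20 Å) distance measurements in biomolecules, and anyone modelling
nuclear spin relaxation near a slowly relaxing paramagnetic centre. The
package provides, as tested reusable components:

* **Powder ENDOR forward model + fit** — central-transition doublet
  ν = ν_I ∓ a/2 with a purely dipolar, orientation-dependent splitting
  a(θ) = (3cos²θ − 1)·μ₀g_eμ_Bg_nμ_N/(4πhr³), optional ^19^F chemical-shift
  anisotropy (traceless tensor δxx, δyy, δzz with Gd–F orientation angles
  γ, ρ), hemispheric powder averaging, Mims blind-spot weighting, Gaussian
  convolution; nonlinear least-squares fitting (NL2SOL via
  `nls(algorithm = "port")`) of distance, CSA orientation and linewidth with
  covariance-based 1σ uncertainties.
* **Relaxation analysis** — stretched-exponential recovery fits
  I = I₀(1 − A·exp[−(t/T₁ₑ)^β]), first-moment averaging
  T̄₁ₑ = (T₁ₑ/β)Γ(1/β), mono/biexponential nuclear-spin-echo decay fits
  I ∝ exp(−2τ_RF/T₂ₙ), and the rate–rate regression 1/T₂ₙ vs 1/T̄₁ₑ.
* **Decoherence theories** — the Solomon–Bloembergen–Morgan fast-relaxation
  limit and the slow-relaxation limit T₂ₙ = 2T₁ₑ, regime classification, and
  the resolution bound r_max = (K/rate)^⅓ with its r⁻⁶ sensitivity penalty.
* **Synthetic data** — seeded generators for every input the pipeline
  consumes (recovery traces, ^19^F/^1^H NSE decays, noisy spectra), plus
  plain-text TSV trace/spectrum I/O and a YAML-configured pipeline with CLI.

## Worked example

Distance from a noisy synthetic powder doublet (13.3 Å ground truth, 2%
noise, fit started at 10 Å):

```r
library(fendor)
a_perp_from_distance(13.3) / 1e3   # perpendicular coupling, kHz
#> [1] 31.47049

acq <- acquisition_params(lw_fwhm = 15e3)          # tau = 2 us, 136.4 MHz
sp  <- gen_spectrum(spin_system(13.3), NULL, acq, noise_frac = 0.02, seed = 7)
fit_spectrum(sp, spin_system(10), NULL, acq = acq)
#> <spectrum_fit>
#>   r_GdF          13.2901 +/- 0.00742
#>   gamma                0 +/- 0 (fixed)
#>   rho                  0 +/- 0 (fixed)
#>   lw_fwhm        15096.6 +/- 95.4
#>   amplitude     0.968612 +/- 0.00253
#>   residual norm 0.389
```

The fitted distance (13.290 ± 0.007 Å) recovers the ground truth; the
linewidth absorbs the RF excitation bandwidth.

End-to-end decoherence mechanism test — generate recovery + NSE traces at
3.7–10 K (electron rates 7–22 kHz, 2% noise), fit everything, regress:

```r
cfg <- default_config()
cfg$spectrum_enabled <- FALSE
cfg$regression$through_origin <- TRUE   # slow limit fixes the intercept at 0
rep <- run_full_analysis(cfg)
rep$relaxation[, c("temperature_K", "inv_T1e_bar_khz", "inv_T2n_khz")]
#>   temperature_K inv_T1e_bar_khz inv_T2n_khz
#> 1           3.7         6.87170    3.410828
#> 2           5.0        10.07386    4.962604
#> 3           7.0        15.20213    7.355904
#> 4          10.0        20.71451   10.740996
rep$regression$slope
#> [1] 0.5040813
```

The slope of 0.504 ± 0.009 reproduces the ½ predicted when nuclear
decoherence is driven by electron spin–lattice flips (T₂ₙ = 2T̄₁ₑ): each
fitted 1/T₂ₙ sits at half the fitted electron rate.

Theory check at the same operating point:

```r
sbm_t2n(70e3, 7/2, 143e-6, 2 * pi * 136.4e6)  # fast-limit prediction: ~8.6 ns
max_resolvable_distance(8e3)                  # ~21 A at an 8 kHz rate
```

The fast-relaxation (SBM) limit predicts nanosecond coherence — orders of
magnitude below the observed ~100–800 µs — confirming the system sits in the
slow-relaxation regime where the doublet stays resolved.

## Command line

```sh
Rscript inst/cli/fendor simulate --config inst/extdata/default_config.yml \
    --seed 7 --out run1/
Rscript inst/cli/fendor fit-trace run1/nse19f_10K.tsv --window-max-us 200
Rscript inst/cli/fendor analyze --config inst/extdata/default_config.yml \
    --out run1/
```

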