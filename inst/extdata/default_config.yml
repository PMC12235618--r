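# Default fendor analysis configuration.
# Physical defaults live here, not in code: W-band (3.40 T) Larmor
# frequencies, Gd(III) ge, the 7-22 kHz electron-rate span over 3.7-10 K.
seed: 1
temperatures: [3.7, 5.0, 7.0, 10.0]
# 1/T1e_bar = c * T^n (Hz); omit to auto-calibrate to 7 kHz @ 3.7 K and
# 22 kHz @ 10 K.
beta: 0.8
noise_frac: 0.02
nse_window_us: 200
spin_system:
  nucleus: 19F
  nu_ref: 136400000.0  # Hz; 144900000.0 for 1H at the same field
  r_GdF: 13.3          # Angstrom
  S: 3.5
  ge: 1.992
acquisition:
  tau_ns: 2000
  lw_khz: 15
  grid_xi: 121
  grid_phi: 241
  mims_weighting: true
regression:
  through_origin: false
spectrum_enabled: true
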