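# Default run configuration: the printed instrument constants and the two
# reference dFON families. Any key may be overridden; unknown keys are
# rejected at load time.
instrument:
  wavelength_nm: 1030
  rep_rate_hz: 8.0e+7
  pulse_tau_s: 1.35e-13          # sech2 pulse parameter tau (135 fs)
  waist_nm: 360                  # infrared waist W0; PSF sigma = W0/sqrt(2)
  collection_efficiency: 0.8
  tau_interpretation: sech2
  calibration_psat_mW: 17.3      # reference pair fixing the geometry factor
  calibration_alpha2_sigma2_GM: 710

species:
  - name: dFONs1
    sigma2_GM: 60
    phi: 0.33
    diameter_nm: 29
    n_molecules: 7500
    tau_b0_s: 1.06
    psat_mW: 17.3
    size_modes_nm: [15, 50]
    size_sds_nm: [3, 15]
    size_weights: [0.5, 0.5]
  - name: dFONs2
    sigma2_GM: 930
    phi: 0.06
    diameter_nm: 20
    n_molecules: 2100
    tau_b0_s: 3.84
    psat_mW: 5.29
    size_modes_nm: [20]
    size_sds_nm: [3]
    size_weights: [1.0]

generator:
  scan_particles: 20
  scan_width_px: 100
  scan_height_px: 100
  pixel_nm: 100                  # 100 nm x 100 nm pixels
  dwell_s: 0.010                 # 10 ms per pixel
  scan_power_mW:                 # per-family scan powers
    dFONs1: 1.7
    dFONs2: 1.6
  background_rate: 100           # counts/s
  aggregate_fraction: 0.1
  detection_scale: 8.0e-5        # overall detection throughput
  sweep_powers_mW: [1, 3.8, 6.6, 9.4, 12.1, 14.9, 17.7, 20.5, 23.3, 26.1,
                    28.9, 31.6, 34.4, 37.2, 40]
  sweep_dwell_s: 1
  sweep_peak_rate: 1.0e+5         # asymptotic counts/s per particle
  n_sweeps: 20
  bleach_traces_per_power: 10
  bleach_bin_s: 0.010
  bleach_s0_rate: 1.0e+5

analysis:
  threshold_sigma: 5
  min_separation_nm: 600
  window_px: 7
  aggregate_tolerance: 0.3
  t_test_var_equal: false
  fit_background: true

seed: 1
output_dir: dfonphot-output
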