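# dfonphot

Single-particle two-photon photophysics of dye-based fluorescent organic
nanoparticles (dFONs), for microscopists and probe designers who need to
turn raw photon-counting data — raster scans, power sweeps, bleaching time
traces — into per-particle brightness statistics, local-field-corrected
two-photon absorption cross sections, and photobleaching constants.

dFONs are self-assembled aggregates of hydrophobic dyes whose two-photon
brightness `B_2P = σ₂·Φ·N` (per-molecule cross section × quantum yield ×
molecules per particle) reaches ~10⁵ GM. The package implements the
forward model and the three-stage inference around it:

* **Photophysics core.** Pulse-train rate-equation emission: during each
  rectangular model pulse (width `δt = 2τ` for a sech² pulse of parameter
  `τ`) a molecule is excited at rate
  `Γ_exc = ½·α²σ₂·[κ·P·T/δt / (ħω·πW₀²)]²`, giving the detected rate
  `R(P) = η·N·Φ·(1/T)·(1 − exp(−Γ_exc·δt))` and hence the saturation
  curve `F(P) = 1 − exp(−P²/P_sat²)`. Inverting the saturation condition
  `Γ_exc(P_sat)·δt = 1` converts a fitted saturation power into the
  combined cross section `α²σ₂`; dividing by the ensemble per-molecule σ₂
  isolates the local-field coefficient `α` (Lorentz estimate
  `((n²+2)/3)²`). Photobleaching follows the inverse-square law
  `τ_b = τ_b,0·(P_sat/P)²`.
* **Scan analysis.** Spot detection (median/MAD threshold, non-maximum
  suppression), 2D Gaussian PSF fits with Poisson weights, `P²`-normalized
  brightness in kcounts·s⁻¹·mW⁻², aggregate flagging, population
  statistics and Welch/Student comparisons.
* **Trace analysis.** Poisson-weighted saturation and monoexponential
  decay fits, ensemble averaging of normalized sweeps, cross-section
  derivation with first-order error propagation, and the bleaching
  power-law fit (P_sat supplied from the saturation stage — the two
  constants are degenerate in a pure power law) plus the log-log slope −2
  check.
* **Synthetic microscope.** Seeded generators for scans, sweeps and decay
  traces with Poisson photon statistics, volume-proportional brightness,
  bimodal/unimodal size mixtures, rare aggregates, and full ground-truth
  sidecars — the validation bed for every estimator.

## Worked example

```r
library(dfonphot)

instr <- default_instrument()   # 1030 nm, 80 MHz, 135 fs, W0 = 360 nm
sp2 <- dfon_species("dFONs2")   # σ₂ = 930 GM, Φ = 0.06, N = 2100

# one particle's saturation sweep, 15 powers spanning 0.5-15 mW
tr <- generate_saturation_sweep(seq(0.5, 15, length.out = 15), sp2,
                                seed = 1)
fit <- fit_saturation(tr)
fit
#> Saturation fit: P_sat = 5.28 +/- 0.0086 mW, asymptote = 9.99e+04 cps (n = 15)

derive_cross_section(fit, instr, sp2$sigma2_GM)
#> alpha^2 sigma2 = 7.62e+03 GM (P_sat = 5.28 mW), alpha = 2.86

# bleaching pipeline: 5 powers around P_sat, 5 traces each
law <- recover_bleach_law(sp2, traces_per_power = 5, seed = 1)
law
#> Bleaching law: tau_b0 = 3.82 +/- 0.00074 s at P_sat = 5.29 mW; log-log slope -2.001 +/- 0.001
```

The fitted saturation power (5.28 mW) matches the 5.29 mW ground truth of
the generator; the derived `α²σ₂ ≈ 7.6×10³ GM` and `α ≈ 2.9` are the
local-field-corrected cross section and correction factor for this family.
The bleaching stage recovers `τ_b,0 = 3.82 s` against a generating value
of 3.84 s, with the expected −2 power-law slope. A full on-disk experiment
(TIFF scans with JSON ground-truth sidecars, CSV traces) runs through
`simulate_experiment()` / `analyze_experiment()` from a validated YAML
config (`read_config()`), and
`inst/scripts/dfonphot-cli.R` exposes `simulate` / `analyze` / `reproduce`
subcommands.

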