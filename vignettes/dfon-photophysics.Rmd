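---
title: "Modelling single-particle two-photon saturation and photobleaching of dye-based organic nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-particle two-photon saturation and photobleaching of dye-based organic nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfonphot)
```

## The system and the model

Dye-based fluorescent organic nanoparticles (dFONs) are self-assembled
aggregates of hydrophobic dye molecules, typically 15-50 nm in dry diameter,
used as ultrabright probes for nonlinear microscopy and single-particle
tracking. A particle of diameter $d$ packs
$N = \rho \frac{\pi}{6} d^3 N_A / M$ dye molecules (density $\rho$ relative
to water, molar mass $M$), so its two-photon brightness
$B_{2P} = \sigma_2 \Phi N$ scales with volume: $\sigma_2$ is the two-photon
absorption cross section per molecule (in Goeppert-Mayer units,
$1\,\mathrm{GM} = 10^{-50}\,\mathrm{cm^4\,s\,photon^{-1}}$) and $\Phi$ the
fluorescence quantum yield. The package ships two reference families with
deliberately matched brightness: family 1 ($\sigma_2 = 60$ GM,
$\Phi = 0.33$, $N = 7500$, $B_{2P} \approx 1.5\times10^5$ GM) and family 2
($\sigma_2 = 930$ GM, $\Phi = 0.06$, $N = 2100$,
$B_{2P} \approx 1.2\times10^5$ GM).

### Pulse-train emission and saturation

Excitation is a femtosecond pulse train (wavelength $\lambda = 1030$ nm,
repetition period $T = 12.5$ ns, sech$^2$ pulse parameter
$\tau = 135$ fs). We model each pulse as a rectangle of equal integral,
$\delta t = 2\tau = 270$ fs (an option reinterprets $\tau$ as the intensity
FWHM, for which the equal-integral width is $2\tau/1.7627$). During the
pulse a ground-state molecule is excited at rate

$$\Gamma_\mathrm{exc} = \tfrac{1}{2}\,\alpha^2\sigma_2
  \left[\frac{\kappa\, P_\mathrm{exc} T/\delta t}
       {\hbar\omega\, \pi W_0^2}\right]^2 ,$$

where $P_\mathrm{exc} T/\delta t$ is the peak power of the rectangular
pulse, $\hbar\omega$ the photon energy, $W_0$ the infrared beam waist
(360 nm; the fluorescence point-spread-function of a point emitter then has
Gaussian width $\sigma = W_0/\sqrt{2} \approx 255$ nm, because two-photon
excitation squares the illumination profile), $\alpha$ the local-field
correction discussed below, and the factor $\tfrac12$ accounts for the two
infrared photons consumed per excitation event. In the regime
$\Gamma_\mathrm{exc} \gg \Gamma$ (excitation much faster than emission
during the pulse) with full relaxation between pulses
($1/\Gamma \ll T$), each molecule emits at most one photon per pulse with
probability $1 - e^{-\Gamma_\mathrm{exc}\delta t}$, so the detected rate of
a particle is

$$R(P) = \eta\, N\, \Phi\, \frac{1}{T}
  \left(1 - e^{-\Gamma_\mathrm{exc}(P)\,\delta t}\right),$$

with collection efficiency $\eta \approx 0.8$. Because
$\Gamma_\mathrm{exc} \propto P^2$, the normalized signal is exactly the
saturation curve

$$F(P) = 1 - \exp\!\left(-P^2/P_\mathrm{sat}^2\right),$$

where the saturation power $P_\mathrm{sat}$ is defined by
$\Gamma_\mathrm{exc}(P_\mathrm{sat})\,\delta t = 1$. Inverting this
condition links the fitted $P_\mathrm{sat}$ to the combined cross section:

$$\alpha^2\sigma_2 = \frac{2\,\delta t\,(\hbar\omega\,\pi W_0^2/\kappa)^2}
                          {T^2 P_\mathrm{sat}^2}.$$

The tests verify that the closed-form per-pulse excitation probability
agrees with a direct numerical integration of the ground-state rate
equation over the pulse to better than $10^{-6}$ relative error, and that
`pulse_train_emission()` normalized by its asymptote reproduces $F(P)$ to
machine precision.

### The geometry factor $\kappa$

The inverse-square relation between $P_\mathrm{sat}$ and $\alpha^2\sigma_2$
is convention-free, but the absolute prefactor depends on how the focal
"beam area" is defined (e.g. $1/e$ vs $1/e^2$ radius). We therefore write
the peak flux with effective area $\pi W_0^2$ and a single dimensionless
factor $\kappa$, calibrated once so that the family-1 reference pair
($P_\mathrm{sat} = 17.3$ mW $\rightarrow$ $\alpha^2\sigma_2 = 710$ GM)
holds with the printed instrument constants. The calibrated value is
$\kappa \approx 1.0014$, i.e. the $\pi W_0^2$ convention reproduces the
reference almost exactly. $\kappa$ is stored in the instrument object and
echoed in all result provenance. With this single calibration, the
family-2 saturation power 5.29 mW predicts $\alpha^2\sigma_2 \approx
7.59\times10^3$ GM, within 0.2% of the independently reported value — the
scientifically meaningful check, since it tests only the inverse-square
law.

### Local-field correction

Inside a dielectric particle a molecule experiences a local field different
from the incident one; the Lorentz virtual-cavity estimate of the intensity
correction is $\alpha = ((n^2+2)/3)^2$, between about 2 ($n = 1.5$) and 13
($n = 3$, near an absorption resonance). Comparing the saturation-derived
$\alpha^2\sigma_2$ with the per-molecule $\sigma_2$ measured on molecular
ensembles isolates $\alpha = \sqrt{\alpha^2\sigma_2/\sigma_2}$, giving
$\approx 3.4$ and $\approx 2.9$ for the two families — inside the Lorentz
range, though a single Lorentz factor cannot be expected to explain the
values exactly, because the ensemble $\sigma_2$ and $\Phi$ measurements
carry their own environment-dependent corrections. The package computes
$\alpha$ but deliberately implements no quantitative model beyond the
Lorentz bound.

### Photobleaching law

Under continuous excitation a particle's fluorescence decays
monoexponentially with characteristic time $\tau_b$. Across powers,

$$\tau_b = \tau_{b,0}\left(\frac{P_\mathrm{sat}}{P_\mathrm{exc}}\right)^2,$$

an inverse-square law (slope $-2$ in log-log) whose constant $\tau_{b,0}$
is the bleaching time at $P_\mathrm{sat}$. In a pure power-law fit
$\tau_{b,0}$ and $P_\mathrm{sat}$ are perfectly degenerate — only
$\tau_{b,0}P_\mathrm{sat}^2$ is identifiable — so `fit_bleach_law()`
always takes $P_\mathrm{sat}$ from the saturation stage and never co-fits
it. Consequently the photostability of two families at any common power
compares as $(\tau_{b,0,1}P_{\mathrm{sat},1}^2) /
(\tau_{b,0,2}P_{\mathrm{sat},2}^2)$; for the reference constants
(1.06 s, 17.3 mW) vs (3.84 s, 5.29 mW) this ratio is 2.95 — family 1 is
about three times more photostable despite family 2's larger $\tau_{b,0}$,
because its saturation power is much higher.

## The synthetic microscope

The generator produces the three raw-data types the pipeline consumes,
with Poisson photon statistics throughout and a ground-truth sidecar for
every object. It emulates the statistical structure the analysis relies
on, not the optics: spots are ideal 2D Gaussians (no aberrations,
no z-sectioning), the detector is ideal apart from a constant background
rate (no dead time or afterpulsing), and bleaching is strictly
monoexponential.

**Scans.** Particles are placed uniformly in the field; diameters are drawn
from truncated-normal mixtures mirroring the TEM size histograms: family 1
bimodal with a narrow mode at 15 nm (spread 3 nm) and a broad mode at
50 nm (spread 15 nm, equal weight), family 2 unimodal at 20 nm (spread
3 nm). The mode spreads are generator defaults — the sources report only
mode centres — chosen so the 50 nm mode carries more than an order of
magnitude more mean volume than the 15 nm mode, which is why the small
mode is effectively invisible in emission. Molecule numbers follow the
volume law with molar masses derived from the reference (diameter, $N$)
pairs: 1025 g/mol and 1201 g/mol. Peak rates come from the pulse-train
model times a `detection_scale` throughput factor (default $8\times10^{-5}$)
that lumps detector quantum efficiency and spectral filtering beyond the
stated 80% collection into one constant, set once so a 50 nm family-1
particle at the 1.7 mW scan power peaks near 620 kcounts/s — the
few-hundred-kcounts/s regime of real photon-counting scans. A default 10%
of spots are aggregates (2-4 particles co-located within half a PSF),
which produces the long right tail that drags population means far above
medians. Default raster: 100 nm pixels, 10 ms dwell.

**Saturation sweeps.** Expected counts per power point are
$\mathrm{dwell} \times [\mathrm{bg} + A\,F(P)]$ with the asymptotic rate
$A$ a per-particle parameter (default $10^5$ counts/s). An option
accumulates bleaching attenuation over the sweep in acquisition order; it
is off by default, matching an uncorrected measurement protocol.

**Bleach traces.** Binned counts with expectation equal to the exact
integral of $S_0 e^{-t/\tau_b}$ over each bin plus background; default
10 ms bins and a duration of $3.5\,\tau_b$ (a warning fires below
$3\,\tau_b$).

Passing tests on these data demonstrate that the estimators are correct
and well-calibrated under the stated model; they cannot certify behaviour
under real-data pathologies the generator omits (drift, aggregate
substructure, non-exponential bleaching, detector nonlinearity).

## Analysis stages and numerical choices

**Scan stage.** Spot detection is a local-maximum search above
$\mathrm{median} + k\,\mathrm{MAD}$ ($k = 5$ by default) with greedy
non-maximum suppression at 600 nm. Each candidate is fitted with
`offset + A exp(-((x-x_0)^2+(y-y_0)^2)/2s^2)` by Levenberg-Marquardt with
Poisson weights $1/(y+1)$; the symmetric model is the default and an
anisotropic variant supports aggregate flagging (width deviating more than
30% from $W_0/\sqrt2$, or comparable anisotropy). The brightness of a spot
is the fitted amplitude above offset — not the brightest raw pixel —
normalized by $P_\mathrm{exc}^2$ and reported in kcounts s$^{-1}$
mW$^{-2}$; in the non-saturated regime this normalization makes
measurements at different powers directly comparable. Population summaries
use the linear-interpolation quartile convention (type 7), and the
two-sample comparison defaults to the Welch $t$-test (brightness
distributions are visibly heteroscedastic), with the pooled-variance
Student variant as an option. Aggregate-flagged spots stay in the
brightness table — the reported means intentionally include them — and are
excluded only from PSF-width quality control.

**Saturation stage.** Per-sweep fits minimize Poisson-weighted squared
residuals of $A(1-e^{-P^2/P_\mathrm{sat}^2})$; start values come from the
quadratic low-power slope and the maximum count, and degenerate sweeps
(flat, or entirely below the inflection) warn that $P_\mathrm{sat}$ is
poorly constrained. The ensemble estimate normalizes each sweep by its own
fitted asymptote, interpolates onto a common grid, and fits the mean
curve; both the ensemble fit and the per-particle fits are reported, since
either could legitimately produce a family-level $P_\mathrm{sat}$.
Uncertainty propagates to the derived quantities at first order: the
relative standard error of $\alpha^2\sigma_2$ is twice that of
$P_\mathrm{sat}$, and that of $\alpha$ equals it.

**Bleaching stage.** Per-trace fits of $S_0 e^{-t/\tau_b} + bg$ use the
same Poisson weighting; traces showing no decay are rejected with a reason
rather than returning an unbounded $\tau_b$. A free background is the
default (robust for measured data); for synthetic traces generated without
background the matched no-background fit is the calibrated estimator, and
the error-calibration test uses it. Fitted times are aggregated by power
(mean and across-particle SD — the error bars represent particle-to-particle
scatter, not fit errors), and the power law is fitted linearly in
$\tau_{b,0}$ with inverse-variance weights, alongside an unconstrained
log-log regression whose slope checks the $-2$ exponent.

## Problem sizes and reproducibility

All generators accept a seed and are exactly reproducible for a fixed
seed, including byte-identical files from `simulate_experiment()`. The
validation suite uses problem sizes a desk machine handles in seconds:
50-200 replicate sweeps of 15 points for saturation recovery, 5 powers
$\times$ 10 traces for the bleaching pipeline, and 40-120 pixel scan
fields; these sizes give Monte-Carlo standard errors comfortably below the
tolerances being checked (e.g. the mean recovered $P_\mathrm{sat}$ over 50
sweeps has a standard error near 0.05%, far under the 5% acceptance
band).

## Known limitations

* The absolute cross-section scale rests on the $\kappa$ calibration pair;
  only cross-section *ratios* between conditions are calibration-free.
* The radiative rate $\Gamma$ is not measured here; the default 2 ns
  lifetime enters only the validity checks of the
  $\Gamma_\mathrm{exc} \gg \Gamma$ and $1/\Gamma \ll T$ assumptions, and
  results do not depend on it in the implemented limit.
* Triplet states, reactive-oxygen chemistry and heating are outside the
  model: the bleaching law is empirical-quadratic, with no mechanistic
  term.
* $\sigma_2$ is treated as a scalar at the excitation wavelength; no
  spectral dependence is modelled.
* Scans are single frames: no drift correction or registration.

## A minimal session

```{r example, eval = FALSE}
instr <- default_instrument()
sp2 <- dfon_species("dFONs2")

# simulate one particle's saturation sweep and recover P_sat
tr <- generate_saturation_sweep(seq(0.5, 15, length.out = 15), sp2,
                                seed = 1)
fit_saturation(tr)

# bleaching pipeline at five powers
law <- recover_bleach_law(sp2, traces_per_power = 10, seed = 1)
law$tau_b0_s       # ~3.84 s
law$loglog_slope   # ~-2

# full synthetic experiment on disk
cfg <- read_config()
simulate_experiment(cfg, "run1")
res <- analyze_experiment(cfg, "run1")
res$comparison$photostability_ratio
```
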