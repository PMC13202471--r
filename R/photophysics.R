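#' Energy of a single photon
#'
#' @param wavelength_nm Wavelength (nm); vectorized.
#' @return Photon energy h*c/lambda in joules.
#' @examples
#' photon_energy(1030)   # ~1.93e-19 J, one infrared photon
#' @export
photon_energy <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || any(wavelength_nm <= 0)) {
    stop("wavelength_nm must be positive")
  }
  .PLANCK_H * .SPEED_C / (wavelength_nm * 1e-9)
}

#' Lorentz local-field correction factor
#'
#' Intensity correction experienced by a molecule embedded in a dielectric of
#' refractive index `n`, in the Lorentz (virtual cavity) model:
#' `alpha = ((n^2 + 2) / 3)^2`. For pure organic dye solids `n` ranges from
#' about 1.5 to 1.8, and up to ~3 near an absorption resonance, so alpha
#' spans roughly 2 to 13.
#'
#' @param n Refractive index, `n >= 1`; vectorized.
#' @return Dimensionless factor alpha, `>= 1`.
#' @examples
#' lorentz_local_field(c(1, 1.5, 3))   # 1, ~2.0, ~13.4
#' @export
lorentz_local_field <- function(n) {
  if (!is.numeric(n) || any(n < 1)) stop("refractive index must be >= 1")
  ((n^2 + 2) / 3)^2
}

#' Two-photon fluorescence saturation curve
#'
#' Normalized fluorescence of a two-photon-excited emitter under a pulsed
#' laser as a function of average excitation power:
#' `F(P) = 1 - exp(-P^2 / P_sat^2)`. At low power the response is quadratic
#' in `P` (the two-photon regime); at the saturation power the per-pulse
#' excitation probability reaches `1 - 1/e`.
#'
#' @param p_exc Average excitation power (same units as `p_sat`), `>= 0`;
#'   vectorized.
#' @param p_sat Saturation power, `> 0`.
#' @return Normalized fluorescence in `[0, 1)`.
#' @examples
#' saturation_curve(17.3, 17.3)        # 1 - 1/e
#' saturation_curve(c(0, 1, 40), 17.3)
#' @export
saturation_curve <- function(p_exc, p_sat) {
  if (!is.numeric(p_sat) || length(p_sat) != 1L || p_sat <= 0) {
    stop("p_sat must be a positive scalar")
  }
  if (!is.numeric(p_exc) || any(p_exc < 0)) stop("p_exc must be >= 0")
  1 - exp(-(p_exc / p_sat)^2)
}

#' Two-photon excitation rate during the pulse
#'
#' Excitation rate of one molecule during the rectangular model pulse:
#' `Gamma_exc = 1/2 * alpha^2 sigma2 * phi_peak^2`, where `phi_peak =
#' kappa * P_peak / (hbar omega * pi * W0^2)` is the peak photon flux density
#' (photons / cm^2 / s), `P_peak = P_exc * T / dt` the peak power of the
#' rectangular pulse, and the factor 1/2 accounts for two infrared photons
#' consumed per excitation event.
#'
#' @param p_exc_mW Average excitation power (mW), `>= 0`; vectorized.
#' @param instrument An [instrument_params()] object.
#' @param alpha2_sigma2_GM Combined local-field-corrected cross section
#'   `alpha^2 * sigma2` (GM).
#' @return Excitation rate during the pulse (1/s).
#' @examples
#' instr <- default_instrument()
#' # at P_sat the per-pulse excitation probability is 1 - 1/e:
#' excitation_rate(17.3, instr, 710) * instr$rect_pulse_dt_s  # = 1
#' @export
excitation_rate <- function(p_exc_mW, instrument, alpha2_sigma2_GM) {
  stopifnot(inherits(instrument, "instrument_params"))
  if (!is.numeric(p_exc_mW) || any(p_exc_mW < 0)) stop("p_exc_mW must be >= 0")
  if (!is.numeric(alpha2_sigma2_GM) || alpha2_sigma2_GM <= 0) {
    stop("alpha2_sigma2_GM must be positive")
  }
  e_ph <- photon_energy(instrument$wavelength_nm)          # J
  area_cm2 <- pi * (instrument$waist_nm * 1e-7)^2          # cm^2
  p_peak_w <- p_exc_mW * 1e-3 *
    instrument$rep_period_s / instrument$rect_pulse_dt_s   # W
  flux <- instrument$geometry_factor * p_peak_w / (e_ph * area_cm2)
  0.5 * alpha2_sigma2_GM * .GM_CM4S * flux^2
}

#' Combined cross section from the saturation power
#'
#' Inverts the saturation condition `Gamma_exc(P_sat) * dt = 1`:
#' `alpha^2 sigma2 = 2 dt (hbar omega * pi W0^2 / kappa)^2 / (T^2 P_sat^2)`.
#' Strictly decreasing in `P_sat` (inverse-square), and the exact inverse of
#' [psat_from_cross_section()].
#'
#' @param p_sat_mW Saturation power (mW), `> 0`; vectorized.
#' @param instrument An [instrument_params()] object (its `geometry_factor`
#'   sets the absolute scale; see [calibrate_geometry_factor()]).
#' @return Combined cross section `alpha^2 * sigma2` (GM).
#' @examples
#' instr <- default_instrument()
#' cross_section_from_psat(17.3, instr)   # 710 GM by calibration
#' cross_section_from_psat(5.29, instr)   # ~7590 GM
#' @export
cross_section_from_psat <- function(p_sat_mW, instrument) {
  stopifnot(inherits(instrument, "instrument_params"))
  if (!is.numeric(p_sat_mW) || any(p_sat_mW <= 0)) {
    stop("p_sat_mW must be positive")
  }
  e_ph <- photon_energy(instrument$wavelength_nm)
  area_cm2 <- pi * (instrument$waist_nm * 1e-7)^2
  dt <- instrument$rect_pulse_dt_s
  tt <- instrument$rep_period_s
  2 * dt * (e_ph * area_cm2 / instrument$geometry_factor)^2 /
    (tt^2 * (p_sat_mW * 1e-3)^2) / .GM_CM4S
}

#' Saturation power from the combined cross section
#'
#' Forward direction of the saturation relation; exact inverse of
#' [cross_section_from_psat()].
#'
#' @param alpha2_sigma2_GM Combined cross section `alpha^2 * sigma2` (GM),
#'   `> 0`; vectorized.
#' @param instrument An [instrument_params()] object.
#' @return Saturation power (mW).
#' @examples
#' instr <- default_instrument()
#' psat_from_cross_section(710, instr)    # 17.3 mW
#' @export
psat_from_cross_section <- function(alpha2_sigma2_GM, instrument) {
  stopifnot(inherits(instrument, "instrument_params"))
  if (!is.numeric(alpha2_sigma2_GM) || any(alpha2_sigma2_GM <= 0)) {
    stop("alpha2_sigma2_GM must be positive")
  }
  e_ph <- photon_energy(instrument$wavelength_nm)
  area_cm2 <- pi * (instrument$waist_nm * 1e-7)^2
  dt <- instrument$rect_pulse_dt_s
  tt <- instrument$rep_period_s
  sqrt(2 * dt / (alpha2_sigma2_GM * .GM_CM4S)) *
    e_ph * area_cm2 / (instrument$geometry_factor * tt) * 1e3
}

#' Local-field coefficient from saturation and ensemble cross sections
#'
#' The combined cross section recovered from single-particle saturation is
#' `alpha^2 * sigma2`; dividing by the per-molecule cross section measured on
#' the molecular ensemble and taking the square root isolates the local-field
#' coefficient `alpha`.
#'
#' @param alpha2_sigma2_GM Saturation-derived combined cross section (GM).
#' @param sigma2_GM Ensemble per-molecule cross section (GM).
#' @return Dimensionless local-field coefficient alpha.
#' @examples
#' alpha_from_ensemble(710, 60)     # ~3.4
#' alpha_from_ensemble(7580, 930)   # ~2.9
#' @export
alpha_from_ensemble <- function(alpha2_sigma2_GM, sigma2_GM) {
  if (!is.numeric(alpha2_sigma2_GM) || any(alpha2_sigma2_GM <= 0) ||
      !is.numeric(sigma2_GM) || any(sigma2_GM <= 0)) {
    stop("cross sections must be positive")
  }
  sqrt(alpha2_sigma2_GM / sigma2_GM)
}

#' Two-photon brightness of a nanoparticle
#'
#' Per-particle two-photon brightness `B_2P = sigma2 * phi * N`: the product
#' of the per-molecule two-photon absorption cross section, the fluorescence
#' quantum yield and the number of dye molecules per particle.
#'
#' @param sigma2_GM Per-molecule cross section (GM).
#' @param phi Fluorescence quantum yield in (0, 1].
#' @param n_molecules Number of dye molecules per particle.
#' @return Brightness (GM per particle).
#' @examples
#' brightness_2p(60, 0.33, 7500)   # ~1.5e5
#' brightness_2p(930, 0.06, 2100)  # ~1.2e5
#' @export
brightness_2p <- function(sigma2_GM, phi, n_molecules) {
  if (!is.numeric(sigma2_GM) || any(sigma2_GM <= 0) ||
      !is.numeric(phi) || any(phi <= 0) ||
      !is.numeric(n_molecules) || any(n_molecules <= 0)) {
    stop("all arguments must be positive")
  }
  sigma2_GM * phi * n_molecules
}

#' Photobleaching time at a given excitation power
#'
#' Quadratic bleaching power law `tau_b = tau_b0 * (P_sat / P_exc)^2`:
#' the characteristic monoexponential bleaching time scales as the inverse
#' square of the excitation power (slope -2 in log-log), and `tau_b0` is its
#' value at `P_exc = P_sat`.
#'
#' @param p_exc Excitation power (same units as `p_sat`), `> 0`; vectorized.
#' @param p_sat Saturation power, `> 0`.
#' @param tau_b0 Bleaching constant (s), `> 0`.
#' @return Bleaching time (s).
#' @examples
#' bleaching_time(5.29, 5.29, 3.84)    # tau_b0
#' bleaching_time(10.58, 5.29, 3.84)   # tau_b0 / 4
#' @export
bleaching_time <- function(p_exc, p_sat, tau_b0) {
  if (!is.numeric(p_exc) || any(p_exc <= 0)) {
    stop("p_exc must be positive (infinite lifetime is out of model range)")
  }
  if (!is.numeric(p_sat) || p_sat <= 0 || !is.numeric(tau_b0) || tau_b0 <= 0) {
    stop("p_sat and tau_b0 must be positive")
  }
  tau_b0 * (p_sat / p_exc)^2
}

#' Detected emission rate of a nanoparticle under a pulse train
#'
#' Integrates the two-level rate equations over one repetition period in the
#' regime where the excitation rate during the pulse far exceeds the emission
#' rate (`Gamma_exc >> Gamma`) and the molecule fully relaxes between pulses
#' (`1 / Gamma << T`). Each molecule is excited at most once per pulse with
#' probability `1 - exp(-Gamma_exc * dt)`, giving a detected rate
#'
#' `R(P) = eta * N * phi * (1/T) * (1 - exp(-Gamma_exc(P) * dt))`,
#'
#' which grows quadratically at low power and saturates at `eta * N * phi / T`
#' (one photon per molecule per pulse, scaled by the quantum yield and the
#' collection efficiency).
#'
#' @param p_exc_mW Average excitation power (mW); vectorized.
#' @param instrument An [instrument_params()] object.
#' @param species A [species_params()] object (provides `N`, `phi`, `Gamma`).
#' @param alpha2_sigma2_GM Combined cross section (GM); defaults to the value
#'   implied by the species' `psat_mW` under the instrument calibration.
#' @return Detected count rate (counts/s).
#' @examples
#' instr <- default_instrument()
#' sp <- dfon_species("dFONs1")
#' r <- pulse_train_emission(c(1, 17.3, 200), instr, sp)
#' r[2] / r[3]   # ~ 1 - 1/e
#' @export
pulse_train_emission <- function(p_exc_mW, instrument, species,
                                 alpha2_sigma2_GM = NULL) {
  stopifnot(inherits(instrument, "instrument_params"),
            inherits(species, "species_params"))
  if (is.null(alpha2_sigma2_GM)) {
    if (is.na(species$psat_mW)) {
      stop("alpha2_sigma2_GM not given and species has no psat_mW")
    }
    alpha2_sigma2_GM <- cross_section_from_psat(species$psat_mW, instrument)
  }
  if (1 / species$gamma_rad_per_s >= instrument$rep_period_s) {
    warning("excited-state lifetime exceeds the repetition period; ",
            "the one-emission-per-pulse model is not valid")
  }
  g_exc <- excitation_rate(p_exc_mW, instrument, alpha2_sigma2_GM)
  p_excite <- 1 - exp(-g_exc * instrument$rect_pulse_dt_s)
  instrument$collection_efficiency * species$n_molecules * species$phi *
    p_excite / instrument$rep_period_s
}

#' Photostability ratio of two nanoparticle families
#'
#' Ratio of bleaching times of two families at any common excitation power.
#' Because `tau_b = tau_b0 * (P_sat / P)^2`, the common power cancels and the
#' ratio equals `(tau_b0_1 * P_sat1^2) / (tau_b0_2 * P_sat2^2)`.
#'
#' @param tau_b0_1,psat_1 Bleaching constant (s) and saturation power (mW) of
#'   family 1.
#' @param tau_b0_2,psat_2 Same for family 2.
#' @return Dimensionless ratio `tau_b,1 / tau_b,2` at equal excitation power.
#' @examples
#' photostability_ratio(1.06, 17.3, 3.84, 5.29)   # ~3
#' @export
photostability_ratio <- function(tau_b0_1, psat_1, tau_b0_2, psat_2) {
  if (any(c(tau_b0_1, psat_1, tau_b0_2, psat_2) <= 0)) {
    stop("all arguments must be positive")
  }
  (tau_b0_1 * psat_1^2) / (tau_b0_2 * psat_2^2)
}
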