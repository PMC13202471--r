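# Physical constants (CODATA 2018, exact SI definitions)
.PLANCK_H <- 6.62607015e-34   # J s
.SPEED_C <- 2.99792458e8      # m / s
.AVOGADRO <- 6.02214076e23    # 1 / mol
.GM_CM4S <- 1e-50             # 1 GM = 1e-50 cm^4 s / photon

#' Instrument parameters for pulsed two-photon excitation
#'
#' Bundles the laser and collection-optics constants that enter the
#' excitation-rate model and the synthetic data generator: excitation
#' wavelength, pulse-train timing, focal spot size and detection efficiency.
#'
#' The femtosecond pulse is modelled as a rectangle of duration
#' `rect_pulse_dt_s`. With `tau_interpretation = "sech2"` (default) the pulse
#' parameter `tau` is the characteristic duration of the sech^2 temporal
#' profile and the equal-integral rectangular width is `2 * tau`; with
#' `"fwhm"` the supplied `tau` is read as the intensity FWHM of a sech^2
#' pulse, for which the equal-integral width is `2 * tau / 1.7627`.
#'
#' `geometry_factor` (kappa) is the single dimensionless prefactor of the
#' peak-intensity expression `kappa * P_peak / (pi * W0^2)`; it absorbs the
#' beam-area convention and is normally set once by
#' [calibrate_geometry_factor()].
#'
#' @param wavelength_nm Excitation wavelength (nm).
#' @param rep_rate_hz Laser repetition rate (Hz); the repetition period is
#'   `1 / rep_rate_hz`.
#' @param pulse_tau_s Pulse duration parameter tau (s); see
#'   `tau_interpretation`.
#' @param waist_nm Beam waist W0 in the focal plane (nm). The fluorescence
#'   point-spread-function of a point emitter under two-photon excitation has
#'   Gaussian standard deviation `W0 / sqrt(2)`.
#' @param collection_efficiency Fraction of emitted photons reaching the
#'   detector, in (0, 1].
#' @param geometry_factor Dimensionless prefactor kappa of the peak-intensity
#'   expression (default 1; see [calibrate_geometry_factor()]).
#' @param tau_interpretation Either `"sech2"` or `"fwhm"`; how `pulse_tau_s`
#'   is converted to the rectangular-pulse width.
#' @return An object of class `instrument_params`: a list with fields
#'   `wavelength_nm`, `rep_period_s`, `pulse_tau_s`, `rect_pulse_dt_s`,
#'   `waist_nm`, `collection_efficiency`, `geometry_factor`,
#'   `tau_interpretation`.
#' @examples
#' instr <- instrument_params()        # 1030 nm, 80 MHz, 135 fs, 360 nm waist
#' instr$rect_pulse_dt_s               # 270 fs
#' @seealso [default_instrument()] for the calibrated default,
#'   [excitation_rate()], [cross_section_from_psat()]
#' @export
instrument_params <- function(wavelength_nm = 1030,
                              rep_rate_hz = 80e6,
                              pulse_tau_s = 135e-15,
                              waist_nm = 360,
                              collection_efficiency = 0.8,
                              geometry_factor = 1,
                              tau_interpretation = c("sech2", "fwhm")) {
  tau_interpretation <- match.arg(tau_interpretation)
  stopifnot(
    is.numeric(wavelength_nm), length(wavelength_nm) == 1L, wavelength_nm > 0,
    is.numeric(rep_rate_hz), rep_rate_hz > 0,
    is.numeric(pulse_tau_s), pulse_tau_s > 0,
    is.numeric(waist_nm), waist_nm > 0,
    is.numeric(collection_efficiency),
    collection_efficiency > 0, collection_efficiency <= 1,
    is.numeric(geometry_factor), geometry_factor > 0
  )
  rect_dt <- switch(tau_interpretation,
    sech2 = 2 * pulse_tau_s,
    # sech^2 pulse: equal-integral rectangle for an intensity FWHM t_f is
    # 2 * t_f / (2 * acosh(sqrt(2))) = t_f / 0.88137
    fwhm = 2 * pulse_tau_s / (2 * acosh(sqrt(2)))
  )
  rep_period <- 1 / rep_rate_hz
  if (rect_dt >= rep_period) {
    stop("rectangular pulse width must be shorter than the repetition period")
  }
  structure(
    list(
      wavelength_nm = wavelength_nm,
      rep_period_s = rep_period,
      pulse_tau_s = pulse_tau_s,
      rect_pulse_dt_s = rect_dt,
      waist_nm = waist_nm,
      collection_efficiency = collection_efficiency,
      geometry_factor = geometry_factor,
      tau_interpretation = tau_interpretation
    ),
    class = "instrument_params"
  )
}

#' Calibrate the geometry factor of the saturation-power relation
#'
#' The absolute prefactor of the excitation-rate expression depends on a
#' beam-area convention that is not pinned down by the inverse-square law
#' itself. This helper fixes the single dimensionless factor kappa so that a
#' reference saturation power maps to a reference combined cross section
#' `alpha^2 * sigma2` for the given instrument; the inverse-square scaling
#' between saturation powers is independent of kappa.
#'
#' @param instrument An [instrument_params()] object (its current
#'   `geometry_factor` is ignored).
#' @param psat_ref_mW Reference saturation power (mW).
#' @param alpha2_sigma2_ref_GM Reference combined cross section (GM) that
#'   `psat_ref_mW` must map to.
#' @return The instrument with `geometry_factor` replaced by the calibrated
#'   value.
#' @examples
#' instr <- calibrate_geometry_factor(instrument_params(), 17.3, 710)
#' instr$geometry_factor   # close to 1
#' @export
calibrate_geometry_factor <- function(instrument,
                                      psat_ref_mW = 17.3,
                                      alpha2_sigma2_ref_GM = 710) {
  stopifnot(inherits(instrument, "instrument_params"),
            psat_ref_mW > 0, alpha2_sigma2_ref_GM > 0)
  instrument$geometry_factor <- 1
  raw <- cross_section_from_psat(psat_ref_mW, instrument)
  instrument$geometry_factor <- sqrt(raw / alpha2_sigma2_ref_GM)
  instrument
}

#' Default instrument: 1030 nm, 80 MHz, 135 fs, calibrated kappa
#'
#' Returns [instrument_params()] defaults with the geometry factor calibrated
#' against the dFONs(1) reference pair (P_sat = 17.3 mW, alpha^2 sigma2 =
#' 710 GM) via [calibrate_geometry_factor()].
#'
#' @return A calibrated `instrument_params` object.
#' @export
default_instrument <- function() {
  calibrate_geometry_factor(instrument_params())
}

#' Photophysical parameters of one nanoparticle family
#'
#' Per-family constants: two-photon absorption cross section per dye molecule,
#' fluorescence quantum yield, mean dry diameter, mean number of dye molecules
#' per particle, radiative decay rate, and the fitted saturation power and
#' bleaching constant.
#'
#' The molar mass is only used by the synthetic generator to convert particle
#' diameters to molecule numbers; when `molar_mass_g_mol = NULL` it is derived
#' from the `(diameter_nm, n_molecules)` pair assuming the stated density, so
#' the pair is reproduced exactly.
#'
#' @param name Family label.
#' @param sigma2_GM Two-photon absorption cross section per molecule (GM).
#' @param phi Fluorescence quantum yield, in (0, 1].
#' @param diameter_nm Mean dry diameter (nm).
#' @param n_molecules Mean number of dye molecules per particle.
#' @param gamma_rad_per_s Radiative decay rate Gamma (1/s). Not printed for
#'   these dyes; the default 5e8 (2 ns lifetime) is typical for bright organic
#'   fluorophores and only enters model-assumption checks.
#' @param tau_b0_s Bleaching constant tau_b0 (s), the monoexponential
#'   bleaching time at P_exc = P_sat. `NA` if not set.
#' @param psat_mW Saturation power (mW). `NA` if not set.
#' @param relative_density Particle density relative to water.
#' @param molar_mass_g_mol Dye molar mass (g/mol), or `NULL` to derive it from
#'   `diameter_nm` and `n_molecules`.
#' @return An object of class `species_params`.
#' @seealso [dfon_species()] for the two reference families.
#' @export
species_params <- function(name,
                           sigma2_GM,
                           phi,
                           diameter_nm,
                           n_molecules,
                           gamma_rad_per_s = 5e8,
                           tau_b0_s = NA_real_,
                           psat_mW = NA_real_,
                           relative_density = 1,
                           molar_mass_g_mol = NULL) {
  stopifnot(
    is.character(name), length(name) == 1L,
    sigma2_GM > 0, phi > 0, phi <= 1,
    diameter_nm > 0, n_molecules >= 1,
    gamma_rad_per_s > 0, relative_density > 0,
    is.na(tau_b0_s) || tau_b0_s > 0,
    is.na(psat_mW) || psat_mW > 0
  )
  if (is.null(molar_mass_g_mol)) {
    # invert N = rho * (pi/6) d^3 NA / M
    vol_cm3 <- (pi / 6) * (diameter_nm * 1e-7)^3
    molar_mass_g_mol <- relative_density * vol_cm3 * .AVOGADRO / n_molecules
  }
  stopifnot(molar_mass_g_mol > 0)
  structure(
    list(
      name = name,
      sigma2_GM = sigma2_GM,
      phi = phi,
      diameter_nm = diameter_nm,
      n_molecules = n_molecules,
      gamma_rad_per_s = gamma_rad_per_s,
      tau_b0_s = tau_b0_s,
      psat_mW = psat_mW,
      relative_density = relative_density,
      molar_mass_g_mol = molar_mass_g_mol
    ),
    class = "species_params"
  )
}

#' Reference dFON families
#'
#' Returns the [species_params()] of the two dye-based fluorescent organic
#' nanoparticle (dFON) families characterized at 1000-1030 nm: family 1
#' (green-emitting, sigma2 = 60 GM, phi = 0.33, 29 nm, 7500 molecules,
#' P_sat = 17.3 mW, tau_b0 = 1.06 s) and family 2 (red-emitting, sigma2 =
#' 930 GM, phi = 0.06, 20 nm, 2100 molecules, P_sat = 5.29 mW, tau_b0 =
#' 3.84 s). Their two-photon brightness sigma2 * phi * N is comparable
#' (1.5e5 vs 1.2e5 GM per particle) by design.
#'
#' @param family `"dFONs1"` or `"dFONs2"`.
#' @return A `species_params` object.
#' @examples
#' sp <- dfon_species("dFONs1")
#' brightness_2p(sp$sigma2_GM, sp$phi, sp$n_molecules)  # ~1.5e5 GM
#' @export
dfon_species <- function(family = c("dFONs1", "dFONs2")) {
  family <- match.arg(family)
  switch(family,
    dFONs1 = species_params(
      name = "dFONs1", sigma2_GM = 60, phi = 0.33,
      diameter_nm = 29, n_molecules = 7500,
      tau_b0_s = 1.06, psat_mW = 17.3
    ),
    dFONs2 = species_params(
      name = "dFONs2", sigma2_GM = 930, phi = 0.06,
      diameter_nm = 20, n_molecules = 2100,
      tau_b0_s = 3.84, psat_mW = 5.29
    )
  )
}

#' Nanoparticle size distribution as a truncated-normal mixture
#'
#' Describes a particle-diameter population as a weighted mixture of normal
#' modes truncated to positive diameters, mirroring transmission electron
#' microscopy size histograms.
#'
#' @param mean_nm Vector of mode centres (nm).
#' @param sd_nm Vector of mode spreads (nm); a zero spread gives a
#'   point mass.
#' @param weight Vector of non-negative mode weights; normalized to sum to 1.
#' @return An object of class `size_population`: a data.frame with columns
#'   `mean_nm`, `sd_nm`, `weight`.
#' @seealso [dfon_size_population()], [sample_diameters()]
#' @export
size_population <- function(mean_nm, sd_nm, weight) {
  stopifnot(
    length(mean_nm) >= 1L,
    length(mean_nm) == length(sd_nm),
    length(mean_nm) == length(weight),
    all(mean_nm > 0), all(sd_nm >= 0), all(weight >= 0), sum(weight) > 0
  )
  structure(
    data.frame(mean_nm = mean_nm, sd_nm = sd_nm,
               weight = weight / sum(weight)),
    class = c("size_population", "data.frame")
  )
}

#' Reference size distributions of the two dFON families
#'
#' Family 1 is bimodal: a narrow mode near 15 nm and a broad mode near 50 nm
#' whose mean particle volume is more than an order of magnitude larger, so
#' emission (proportional to volume) is dominated by the 50 nm mode. Family 2
#' is unimodal near 20 nm. Mode spreads (3 nm for the narrow modes, 15 nm for
#' the broad one) are generator defaults chosen to reproduce the qualitative
#' histogram shapes; the sources report only the mode centres.
#'
#' @param family `"dFONs1"` or `"dFONs2"`.
#' @return A [size_population()] object.
#' @export
dfon_size_population <- function(family = c("dFONs1", "dFONs2")) {
  family <- match.arg(family)
  switch(family,
    dFONs1 = size_population(mean_nm = c(15, 50), sd_nm = c(3, 15),
                             weight = c(0.5, 0.5)),
    dFONs2 = size_population(mean_nm = 20, sd_nm = 3, weight = 1)
  )
}

#' @export
print.instrument_params <- function(x, ...) {
  cat("Two-photon instrument parameters\n")
  cat(sprintf("  wavelength      : %g nm\n", x$wavelength_nm))
  cat(sprintf("  repetition rate : %.4g MHz (T = %.4g ns)\n",
              1e-6 / x$rep_period_s, x$rep_period_s * 1e9))
  cat(sprintf("  pulse tau       : %g fs (%s), rect. width %g fs\n",
              x$pulse_tau_s * 1e15, x$tau_interpretation,
              x$rect_pulse_dt_s * 1e15))
  cat(sprintf("  waist W0        : %g nm (PSF sigma %.0f nm)\n",
              x$waist_nm, x$waist_nm / sqrt(2)))
  cat(sprintf("  collection      : %g\n", x$collection_efficiency))
  cat(sprintf("  geometry factor : %.6g\n", x$geometry_factor))
  invisible(x)
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("dFON species '%s'\n", x$name))
  cat(sprintf("  sigma2   : %g GM/molecule   phi: %g\n", x$sigma2_GM, x$phi))
  cat(sprintf("  diameter : %g nm   N: %g molecules\n",
              x$diameter_nm, x$n_molecules))
  cat(sprintf("  B_2P     : %.3g GM/particle\n",
              x$sigma2_GM * x$phi * x$n_molecules))
  if (!is.na(x$psat_mW)) cat(sprintf("  P_sat    : %g mW\n", x$psat_mW))
  if (!is.na(x$tau_b0_s)) cat(sprintf("  tau_b0   : %g s\n", x$tau_b0_s))
  invisible(x)
}
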