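# Core photophysics: photon energy, local field, saturation curve,
# excitation rate, cross-section relations, brightness, bleaching law,
# pulse-train emission model.

test_that("photon energy follows h*c/lambda and its scaling", {
  # frozen from CODATA h = 6.62607015e-34 J s, c = 2.99792458e8 m/s
  expect_equal(photon_energy(1030), 1.928588e-19, tolerance = 1e-6)
  expect_equal(photon_energy(515), 2 * photon_energy(1030))
  expect_equal(photon_energy(2060), photon_energy(1030) / 2)
  expect_error(photon_energy(0), "positive")
  expect_error(photon_energy(-5), "positive")
})

test_that("Lorentz local-field factor matches ((n^2+2)/3)^2 and its bounds", {
  expect_equal(lorentz_local_field(1), 1)
  expect_equal(lorentz_local_field(1.5), 2.006944, tolerance = 1e-6)
  expect_equal(lorentz_local_field(3), 13.44444, tolerance = 1e-6)
  # monotone increasing over the physically relevant range
  n <- seq(1, 3, by = 0.05)
  expect_true(all(diff(lorentz_local_field(n)) > 0))
  expect_error(lorentz_local_field(0.9), ">= 1")
})

test_that("saturation curve has the right limits and quadratic onset", {
  expect_equal(saturation_curve(0, 17.3), 0)
  expect_equal(saturation_curve(17.3, 17.3), 1 - exp(-1))
  # quadratic low-power regime: F ~ (P/Psat)^2
  expect_equal(saturation_curve(1.73, 17.3), 0.00995, tolerance = 1e-3)
  p <- seq(0, 100, by = 0.5)
  f <- saturation_curve(p, 17.3)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < 1))
  # relative deviation from the pure quadratic vanishes as P -> 0
  small <- c(1e-3, 1e-2, 1e-1)
  rel <- saturation_curve(small, 17.3) / (small / 17.3)^2 - 1
  expect_true(all(abs(rel) < 1e-3))
  expect_error(saturation_curve(1, -1), "positive")
})

test_that("excitation rate is quadratic in power and hits 1/dt at P_sat", {
  instr <- test_instrument()
  expect_equal(excitation_rate(2, instr, 710),
               4 * excitation_rate(1, instr, 710))
  # saturation condition: Gamma_exc(P_sat) * dt = 1, i.e. ~3.70e12 1/s
  g <- excitation_rate(17.3, instr, 710)
  expect_equal(g * instr$rect_pulse_dt_s, 1, tolerance = 1e-10)
  expect_equal(g, 1 / 270e-15, tolerance = 1e-6)
})

test_that("cross-section/P_sat relations are mutual inverses", {
  instr <- test_instrument()
  for (x in c(10, 710, 7580)) {
    expect_equal(cross_section_from_psat(psat_from_cross_section(x, instr),
                                         instr),
                 x, tolerance = 1e-12)
  }
  expect_equal(psat_from_cross_section(710, instr), 17.3,
               tolerance = 1e-10)
  # inverse-square scaling: halving P_sat quadruples the cross section
  expect_equal(cross_section_from_psat(8.65, instr),
               4 * cross_section_from_psat(17.3, instr))
  expect_equal(psat_from_cross_section(4 * 710, instr), 17.3 / 2)
  # alpha^2 sigma2 * P_sat^2 is an instrument constant
  ps <- c(2, 5.29, 17.3, 40)
  prod <- cross_section_from_psat(ps, instr) * ps^2
  expect_equal(max(prod) / min(prod), 1, tolerance = 1e-12)
})

test_that("inverse-square P_sat scaling is calibration-free", {
  # the 7580/710 ratio check holds for any geometry factor
  for (kap in c(0.5, 1, 2)) {
    instr <- instrument_params(geometry_factor = kap)
    ratio <- cross_section_from_psat(5.29, instr) /
      cross_section_from_psat(17.3, instr)
    expect_equal(ratio, (17.3 / 5.29)^2, tolerance = 1e-12)
  }
  expect_equal((17.3 / 5.29)^2, 7580 / 710, tolerance = 0.01)
})

test_that("local-field coefficient and brightness product reproduce the references", {
  expect_equal(alpha_from_ensemble(710, 60), 3.44, tolerance = 1e-2)
  expect_equal(alpha_from_ensemble(7580, 930), 2.855, tolerance = 1e-3)
  expect_equal(alpha_from_ensemble(5, 5), 1)
  expect_equal(brightness_2p(60, 0.33, 7500), 148500)
  expect_equal(brightness_2p(930, 0.06, 2100), 117180)
  expect_equal(brightness_2p(42, 1, 1), 42)
})

test_that("bleaching power law scales as inverse-square power", {
  expect_equal(bleaching_time(17.3, 17.3, 1.06), 1.06)
  expect_equal(bleaching_time(2 * 17.3, 17.3, 1.06), 1.06 / 4)
  # tau_b * P^2 constant (log-log slope -2)
  p <- c(1, 2, 5, 10, 20)
  tb <- bleaching_time(p, 5.29, 3.84)
  expect_equal(max(tb * p^2) / min(tb * p^2), 1, tolerance = 1e-12)
  # family ratio at equal power ~ 3
  r <- bleaching_time(10, 17.3, 1.06) / bleaching_time(10, 5.29, 3.84)
  expect_equal(r, 2.95, tolerance = 1e-2)
  expect_error(bleaching_time(0, 5, 1), "positive")
})

test_that("pulse-train emission reproduces the saturation curve and its asymptote", {
  instr <- test_instrument()
  sp <- dfon_species("dFONs1")
  a2s2 <- cross_section_from_psat(sp$psat_mW, instr)
  p <- c(0.5, 2, 5, 17.3, 30, 80)
  r <- pulse_train_emission(p, instr, sp, a2s2)
  asym <- instr$collection_efficiency * sp$n_molecules * sp$phi /
    instr$rep_period_s
  expect_equal(r / asym, saturation_curve(p, sp$psat_mW), tolerance = 1e-12)
  # hard saturation limit: one emission per molecule per pulse
  expect_equal(pulse_train_emission(1e4, instr, sp, a2s2), asym,
               tolerance = 1e-9)
  # linear in N and in collection efficiency
  sp2 <- sp; sp2$n_molecules <- 2 * sp$n_molecules
  expect_equal(pulse_train_emission(5, instr, sp2, a2s2), 2 * r[3])
  in2 <- instr; in2$collection_efficiency <- instr$collection_efficiency / 2
  expect_equal(pulse_train_emission(5, in2, sp, a2s2), r[3] / 2)
})

test_that("closed-form per-pulse excitation matches direct rate-equation integration", {
  skip_if_not_installed("deSolve")
  instr <- test_instrument()
  for (p in c(2, 8, 17.3, 35)) {
    g <- excitation_rate(p, instr, 710)
    # ground-state depletion over one rectangular pulse on a time grid
    sol <- deSolve::ode(
      y = c(ng = 1), times = c(0, instr$rect_pulse_dt_s),
      func = function(t, y, parms) list(-parms * y), parms = g,
      rtol = 1e-10, atol = 1e-12
    )
    excited_ode <- 1 - unname(sol[2, "ng"])
    closed <- 1 - exp(-g * instr$rect_pulse_dt_s)
    expect_equal(excited_ode, closed, tolerance = 1e-6)
    expect_equal(closed, saturation_curve(p, 17.3), tolerance = 1e-10)
  }
})

test_that("photostability ratio is power-invariant and ~3 for the reference families", {
  r <- photostability_ratio(1.06, 17.3, 3.84, 5.29)
  expect_equal(r, 2.95, tolerance = 1e-2)
  expect_equal(photostability_ratio(1, 5, 1, 5), 1)
  # rescaling both saturation powers by a common factor leaves it unchanged
  expect_equal(photostability_ratio(1.06, 17.3 * 3, 3.84, 5.29 * 3), r)
})

test_that("parameter containers validate their invariants", {
  instr <- instrument_params()
  expect_equal(instr$rect_pulse_dt_s, 2 * instr$pulse_tau_s)
  expect_lt(instr$rect_pulse_dt_s, instr$rep_period_s)
  expect_error(instrument_params(collection_efficiency = 1.2))
  expect_error(instrument_params(pulse_tau_s = 1), "shorter")
  # fwhm reinterpretation gives a narrower rectangle than the sech2 reading
  i2 <- instrument_params(tau_interpretation = "fwhm")
  expect_lt(i2$rect_pulse_dt_s, instr$rect_pulse_dt_s)
  expect_equal(i2$rect_pulse_dt_s, 2 * 135e-15 / 1.7627, tolerance = 1e-4)
  expect_error(species_params("x", -1, 0.5, 20, 100))
  expect_error(species_params("x", 60, 1.5, 20, 100))
  # derived molar mass reproduces the (diameter, N) pair
  sp <- dfon_species("dFONs1")
  expect_equal(sp$molar_mass_g_mol, 1025.4, tolerance = 1e-3)
  expect_equal(molecules_per_particle(sp$diameter_nm, sp$molar_mass_g_mol),
               sp$n_molecules)
})
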