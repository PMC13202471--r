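# Trace stage: saturation fits, ensemble curves, cross-section derivation,
# decay fits and the bleaching power law.

test_that("saturation fit recovers a noiseless curve to numerical precision", {
  p <- seq(0.5, 45, length.out = 20)
  tr <- structure(
    data.frame(power_mW = p, counts = 1e5 * saturation_curve(p, 17.3)),
    dwell_s = 1, class = c("sweep_trace", "data.frame"))
  ft <- fit_saturation(tr)
  expect_equal(ft$p_sat_mW, 17.3, tolerance = 1e-6)
  expect_equal(ft$asymptote_cps, 1e5, tolerance = 1e-6)
})

test_that("saturation fit warns on degenerate sweeps", {
  p <- seq(1, 40, length.out = 12)
  flat <- structure(data.frame(power_mW = p, counts = rep(1000L, 12)),
                    dwell_s = 1, class = c("sweep_trace", "data.frame"))
  expect_warning(try(fit_saturation(flat), silent = TRUE),
                 "poorly constrained")
  few <- structure(data.frame(power_mW = c(1, 2, 3),
                              counts = c(10L, 40L, 95L)),
                   dwell_s = 1, class = c("sweep_trace", "data.frame"))
  expect_warning(try(fit_saturation(few), silent = TRUE), "fewer than 5")
})

test_that("saturation fits are unbiased and their errors calibrated", {
  sp <- dfon_species("dFONs1")
  fits <- lapply(1:200, function(i) {
    tr <- generate_saturation_sweep(seq(1, 40, length.out = 15), sp,
                                    dwell_s = 1, peak_rate = 1e5,
                                    seed = 10000 + i)
    fit_saturation(tr)
  })
  psat <- vapply(fits, `[[`, 0, "p_sat_mW")
  se <- vapply(fits, `[[`, 0, "p_sat_se_mW")
  expect_equal(mean(psat), 17.3, tolerance = 0.02)
  # reported standard errors track the empirical scatter
  expect_equal(stats::sd(psat) / mean(se), 1, tolerance = 0.3)
})

test_that("normalization to the asymptote is idempotent and ~0.632 at P_sat", {
  sp <- dfon_species("dFONs1")
  tr <- generate_saturation_sweep(c(seq(2, 40, length.out = 14), 17.3), sp,
                                  peak_rate = 2e5, seed = 31)
  ft <- fit_saturation(tr)
  nt <- normalize_to_asymptote(tr, ft)
  expect_equal(nt$normalized[15], 1 - exp(-1), tolerance = 0.05)
  nt2 <- normalize_to_asymptote(nt, ft)
  expect_equal(nt2$normalized, nt$normalized)
  # noiseless normalized curve is bounded by 1
  p <- seq(0.5, 45, length.out = 20)
  noiseless <- structure(
    data.frame(power_mW = p, counts = 5e4 * saturation_curve(p, 17.3)),
    dwell_s = 1, class = c("sweep_trace", "data.frame"))
  fnl <- fit_saturation(noiseless)
  expect_true(all(normalize_to_asymptote(noiseless, fnl)$normalized <= 1))
})

test_that("ensemble saturation averages particles and recovers P_sat", {
  sp <- dfon_species("dFONs2")
  traces <- lapply(1:30, function(i)
    generate_saturation_sweep(seq(0.5, 15, length.out = 15), sp,
                              peak_rate = 1e5, particle_id = i,
                              seed = 700 + i))
  ens <- ensemble_saturation(traces)
  expect_equal(ens$n_traces, 30)
  expect_equal(ens$fit$p_sat_mW, 5.29, tolerance = 0.05)
  expect_true(all(ens$sd >= 0))
  # identical traces give a zero-width band
  tr <- traces[[1]]
  ens0 <- ensemble_saturation(list(tr, tr, tr))
  expect_equal(max(ens0$sd), 0)
  # family 2 saturates at lower power than family 1
  sp1 <- dfon_species("dFONs1")
  traces1 <- lapply(1:10, function(i)
    generate_saturation_sweep(seq(1, 40, length.out = 15), sp1,
                              peak_rate = 1e5, seed = 800 + i))
  ens1 <- ensemble_saturation(traces1)
  expect_lt(ens$fit$p_sat_mW, ens1$fit$p_sat_mW)
  # disjoint power ranges are an error
  lo <- generate_saturation_sweep(1:3, sp, seed = 1)
  hi <- generate_saturation_sweep(10:12, sp, seed = 2)
  expect_error(ensemble_saturation(list(lo, hi)), "disjoint")
})

test_that("cross-section derivation composes the relations with error propagation", {
  instr <- test_instrument()
  r1 <- derive_cross_section(list(p_sat_mW = 17.3, p_sat_se_mW = 0.5),
                             instr, 60)
  expect_equal(r1$alpha2_sigma2_GM, 710, tolerance = 1e-6)
  expect_equal(signif(r1$alpha, 2), 3.4)
  expect_equal(r1$alpha2_sigma2_se_GM / r1$alpha2_sigma2_GM,
               2 * 0.5 / 17.3, tolerance = 1e-10)
  expect_equal(r1$alpha_se / r1$alpha, 0.5 / 17.3, tolerance = 1e-10)
  r2 <- derive_cross_section(list(p_sat_mW = 5.29, p_sat_se_mW = 0.2),
                             instr, 930)
  expect_equal(signif(r2$alpha, 2), 2.9)
  # alpha halves when P_sat doubles
  rd <- derive_cross_section(list(p_sat_mW = 34.6, p_sat_se_mW = 1),
                             instr, 60)
  expect_equal(rd$alpha, r1$alpha / 2, tolerance = 1e-10)
})

test_that("end-to-end closure: generated sweeps return the generator cross section", {
  instr <- test_instrument()
  sp <- dfon_species("dFONs1")
  a2s2_true <- cross_section_from_psat(sp$psat_mW, instr)
  traces <- lapply(1:20, function(i)
    generate_saturation_sweep(seq(1, 40, length.out = 15), sp,
                              peak_rate = 1e5, seed = 880 + i))
  ens <- ensemble_saturation(traces)
  lf <- derive_cross_section(ens$fit, instr, sp$sigma2_GM)
  expect_equal(lf$alpha2_sigma2_GM, a2s2_true, tolerance = 0.05)
})

test_that("decay fit recovers a noiseless exponential exactly and flags flat traces", {
  t <- seq(0.005, 3, by = 0.01)
  tr <- structure(data.frame(time_s = t, counts = 1000 * exp(-t / 1.0)),
                  bin_s = 0.01, class = c("decay_trace", "data.frame"))
  ft <- fit_decay(tr, fit_background = FALSE)
  expect_true(ft$converged)
  expect_equal(ft$tau_b_s, 1.0, tolerance = 1e-6)
  expect_equal(ft$s0_rate, 1000 / 0.01, tolerance = 1e-4)
  flat <- structure(data.frame(time_s = t,
                               counts = rep(500L, length(t))),
                    bin_s = 0.01, class = c("decay_trace", "data.frame"))
  ff <- fit_decay(flat)
  expect_false(ff$converged)
  expect_match(ff$reason, "unbounded|no decay")
})

test_that("decay fits are unbiased over seeded Poisson traces", {
  sp <- dfon_species("dFONs2")
  p <- 2 * sp$psat_mW          # tau_b = 0.96 s
  taus <- c(); ses <- c(); hits <- 0L
  for (i in 1:200) {
    tr <- generate_bleach_trace(p, sp, s0_rate = 1e5, bin_s = 0.01,
                                seed = 20000 + i)
    # matched model: traces carry no background, so none is fitted
    ft <- fit_decay(tr, fit_background = FALSE)
    taus <- c(taus, ft$tau_b_s); ses <- c(ses, ft$tau_b_se_s)
    if (abs(ft$tau_b_s - 0.96) / 0.96 < 0.05) hits <- hits + 1L
  }
  expect_equal(mean(taus), 0.96, tolerance = 0.02)
  expect_gte(hits / 200, 0.95)
  expect_equal(stats::sd(taus) / mean(ses), 1, tolerance = 0.3)
})

test_that("bleach law fit recovers tau_b0 and the -2 slope", {
  # exact power-law data
  p <- c(4, 8.65, 17.3, 25, 34.6)
  tb <- data.frame(power_mW = p, tau_mean_s = 1.06 * (17.3 / p)^2,
                   tau_sd_s = 0.05 * (17.3 / p)^2)
  law <- fit_bleach_law(tb, 17.3)
  expect_equal(law$tau_b0_s, 1.06, tolerance = 1e-10)
  expect_equal(law$loglog_slope, -2, tolerance = 1e-10)
  expect_error(fit_bleach_law(tb[1:2, ], 17.3), "3 distinct")
  # Poisson pipeline: slope within 3 SE of -2
  bl <- recover_bleach_law(dfon_species("dFONs2"), traces_per_power = 5,
                           seed = 77)
  expect_lt(abs(bl$loglog_slope + 2), 3 * bl$loglog_slope_se)
  expect_equal(bl$tau_b0_s, 3.84, tolerance = 0.1)
})

test_that("bleach-time aggregation groups by power", {
  agg <- aggregate_bleach_times(c(1, 1, 2, 2, 2), c(4, 6, 1, 2, 3))
  expect_equal(agg$power_mW, c(1, 2))
  expect_equal(agg$tau_mean_s, c(5, 2))
  expect_equal(agg$n, c(2L, 3L))
  expect_error(aggregate_bleach_times(1, NA_real_), "no finite")
})
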