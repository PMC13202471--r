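# Scan stage: detection, PSF fitting, brightness normalization, population
# statistics, two-sample comparison.

test_that("blank Poisson images yield zero candidates at 5 sigma", {
  for (s in 1:100) {
    sc <- generate_scan(0, width_px = 50, height_px = 50,
                        background_rate = 100, seed = s)
    cand <- detect_spots(sc$image, 100, threshold_sigma = 5)
    expect_equal(nrow(cand), 0)
  }
})

test_that("detection recovers well-separated bright particles", {
  recovered <- 0L; eligible <- 0L
  for (s in 1:20) {
    sc <- generate_scan(12, width_px = 120, height_px = 120,
                        size_spec = bright_population(),
                        aggregate_fraction = 0, background_rate = 100,
                        seed = 400 + s)
    cand <- detect_spots(sc$image, 100)
    nn <- nearest_neighbour_nm(sc$truth)
    # peak SNR >= 10 over background noise, non-overlapping spots
    snr <- sc$truth$peak_rate * 0.01 / sqrt(100 * 0.01)
    elig <- sc$truth[snr >= 10 & nn > 800, ]
    eligible <- eligible + nrow(elig)
    recovered <- recovered + count_recovered(cand, elig)
  }
  expect_gt(eligible, 100)
  expect_gte(recovered / eligible, 0.95)
})

test_that("two particles inside one PSF collapse to a single candidate", {
  # construct a doublet 150 nm apart directly on the rate model
  instr <- test_instrument()
  px <- 100; n <- 41; sig <- instr$waist_nm / sqrt(2)
  xc <- (seq_len(n) - 0.5) * px
  rate <- matrix(50, n, n)
  for (x0 in c(2000, 2150)) {
    gx <- exp(-(xc - x0)^2 / (2 * sig^2))
    gy <- exp(-(xc - 2050)^2 / (2 * sig^2))
    rate <- rate + 3e5 * outer(gy, gx)
  }
  set.seed(99)
  img <- matrix(rpois(n * n, rate * 0.01), n, n)
  cand <- detect_spots(img, px)
  expect_equal(nrow(cand), 1)
  ft <- fit_psf(img, cand[1, ], px, 0.01)
  expect_true(flag_aggregates(ft, sig, tolerance = 0.3) ||
                ft$sigma_nm > sig)
})

test_that("PSF fit recovers a noiseless Gaussian almost exactly", {
  px <- 100; n <- 31
  xc <- (seq_len(n) - 0.5) * px
  a_true <- 1000; sig_true <- 250; dwell <- 0.01
  gx <- exp(-(xc - 1550)^2 / (2 * sig_true^2))
  img <- round(1e4 * (0.05 + a_true / 1000 * outer(gx, gx)))
  cand <- data.frame(row = 16, col = 16)
  ft <- fit_psf(img, cand, px, dwell)
  expect_true(ft$converged)
  expect_equal(ft$sigma_nm, sig_true, tolerance = 1e-3)
  expect_equal(ft$x0_nm, 1550, tolerance = 1e-3)
  # flat background is rejected with a reason
  flat <- matrix(5L, n, n)
  ftf <- fit_psf(flat, cand, px, dwell)
  expect_false(ftf$converged)
  expect_true(is.character(ftf$reason))
})

test_that("PSF amplitude is recovered within error on Poisson spots", {
  px <- 100; n <- 21; sig <- 250; dwell <- 0.01
  xc <- (seq_len(n) - 0.5) * px
  peak_rate <- 1e6  # 1e4 counts at the peak
  g <- outer(exp(-(xc - 1050)^2 / (2 * sig^2)),
             exp(-(xc - 1050)^2 / (2 * sig^2)))
  hits <- 0L
  for (s in 1:200) {
    set.seed(1200 + s)
    img <- matrix(rpois(n * n, (100 + peak_rate * g) * dwell), n, n)
    ft <- fit_psf(img, data.frame(row = 11, col = 11), px, dwell)
    if (ft$converged &&
        abs(ft$amplitude_cps - peak_rate) < 3 * ft$amplitude_se_cps) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 200, 0.95)
})

test_that("brightness normalization divides by the squared power", {
  expect_equal(normalize_brightness(6e5, 1.7), 600 / 1.7^2,
               tolerance = 1e-12)
  expect_equal(normalize_brightness(0, 2), 0)
  expect_equal(normalize_brightness(1e5, 2),
               normalize_brightness(1e5, 1) / 4)
  expect_error(normalize_brightness(1e5, 0), "> 0")
})

test_that("normalized brightness is power-invariant in the quadratic regime", {
  # image the same particle at two powers; amplitude/P^2 must agree
  b <- vapply(c(1.2, 2.4), function(p) {
    sc <- generate_scan(1, width_px = 40, height_px = 40, p_exc_mW = p,
                        size_spec = bright_population(),
                        aggregate_fraction = 0, background_rate = 0,
                        detection_scale = 8e-4, margin_px = 15, seed = 77)
    cand <- detect_spots(sc$image, 100)
    ft <- fit_psf(sc$image, cand[1, ], 100, 0.01)
    normalize_brightness(ft$amplitude_cps, p)
  }, 0)
  expect_equal(b[1], b[2], tolerance = 0.03)
})

test_that("aggregate flagging keys on width deviation and anisotropy", {
  ok <- list(x0_nm = 0, y0_nm = 0, amplitude_cps = 1, sigma_nm = 250,
             sigma_y_nm = NA_real_, converged = TRUE)
  expect_false(flag_aggregates(ok, 250, 0.3))
  wide <- ok; wide$sigma_nm <- 400
  expect_true(flag_aggregates(wide, 250, 0.3))
  aniso <- ok; aniso$sigma_nm <- 260; aniso$sigma_y_nm <- 180
  expect_true(flag_aggregates(aniso, 250, 0.3))
  bad <- ok; bad$converged <- FALSE
  expect_true(is.na(flag_aggregates(bad, 250)))
})

test_that("population statistics match a sort-based oracle", {
  expect_equal(unclass(population_stats(1:5))[c("median", "q1", "q3")],
               list(median = 3, q1 = 2, q3 = 4))
  expect_equal(population_stats(rep(7, 10))$sd, 0)
  # oracle: linear interpolation on the sorted sample (type-7 definition)
  oracle_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(42)
  for (i in 1:20) {
    x <- sample.int(1000, sample(5:60, 1), replace = TRUE)
    st <- population_stats(x)
    expect_identical(st$median, oracle_q(x, 0.5))
    expect_identical(st$q1, oracle_q(x, 0.25))
    expect_identical(st$q3, oracle_q(x, 0.75))
    expect_equal(st$mean, sum(x) / length(x))
  }
  # aggregates drag the mean above the median (right skew)
  set.seed(1)
  pop <- c(rlnorm(180, log(200), 0.4), rlnorm(20, log(1500), 0.4))
  st <- population_stats(pop)
  expect_gt(st$mean, st$median)
  expect_error(population_stats(numeric(0)), "empty")
})

test_that("population comparison behaves as a calibrated Welch t-test", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_populations(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # degenerate equal constants -> p = 1 by convention
  expect_equal(compare_populations(rep(2, 5), rep(2, 7))$p_value, 1)
  # type-I error calibration on identical generators
  set.seed(31)
  rej <- 0L; reps <- 300L
  for (i in seq_len(reps)) {
    a <- rlnorm(100, log(200), 0.5)
    b <- rlnorm(100, log(200), 0.5)
    if (compare_populations(a, b)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.01)
  expect_lt(rej / reps, 0.10)
  # power: a 2-SD shift at n = 50 is essentially always detected
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50, mean = 2)
  expect_lt(compare_populations(a, b)$p_value, 0.001)
  # Student variant uses pooled degrees of freedom
  st <- compare_populations(rnorm(10), rnorm(12), var_equal = TRUE)
  expect_equal(st$df, 20)
})

test_that("full scan analysis returns brightness with aggregate flags", {
  sc <- generate_scan(15, width_px = 120, height_px = 120,
                      aggregate_fraction = 0.3, seed = 55)
  spots <- analyze_scan(sc$image, sc$meta$pixel_nm, sc$meta$dwell_s,
                        sc$meta$p_exc_mW)
  expect_true(nrow(spots) > 0)
  expect_true(all(spots$amplitude_cps > 0))
  expect_true(all(c("brightness", "aggregate", "sigma_nm") %in%
                    names(spots)))
  expect_equal(spots$brightness,
               normalize_brightness(spots$amplitude_cps, sc$meta$p_exc_mW))
})
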