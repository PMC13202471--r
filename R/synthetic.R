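# Seeded synthetic microscope data: scans, saturation sweeps, bleach traces.
# All generators take an integer seed and are reproducible for a fixed seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Sample particle diameters from a size-population mixture
#'
#' Draws i.i.d. diameters from the truncated-normal mixture described by a
#' [size_population()] object (each mode truncated to positive diameters by
#' rejection).
#'
#' @param spec A [size_population()] object.
#' @param n Number of draws, `>= 1`.
#' @param seed Optional integer seed; the same seed reproduces the same draw.
#' @return Numeric vector of `n` diameters (nm).
#' @examples
#' d <- sample_diameters(dfon_size_population("dFONs1"), 1000, seed = 1)
#' @export
sample_diameters <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "size_population") || nrow(spec) == 0L) {
    stop("spec must be a non-empty size_population")
  }
  stopifnot(n >= 1)
  with_seed(seed, {
    mode <- sample.int(nrow(spec), n, replace = TRUE, prob = spec$weight)
    d <- spec$mean_nm[mode] + spec$sd_nm[mode] * stats::rnorm(n)
    bad <- which(d <= 0)
    while (length(bad) > 0L) {
      d[bad] <- spec$mean_nm[mode[bad]] +
        spec$sd_nm[mode[bad]] * stats::rnorm(length(bad))
      bad <- bad[d[bad] <= 0]
    }
    d
  })
}

#' Number of dye molecules in a particle of given diameter
#'
#' Assumes a spherical particle of density `relative_density` times that of
#' water packed with dye of the given molar mass:
#' `N = rho_water * relative_density * (pi/6) d^3 * N_A / M`, rounded to the
#' nearest integer. Molecule number therefore scales with particle volume.
#'
#' @param diameter_nm Particle diameter (nm); vectorized.
#' @param molar_mass_g_mol Dye molar mass (g/mol).
#' @param relative_density Density relative to water (water = 1 g/cm^3).
#' @return Integer molecule count(s).
#' @examples
#' molecules_per_particle(29, 1025.4)   # ~7500
#' @export
molecules_per_particle <- function(diameter_nm, molar_mass_g_mol,
                                   relative_density = 1) {
  if (any(diameter_nm < 0) || molar_mass_g_mol <= 0 || relative_density <= 0) {
    stop("arguments must be positive")
  }
  vol_cm3 <- (pi / 6) * (diameter_nm * 1e-7)^3
  round(relative_density * vol_cm3 * .AVOGADRO / molar_mass_g_mol)
}

#' Half-wave-plate angle to transmitted power
#'
#' A rotating half-wave plate in front of a polarizer modulates the
#' transmitted power as `P = P_max * sin^2(2 * (theta - theta0))` (Malus law
#' with the doubled rotation of the polarization plane).
#'
#' @param theta_deg Plate angle (degrees); vectorized.
#' @param p_max_mW Maximum transmitted power (mW).
#' @param theta0_deg Angle of extinction (degrees).
#' @return Transmitted power (mW).
#' @examples
#' hwp_angle_to_power(c(0, 22.5, 45), 40)   # 0, 20, 40 mW
#' @export
hwp_angle_to_power <- function(theta_deg, p_max_mW, theta0_deg = 0) {
  stopifnot(p_max_mW > 0)
  p_max_mW * sin(2 * (theta_deg - theta0_deg) * pi / 180)^2
}

# Expected peak detected rate (counts/s) of one particle of n_mol molecules,
# from the pulse-train model scaled by the detection throughput.
particle_peak_rate <- function(p_exc_mW, instrument, species, n_mol,
                               detection_scale) {
  sp <- species
  sp$n_molecules <- 1
  n_mol * detection_scale * pulse_train_emission(p_exc_mW, instrument, sp)
}

#' Generate a synthetic raster scan of dispersed nanoparticles
#'
#' Places particles uniformly in the field, renders each as a 2D Gaussian
#' spot of standard deviation `W0 / sqrt(2)` whose peak rate follows the
#' pulse-train emission model with volume-proportional molecule numbers, adds
#' a constant background rate, and draws per-pixel Poisson counts for the
#' given dwell time. A configurable fraction of spots are aggregates: 2-4
#' particles co-located within one PSF, producing a long right tail in the
#' brightness distribution.
#'
#' @param n_particles Number of particles (aggregates count as one spot).
#' @param width_px,height_px Image size in pixels.
#' @param pixel_nm Pixel size (nm).
#' @param dwell_s Integration time per pixel (s).
#' @param p_exc_mW Scan excitation power (mW).
#' @param instrument An [instrument_params()] object.
#' @param species A [species_params()] object.
#' @param size_spec A [size_population()] object for particle diameters.
#' @param background_rate Constant background count rate (counts/s).
#' @param aggregate_fraction Fraction of spots that are aggregates.
#' @param detection_scale Dimensionless detection throughput applied to the
#'   pulse-train emission rate: it lumps detector quantum efficiency,
#'   spectral filtering beyond the stated collection fraction and dead-time
#'   losses into a single factor so that peak count rates match the
#'   few-hundred-kcounts/s regime of real photon-counting scans.
#' @param margin_px Border (pixels) kept free of particle centres.
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_scan`: `image` (integer count matrix,
#'   rows = y), `truth` (data.frame with one row per particle: `spot`,
#'   `x_nm`, `y_nm`, `diameter_nm`, `n_molecules`, `peak_rate`, `aggregate`),
#'   and `meta` (pixel size, dwell, power, background, seed, PSF sigma).
#' @examples
#' sc <- generate_scan(10, seed = 1)
#' dim(sc$image)
#' @export
generate_scan <- function(n_particles = 20,
                          width_px = 100, height_px = 100,
                          pixel_nm = 100, dwell_s = 0.010,
                          p_exc_mW = 1.7,
                          instrument = default_instrument(),
                          species = dfon_species("dFONs1"),
                          size_spec = dfon_size_population(species$name),
                          background_rate = 100,
                          aggregate_fraction = 0.1,
                          detection_scale = 8e-5,
                          margin_px = 5,
                          seed = NULL) {
  stopifnot(width_px > 0, height_px > 0, pixel_nm > 0, dwell_s > 0,
            p_exc_mW >= 0, background_rate >= 0,
            aggregate_fraction >= 0, aggregate_fraction <= 1,
            detection_scale > 0, n_particles >= 0)
  sigma_nm <- instrument$waist_nm / sqrt(2)
  field_w <- width_px * pixel_nm
  field_h <- height_px * pixel_nm
  if (n_particles * (4 * sigma_nm)^2 > 0.5 * field_w * field_h) {
    warning("particle density so high that spots will routinely overlap")
  }
  with_seed(seed, {
    rows <- list()
    if (n_particles > 0) {
      lo_x <- margin_px * pixel_nm; hi_x <- field_w - margin_px * pixel_nm
      lo_y <- margin_px * pixel_nm; hi_y <- field_h - margin_px * pixel_nm
      for (i in seq_len(n_particles)) {
        is_agg <- stats::runif(1) < aggregate_fraction
        k <- if (is_agg) sample(2:4, 1) else 1L
        cx <- stats::runif(1, lo_x, hi_x)
        cy <- stats::runif(1, lo_y, hi_y)
        # aggregate members sit within ~half a PSF of the common centre
        dx <- if (k > 1) stats::rnorm(k, 0, 0.5 * sigma_nm) else 0
        dy <- if (k > 1) stats::rnorm(k, 0, 0.5 * sigma_nm) else 0
        d <- sample_diameters(size_spec, k)
        nm <- molecules_per_particle(d, species$molar_mass_g_mol,
                                     species$relative_density)
        pk <- particle_peak_rate(p_exc_mW, instrument, species, nm,
                                 detection_scale)
        rows[[i]] <- data.frame(
          spot = i, x_nm = cx + dx, y_nm = cy + dy,
          diameter_nm = d, n_molecules = nm, peak_rate = pk,
          aggregate = is_agg
        )
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(spot = integer(), x_nm = numeric(), y_nm = numeric(),
                 diameter_nm = numeric(), n_molecules = numeric(),
                 peak_rate = numeric(), aggregate = logical())
    # pixel centres
    xc <- (seq_len(width_px) - 0.5) * pixel_nm
    yc <- (seq_len(height_px) - 0.5) * pixel_nm
    rate <- matrix(background_rate, nrow = height_px, ncol = width_px)
    for (j in seq_len(nrow(truth))) {
      gx <- exp(-(xc - truth$x_nm[j])^2 / (2 * sigma_nm^2))
      gy <- exp(-(yc - truth$y_nm[j])^2 / (2 * sigma_nm^2))
      rate <- rate + truth$peak_rate[j] * outer(gy, gx)
    }
    counts <- matrix(stats::rpois(length(rate), rate * dwell_s),
                     nrow = height_px, ncol = width_px)
    structure(
      list(
        image = counts,
        truth = truth,
        meta = list(pixel_nm = pixel_nm, dwell_s = dwell_s,
                    p_exc_mW = p_exc_mW, background_rate = background_rate,
                    psf_sigma_nm = sigma_nm, detection_scale = detection_scale,
                    species = species$name, seed = seed)
      ),
      class = "synthetic_scan"
    )
  })
}

#' Generate a synthetic per-particle saturation sweep
#'
#' Expected counts at each power follow the pulse-train emission model
#' normalized to its asymptote and scaled to `peak_rate`:
#' `E[counts] = dwell * (background + peak_rate * F(P))` with
#' `F(P) = 1 - exp(-P^2 / P_sat^2)`. Counts are Poisson. With
#' `include_bleaching = TRUE` the signal is additionally attenuated by the
#' photobleaching accumulated over the sweep (each point contributes
#' exposure `dwell / tau_b(P)`).
#'
#' @param powers_mW Vector of excitation powers (mW), in acquisition order.
#' @param species A [species_params()] object with `psat_mW` set (and
#'   `tau_b0_s` if bleaching is simulated).
#' @param instrument An [instrument_params()] object.
#' @param dwell_s Integration time per power point (s).
#' @param peak_rate Asymptotic detected rate (counts/s) of this particle.
#' @param background_rate Background rate (counts/s).
#' @param include_bleaching Simulate bleaching during the sweep?
#' @param particle_id Identifier stored with the trace.
#' @param seed Optional integer seed.
#' @return A data.frame of class `sweep_trace` with columns `power_mW`,
#'   `counts`; attributes `dwell_s`, `particle_id`, `background_rate`.
#' @examples
#' tr <- generate_saturation_sweep(seq(1, 40, length.out = 15),
#'                                 dfon_species("dFONs1"), seed = 1)
#' @export
generate_saturation_sweep <- function(powers_mW,
                                      species = dfon_species("dFONs1"),
                                      instrument = default_instrument(),
                                      dwell_s = 1,
                                      peak_rate = 1e5,
                                      background_rate = 0,
                                      include_bleaching = FALSE,
                                      particle_id = 1L,
                                      seed = NULL) {
  stopifnot(inherits(species, "species_params"), !is.na(species$psat_mW),
            all(powers_mW >= 0), dwell_s > 0, peak_rate > 0,
            background_rate >= 0)
  a2s2 <- cross_section_from_psat(species$psat_mW, instrument)
  norm <- pulse_train_emission(powers_mW, instrument, species, a2s2) /
    (instrument$collection_efficiency * species$n_molecules * species$phi /
       instrument$rep_period_s)
  signal <- peak_rate * norm
  if (include_bleaching) {
    if (is.na(species$tau_b0_s)) stop("species has no tau_b0_s")
    tb <- ifelse(powers_mW > 0,
                 bleaching_time(pmax(powers_mW, 1e-12), species$psat_mW,
                                species$tau_b0_s),
                 Inf)
    # survival at the start of each point, then average over the dwell
    expo <- dwell_s / tb
    surv0 <- exp(-c(0, cumsum(expo[-length(expo)])))
    frac <- ifelse(is.finite(tb), (1 - exp(-expo)) / expo, 1)
    signal <- signal * surv0 * frac
  }
  expected <- dwell_s * (signal + background_rate)
  counts <- with_seed(seed, stats::rpois(length(expected), expected))
  structure(
    data.frame(power_mW = powers_mW, counts = counts),
    dwell_s = dwell_s, particle_id = particle_id,
    background_rate = background_rate,
    class = c("sweep_trace", "data.frame")
  )
}

#' Generate a synthetic photobleaching time trace
#'
#' Expected detected rate decays monoexponentially,
#' `S(t) = S0 * exp(-t / tau_b) + background`, with
#' `tau_b = tau_b0 * (P_sat / P_exc)^2`; counts per bin are Poisson with mean
#' equal to the integral of the rate over the bin.
#'
#' @param p_exc_mW Excitation power (mW).
#' @param species A [species_params()] with `psat_mW` and `tau_b0_s` set.
#' @param duration_s Trace duration (s); a warning is issued when it covers
#'   less than 3 bleaching times.
#' @param bin_s Bin width (s).
#' @param s0_rate Initial detected rate S0 (counts/s).
#' @param background_rate Background rate (counts/s).
#' @param particle_id Identifier stored with the trace.
#' @param seed Optional integer seed.
#' @return A data.frame of class `decay_trace` with columns `time_s` (bin
#'   centres) and `counts`; attributes `bin_s`, `p_exc_mW`, `particle_id`,
#'   `tau_b_true`.
#' @examples
#' tr <- generate_bleach_trace(5.29, dfon_species("dFONs2"),
#'                             duration_s = 12, seed = 1)
#' @export
generate_bleach_trace <- function(p_exc_mW,
                                  species = dfon_species("dFONs2"),
                                  duration_s = NULL,
                                  bin_s = 0.010,
                                  s0_rate = 1e5,
                                  background_rate = 0,
                                  particle_id = 1L,
                                  seed = NULL) {
  stopifnot(inherits(species, "species_params"),
            !is.na(species$psat_mW), !is.na(species$tau_b0_s),
            p_exc_mW > 0, bin_s > 0, s0_rate > 0, background_rate >= 0)
  tau_b <- bleaching_time(p_exc_mW, species$psat_mW, species$tau_b0_s)
  if (is.null(duration_s)) duration_s <- 3.5 * tau_b
  if (duration_s < 3 * tau_b) {
    warning("trace duration covers less than 3 bleaching times; ",
            "tau_b will be poorly constrained")
  }
  n_bins <- max(1L, floor(duration_s / bin_s))
  t0 <- (seq_len(n_bins) - 1) * bin_s
  # exact integral of S0 exp(-t/tau) over each bin
  expected <- s0_rate * tau_b * (exp(-t0 / tau_b) -
                                   exp(-(t0 + bin_s) / tau_b)) +
    background_rate * bin_s
  counts <- with_seed(seed, stats::rpois(n_bins, expected))
  structure(
    data.frame(time_s = t0 + bin_s / 2, counts = counts),
    bin_s = bin_s, p_exc_mW = p_exc_mW, particle_id = particle_id,
    tau_b_true = tau_b,
    class = c("decay_trace", "data.frame")
  )
}
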