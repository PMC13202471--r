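# Trace-stage pipeline: saturation-curve fits (P_sat -> alpha^2 sigma2 ->
# alpha) and monoexponential bleaching fits aggregated into the quadratic
# power law.

#' Fit the saturation curve to a power sweep
#'
#' Weighted least squares of `counts = A * (1 - exp(-P^2 / P_sat^2))` with
#' Poisson weights `1 / (counts + 1)` (the +1 avoids zero weights at empty
#' points). Start values come from the quadratic low-power regime
#' (`counts ~ (A / P_sat^2) * P^2`) and the maximum count. A warning is
#' issued when the powers do not bracket the fitted `P_sat` (the curve is
#' then all in the quadratic regime and `P_sat` poorly constrained) or when
#' fewer than 5 distinct powers are available.
#'
#' @param trace A `sweep_trace` data.frame (columns `power_mW`, `counts`),
#'   e.g. from [generate_saturation_sweep()] or [read_sweep_csv()].
#' @param dwell_s Integration time per point (s); defaults to the trace
#'   attribute, else 1.
#' @return A list of class `saturation_fit`: `p_sat_mW`, `p_sat_se_mW`,
#'   `asymptote_cps`, `asymptote_se_cps`, `A_counts`, `rss`, `n_points`,
#'   `converged`, `warning` (NA when clean).
#' @examples
#' tr <- generate_saturation_sweep(seq(1, 40, length.out = 15),
#'                                 dfon_species("dFONs1"), seed = 1)
#' fit_saturation(tr)
#' @export
fit_saturation <- function(trace, dwell_s = NULL) {
  stopifnot(is.data.frame(trace),
            all(c("power_mW", "counts") %in% names(trace)))
  if (is.null(dwell_s)) dwell_s <- attr(trace, "dwell_s")
  if (is.null(dwell_s)) dwell_s <- 1
  df <- data.frame(p = trace$power_mW, z = trace$counts)
  warn <- NA_character_
  if (length(unique(df$p)) < 5) {
    warn <- "fewer than 5 distinct powers; P_sat poorly constrained"
    warning(warn)
  }
  a0 <- max(df$z)
  lower_half <- mean(df$z[df$p <= stats::median(df$p)])
  upper_half <- mean(df$z[df$p > stats::median(df$p)])
  if (lower_half >= 0.9 * upper_half) {
    warn <- "counts show no power dependence (already saturated?); P_sat poorly constrained"
    warning(warn)
  }
  low <- df$p > 0 & df$p <= stats::quantile(df$p[df$p > 0], 0.4)
  slope <- if (any(low)) {
    sum(df$z[low] * df$p[low]^2) / sum(df$p[low]^4)
  } else a0 / max(df$p)^2
  psat0 <- if (slope > 0) sqrt(a0 / slope) else max(df$p) / 2
  psat0 <- min(max(psat0, 0.1 * max(df$p)), 3 * max(df$p))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * (1 - exp(-(p / psat)^2)),
      data = df, start = list(A = a0, psat = psat0),
      weights = 1 / (df$z + 1),
      lower = c(A = 0, psat = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    stop("saturation fit did not converge (n = ", nrow(df),
         ", power range ", min(df$p), "-", max(df$p), " mW)")
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(A = NA_real_, psat = NA_real_))
  if (is.na(warn) && cf[["psat"]] > max(df$p)) {
    warn <- "data entirely in the quadratic regime; P_sat poorly constrained"
    warning(warn)
  }
  if (is.na(warn) && cf[["psat"]] < min(df$p[df$p > 0])) {
    warn <- "data entirely saturated; P_sat poorly constrained"
    warning(warn)
  }
  structure(list(
    p_sat_mW = unname(cf[["psat"]]),
    p_sat_se_mW = unname(se[["psat"]]),
    asymptote_cps = unname(cf[["A"]]) / dwell_s,
    asymptote_se_cps = unname(se[["A"]]) / dwell_s,
    A_counts = unname(cf[["A"]]),
    rss = sum(stats::resid(fit)^2),
    n_points = nrow(df),
    converged = TRUE,
    warning = warn
  ), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit: P_sat = %.3g +/- %.2g mW, asymptote = %.3g cps (n = %d)\n",
              x$p_sat_mW, x$p_sat_se_mW, x$asymptote_cps, x$n_points))
  invisible(x)
}

#' Normalize a sweep to its fitted asymptote
#'
#' Divides the counts by the fitted asymptotic count level so that the trace
#' approaches 1 at high power; normalized traces from different particles
#' become directly comparable.
#'
#' @param trace A `sweep_trace` data.frame.
#' @param fit Its [fit_saturation()] result.
#' @return The trace with an added column `normalized`.
#' @export
normalize_to_asymptote <- function(trace, fit) {
  stopifnot(inherits(fit, "saturation_fit"))
  if (!is.finite(fit$A_counts) || fit$A_counts <= 0) {
    stop("fitted asymptote must be positive")
  }
  trace$normalized <- trace$counts / fit$A_counts
  trace
}

#' Ensemble saturation curve over many particles
#'
#' Normalizes each sweep to its own fitted asymptote, interpolates all
#' normalized curves onto a common power grid, and reports the pointwise
#' mean and standard deviation band together with a saturation-curve fit of
#' the mean curve (the ensemble estimate of `P_sat`).
#'
#' @param traces List of `sweep_trace` data.frames.
#' @param power_grid_mW Common power grid (mW); defaults to the sorted
#'   unique powers shared by the traces' span.
#' @return A list of class `ensemble_saturation`: `power_mW`, `mean`, `sd`
#'   (vectors over the grid), `n_traces`, `fit` (a `saturation_fit` of the
#'   mean curve, asymptote in normalized units), `per_particle_psat_mW`.
#' @examples
#' trs <- lapply(1:5, function(i) generate_saturation_sweep(
#'   seq(1, 20, length.out = 12), dfon_species("dFONs2"), seed = i))
#' ensemble_saturation(trs)
#' @export
ensemble_saturation <- function(traces, power_grid_mW = NULL) {
  stopifnot(is.list(traces), length(traces) >= 2)
  lo <- max(vapply(traces, function(tr) min(tr$power_mW), 0))
  hi <- min(vapply(traces, function(tr) max(tr$power_mW), 0))
  if (lo >= hi) stop("traces have disjoint power ranges")
  if (is.null(power_grid_mW)) {
    power_grid_mW <- sort(unique(unlist(lapply(traces, function(tr)
      tr$power_mW[tr$power_mW >= lo & tr$power_mW <= hi]))))
  }
  fits <- lapply(traces, fit_saturation)
  norm_mat <- vapply(seq_along(traces), function(i) {
    tr <- normalize_to_asymptote(traces[[i]], fits[[i]])
    stats::approx(tr$power_mW, tr$normalized, xout = power_grid_mW,
                  rule = 2, ties = mean)$y
  }, numeric(length(power_grid_mW)))
  norm_mat <- matrix(norm_mat, nrow = length(power_grid_mW))
  m <- rowMeans(norm_mat)
  s <- apply(norm_mat, 1, stats::sd)
  mean_trace <- structure(
    data.frame(power_mW = power_grid_mW, counts = m),
    dwell_s = 1, class = c("sweep_trace", "data.frame"))
  fit_mean <- fit_saturation(mean_trace)
  structure(list(
    power_mW = power_grid_mW, mean = m, sd = s,
    n_traces = length(traces), fit = fit_mean,
    per_particle_psat_mW = vapply(fits, `[[`, 0, "p_sat_mW")
  ), class = "ensemble_saturation")
}

#' Combined cross section and local-field coefficient from a saturation fit
#'
#' Composes [cross_section_from_psat()] (fitted `P_sat` to `alpha^2 sigma2`)
#' with [alpha_from_ensemble()] (division by the ensemble per-molecule cross
#' section). Uncertainty is propagated to first order: the relative standard
#' error of `alpha^2 sigma2` is twice that of `P_sat`, and that of `alpha`
#' equals that of `P_sat`.
#'
#' @param fit A `saturation_fit` (or any list with `p_sat_mW`,
#'   `p_sat_se_mW`).
#' @param instrument An [instrument_params()] object (calibrated).
#' @param sigma2_GM Ensemble per-molecule cross section (GM).
#' @return A list of class `local_field_result`: `alpha2_sigma2_GM` (+`_se`),
#'   `alpha` (+`_se`), `p_sat_mW`, `sigma2_GM`, `geometry_factor`.
#' @examples
#' instr <- default_instrument()
#' f <- list(p_sat_mW = 17.3, p_sat_se_mW = 0.5)
#' derive_cross_section(f, instr, 60)
#' @export
derive_cross_section <- function(fit, instrument, sigma2_GM) {
  stopifnot(fit$p_sat_mW > 0, sigma2_GM > 0)
  a2s2 <- cross_section_from_psat(fit$p_sat_mW, instrument)
  alpha <- alpha_from_ensemble(a2s2, sigma2_GM)
  rel <- if (is.null(fit$p_sat_se_mW) || !is.finite(fit$p_sat_se_mW)) {
    NA_real_
  } else fit$p_sat_se_mW / fit$p_sat_mW
  structure(list(
    alpha2_sigma2_GM = a2s2,
    alpha2_sigma2_se_GM = 2 * rel * a2s2,
    alpha = alpha,
    alpha_se = rel * alpha,
    p_sat_mW = fit$p_sat_mW,
    sigma2_GM = sigma2_GM,
    geometry_factor = instrument$geometry_factor
  ), class = "local_field_result")
}

#' @export
print.local_field_result <- function(x, ...) {
  cat(sprintf("alpha^2 sigma2 = %.3g GM (P_sat = %.3g mW), alpha = %.2f\n",
              x$alpha2_sigma2_GM, x$p_sat_mW, x$alpha))
  invisible(x)
}

#' Fit a monoexponential bleaching decay
#'
#' Weighted least squares of `counts = S0_counts * exp(-t / tau_b) + bg` per
#' bin, with Poisson weights `1 / (counts + 1)`. The background can be fixed
#' to zero. Rates (`s0_rate`, `background_rate`) are returned in counts/s
#' using the bin width.
#'
#' @param trace A `decay_trace` data.frame (columns `time_s`, `counts`),
#'   e.g. from [generate_bleach_trace()] or [read_decay_csv()].
#' @param bin_s Bin width (s); defaults to the trace attribute, else the
#'   median time step.
#' @param fit_background Estimate a constant background (default) or fix it
#'   to zero.
#' @return A list of class `decay_fit`: `tau_b_s`, `tau_b_se_s`, `s0_rate`,
#'   `background_rate`, `rss`, `n_bins`, `converged`, `reason` (NA when
#'   accepted).
#' @examples
#' tr <- generate_bleach_trace(5.29, dfon_species("dFONs2"), seed = 1)
#' fit_decay(tr)
#' @export
fit_decay <- function(trace, bin_s = NULL, fit_background = TRUE) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "counts") %in% names(trace)))
  if (is.null(bin_s)) bin_s <- attr(trace, "bin_s")
  if (is.null(bin_s)) bin_s <- stats::median(diff(trace$time_s))
  df <- data.frame(t = trace$time_s, z = trace$counts)
  if (nrow(df) < 10) warning("fewer than 10 bins; tau_b poorly constrained")
  reject <- function(reason) {
    structure(list(tau_b_s = NA_real_, tau_b_se_s = NA_real_,
                   s0_rate = NA_real_, background_rate = NA_real_,
                   rss = NA_real_, n_bins = nrow(df), converged = FALSE,
                   reason = reason), class = "decay_fit")
  }
  s0_0 <- max(mean(utils::head(df$z, 5)), 1)
  tail_m <- mean(utils::tail(df$z, max(3, nrow(df) %/% 10)))
  if (tail_m >= 0.8 * s0_0) {
    return(reject("tau_b unbounded (trace shows no decay)"))
  }
  # crude tau start: time to fall to (s0 + tail)/2
  half <- which(df$z <= (s0_0 + tail_m) / 2)
  tau0 <- if (length(half)) max(df$t[half[1]], bin_s) / log(2) else
    max(df$t) / 2
  span <- max(df$t) - min(df$t)
  fit <- tryCatch({
    if (fit_background) {
      minpack.lm::nlsLM(z ~ s0 * exp(-t / tau) + bg, data = df,
                        start = list(s0 = s0_0, tau = tau0,
                                     bg = max(tail_m, 0.01)),
                        weights = 1 / (df$z + 1),
                        lower = c(s0 = 0, tau = bin_s / 10, bg = 0),
                        upper = c(s0 = Inf, tau = 100 * span, bg = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(z ~ s0 * exp(-t / tau), data = df,
                        start = list(s0 = s0_0, tau = tau0),
                        weights = 1 / (df$z + 1),
                        lower = c(s0 = 0, tau = bin_s / 10),
                        upper = c(s0 = Inf, tau = 100 * span),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(reject("fit did not converge"))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(
                   rep(NA_real_, length(cf)), names(cf)))
  tau <- unname(cf[["tau"]])
  if (tau >= 50 * span) {
    return(reject("tau_b unbounded (trace shows no decay)"))
  }
  if (tau <= bin_s / 5) {
    return(reject("tau_b at lower bound (decay faster than binning)"))
  }
  structure(list(
    tau_b_s = tau,
    tau_b_se_s = unname(se[["tau"]]),
    s0_rate = unname(cf[["s0"]]) / bin_s,
    background_rate = if (fit_background) unname(cf[["bg"]]) / bin_s else 0,
    rss = sum(stats::resid(fit)^2),
    n_bins = nrow(df), converged = TRUE, reason = NA_character_
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("Bleaching fit: tau_b = %.3g +/- %.2g s, S0 = %.3g cps (n = %d bins)\n",
                x$tau_b_s, x$tau_b_se_s, x$s0_rate, x$n_bins))
  } else {
    cat(sprintf("Bleaching fit rejected: %s\n", x$reason))
  }
  invisible(x)
}

#' Aggregate per-trace bleaching times by excitation power
#'
#' @param powers_mW Excitation power of each trace (mW).
#' @param tau_b_s Fitted bleaching time of each trace (s); `NA`s dropped.
#' @return A data.frame with one row per distinct power: `power_mW`,
#'   `tau_mean_s`, `tau_sd_s`, `n`.
#' @export
aggregate_bleach_times <- function(powers_mW, tau_b_s) {
  stopifnot(length(powers_mW) == length(tau_b_s))
  ok <- is.finite(tau_b_s)
  powers_mW <- powers_mW[ok]; tau_b_s <- tau_b_s[ok]
  if (length(tau_b_s) == 0) stop("no finite bleaching times")
  sp <- split(tau_b_s, powers_mW)
  out <- data.frame(
    power_mW = as.numeric(names(sp)),
    tau_mean_s = vapply(sp, mean, 0),
    tau_sd_s = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else
      NA_real_, 0),
    n = vapply(sp, length, 0L)
  )
  rownames(out) <- NULL
  out[order(out$power_mW), ]
}

#' Fit the quadratic bleaching power law
#'
#' Fits `tau_b = tau_b0 * (P_sat / P)^2` to per-power mean bleaching times
#' by weighted least squares (weights `1 / sd^2` where the per-power spread
#' is available). `P_sat` and `tau_b0` are degenerate in a pure power law
#' (only `tau_b0 * P_sat^2` is identifiable), so `P_sat` must be supplied
#' from the saturation stage and is never co-fitted. Separately, an
#' unconstrained log-log linear regression returns the power-law slope
#' (expected -2) with its standard error.
#'
#' @param bleach_table Data.frame from [aggregate_bleach_times()] (columns
#'   `power_mW`, `tau_mean_s`, optionally `tau_sd_s`, `n`), with `>= 3`
#'   distinct powers.
#' @param p_sat_mW Saturation power (mW) from the saturation stage.
#' @return A list of class `bleach_law_fit`: `tau_b0_s`, `tau_b0_se_s`,
#'   `p_sat_mW`, `loglog_slope`, `loglog_slope_se`, `n_powers`.
#' @examples
#' tb <- data.frame(power_mW = c(3, 5, 8),
#'                  tau_mean_s = 3.84 * (5.29 / c(3, 5, 8))^2,
#'                  tau_sd_s = c(0.3, 0.2, 0.1))
#' fit_bleach_law(tb, 5.29)
#' @export
fit_bleach_law <- function(bleach_table, p_sat_mW) {
  stopifnot(is.data.frame(bleach_table),
            all(c("power_mW", "tau_mean_s") %in% names(bleach_table)),
            p_sat_mW > 0)
  tb <- bleach_table[is.finite(bleach_table$tau_mean_s), ]
  if (length(unique(tb$power_mW)) < 3) {
    stop("at least 3 distinct powers are required")
  }
  w <- if ("tau_sd_s" %in% names(tb) && all(is.finite(tb$tau_sd_s)) &&
           all(tb$tau_sd_s > 0)) 1 / tb$tau_sd_s^2 else
    rep(1, nrow(tb))
  x <- (p_sat_mW / tb$power_mW)^2
  # linear in tau_b0: weighted LS through the origin
  tau_b0 <- sum(w * x * tb$tau_mean_s) / sum(w * x^2)
  resid <- tb$tau_mean_s - tau_b0 * x
  dof <- nrow(tb) - 1
  tau_b0_se <- sqrt(sum(w * resid^2) / dof / sum(w * x^2))
  ll <- stats::lm(log(tau_mean_s) ~ log(power_mW), data = tb)
  # suppress the spurious perfect-fit warning on exact power-law input
  sl <- suppressWarnings(summary(ll))$coefficients
  structure(list(
    tau_b0_s = tau_b0, tau_b0_se_s = tau_b0_se, p_sat_mW = p_sat_mW,
    loglog_slope = unname(sl["log(power_mW)", "Estimate"]),
    loglog_slope_se = unname(sl["log(power_mW)", "Std. Error"]),
    n_powers = nrow(tb)
  ), class = "bleach_law_fit")
}

#' @export
print.bleach_law_fit <- function(x, ...) {
  cat(sprintf(
    "Bleaching law: tau_b0 = %.3g +/- %.2g s at P_sat = %.3g mW; log-log slope %.3f +/- %.3f\n",
    x$tau_b0_s, x$tau_b0_se_s, x$p_sat_mW, x$loglog_slope, x$loglog_slope_se))
  invisible(x)
}
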