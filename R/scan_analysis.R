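# Scan-stage pipeline: detect bright spots in a photon-count raster, fit a
# 2D Gaussian PSF to each, normalize the peak rate by the squared excitation
# power, and compare brightness populations.

#' Detect candidate nanoparticle spots in a scan image
#'
#' Estimates the background level and spread robustly (median and MAD over
#' all pixels), then returns local maxima exceeding
#' `background + threshold_sigma * sigma_bg`, with greedy non-maximum
#' suppression at the given minimum separation.
#'
#' @param image Integer count matrix (rows = y).
#' @param pixel_nm Pixel size (nm).
#' @param min_separation_nm Minimum centre-to-centre separation (nm); closer
#'   maxima are suppressed in favour of the brighter one.
#' @param threshold_sigma Detection threshold in units of the robust
#'   background standard deviation.
#' @return A data.frame with one row per candidate: `row`, `col` (pixel
#'   indices), `x_nm`, `y_nm` (pixel-centre coordinates), `value` (counts);
#'   ordered by decreasing `value`. Zero rows is a valid result.
#' @examples
#' sc <- generate_scan(5, seed = 1)
#' detect_spots(sc$image, sc$meta$pixel_nm)
#' @export
detect_spots <- function(image, pixel_nm,
                         min_separation_nm = 600,
                         threshold_sigma = 5) {
  stopifnot(is.matrix(image), length(image) > 0, pixel_nm > 0,
            min_separation_nm >= 0, threshold_sigma >= 0)
  bg <- stats::median(image)
  sigma_bg <- max(stats::mad(image), sqrt(max(bg, 1)) * 0.5)
  thr <- bg + threshold_sigma * sigma_bg
  nr <- nrow(image); nc <- ncol(image)
  # strict local maximum over the 8-neighbourhood (ties broken by >=)
  cand <- which(image > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; cl <- cand[i, 2]
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, cl - 1):min(nc, cl + 1)
    keep[i] <- image[r, cl] == max(image[rr, cc])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(row = integer(), col = integer(),
                      x_nm = numeric(), y_nm = numeric(), value = numeric()))
  }
  val <- image[cand]
  ord <- order(val, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  val <- val[ord]
  # greedy non-maximum suppression
  sel <- integer()
  min_sep_px2 <- (min_separation_nm / pixel_nm)^2
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in sel) {
      d2 <- (cand[i, 1] - cand[j, 1])^2 + (cand[i, 2] - cand[j, 2])^2
      if (d2 < min_sep_px2) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  cand <- cand[sel, , drop = FALSE]
  data.frame(
    row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
    x_nm = (cand[, 2] - 0.5) * pixel_nm,
    y_nm = (cand[, 1] - 0.5) * pixel_nm,
    value = val[sel]
  )
}

#' Fit a 2D Gaussian PSF to one candidate spot
#'
#' Least-squares fit of `offset + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 s^2))`
#' to the counts in a square window around the candidate (Levenberg-
#' Marquardt). The symmetric model is the default; the anisotropic variant
#' (separate `sx`, `sy`) supports aggregate flagging. Amplitude and offset
#' are returned as count rates (counts divided by the dwell time).
#'
#' @param image Integer count matrix.
#' @param candidate One row of the [detect_spots()] result (needs `row`,
#'   `col`), or a list with those fields.
#' @param pixel_nm Pixel size (nm).
#' @param dwell_s Integration time per pixel (s).
#' @param window_px Half-width of the square fit window (pixels).
#' @param shape `"symmetric"` (one width) or `"anisotropic"` (`sx`, `sy`).
#' @return An object of class `spot_fit`: list with `x0_nm`, `y0_nm`,
#'   `amplitude_cps`, `amplitude_se_cps`, `sigma_nm` (and `sigma_y_nm` for
#'   the anisotropic shape), `offset_cps`, `rss`, `n_pixels`, `converged`,
#'   `reason` (`NA` when accepted), `shape`.
#' @examples
#' sc <- generate_scan(1, n_particles = 1, seed = 2)
#' cand <- detect_spots(sc$image, sc$meta$pixel_nm)
#' if (nrow(cand) > 0) fit_psf(sc$image, cand[1, ], sc$meta$pixel_nm,
#'                             sc$meta$dwell_s)
#' @export
fit_psf <- function(image, candidate, pixel_nm, dwell_s,
                    window_px = 7, shape = c("symmetric", "anisotropic")) {
  shape <- match.arg(shape)
  stopifnot(is.matrix(image), pixel_nm > 0, dwell_s > 0, window_px >= 2)
  r0 <- candidate$row[1]; c0 <- candidate$col[1]
  rr <- max(1, r0 - window_px):min(nrow(image), r0 + window_px)
  cc <- max(1, c0 - window_px):min(ncol(image), c0 + window_px)
  sub <- image[rr, cc, drop = FALSE]
  df <- data.frame(
    x = rep((cc - 0.5) * pixel_nm, each = length(rr)),
    y = rep((rr - 0.5) * pixel_nm, times = length(cc)),
    z = as.vector(sub)
  )
  off0 <- stats::median(df$z)
  a0 <- max(df$z) - off0
  reject <- function(reason) {
    structure(list(x0_nm = NA_real_, y0_nm = NA_real_,
                   amplitude_cps = NA_real_, amplitude_se_cps = NA_real_,
                   sigma_nm = NA_real_, sigma_y_nm = NA_real_,
                   offset_cps = NA_real_, rss = NA_real_,
                   n_pixels = nrow(df), converged = FALSE, reason = reason,
                   shape = shape),
              class = "spot_fit")
  }
  if (a0 <= 0) return(reject("no signal above local median"))
  start <- list(A = a0, x0 = (c0 - 0.5) * pixel_nm,
                y0 = (r0 - 0.5) * pixel_nm, s = 2.5 * pixel_nm, off = off0)
  fit <- tryCatch({
    if (shape == "symmetric") {
      minpack.lm::nlsLM(
        z ~ off + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
        data = df, start = start,
        weights = 1 / (df$z + 1),
        lower = c(A = 0, x0 = min(df$x), y0 = min(df$y),
                  s = 0.3 * pixel_nm, off = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        z ~ off + A * exp(-(x - x0)^2 / (2 * sx^2) -
                            (y - y0)^2 / (2 * sy^2)),
        data = df,
        start = list(A = start$A, x0 = start$x0, y0 = start$y0,
                     sx = start$s, sy = start$s, off = start$off),
        weights = 1 / (df$z + 1),
        lower = c(A = 0, x0 = min(df$x), y0 = min(df$y),
                  sx = 0.3 * pixel_nm, sy = 0.3 * pixel_nm, off = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(reject("fit did not converge"))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  if (cf[["A"]] <= 0) return(reject("non-positive fitted amplitude"))
  structure(list(
    x0_nm = unname(cf[["x0"]]), y0_nm = unname(cf[["y0"]]),
    amplitude_cps = unname(cf[["A"]]) / dwell_s,
    amplitude_se_cps = unname(se[["A"]]) / dwell_s,
    sigma_nm = unname(if (shape == "symmetric") cf[["s"]] else cf[["sx"]]),
    sigma_y_nm = unname(if (shape == "symmetric") NA_real_ else cf[["sy"]]),
    offset_cps = unname(cf[["off"]]) / dwell_s,
    rss = sum(stats::resid(fit)^2),
    n_pixels = nrow(df), converged = TRUE, reason = NA_character_,
    shape = shape
  ), class = "spot_fit")
}

#' Power-squared brightness normalization
#'
#' Two-photon emission scales with the square of the excitation power in the
#' non-saturated regime, so peak rates measured at different powers are made
#' comparable by dividing by `P_exc^2`. Returns kilocounts/s/mW^2, the
#' conventional unit for these scans.
#'
#' @param amplitude_cps Fitted peak rate above offset (counts/s); vectorized.
#' @param p_exc_mW Excitation power used for the scan (mW).
#' @return Normalized brightness (kcounts s^-1 mW^-2).
#' @examples
#' normalize_brightness(6e5, 1.7)   # ~207.6
#' @export
normalize_brightness <- function(amplitude_cps, p_exc_mW) {
  if (!is.numeric(p_exc_mW) || p_exc_mW <= 0) stop("p_exc_mW must be > 0")
  if (any(amplitude_cps < 0, na.rm = TRUE)) stop("amplitude must be >= 0")
  amplitude_cps / 1000 / p_exc_mW^2
}

#' Flag spots whose shape departs from the PSF
#'
#' A single sub-diffraction particle images as the instrument PSF; a fitted
#' width far from the reference width, or a strongly anisotropic fit, points
#' to an aggregate (or other non-pointlike object).
#'
#' @param fit A `spot_fit` from [fit_psf()].
#' @param sigma_ref_nm Reference PSF standard deviation (nm), typically
#'   `W0 / sqrt(2)`.
#' @param tolerance Allowed relative deviation of the fitted width(s) from
#'   the reference, and of the axis ratio from 1.
#' @return Logical flag (`TRUE` = aggregate-like); `NA` for rejected fits.
#' @export
flag_aggregates <- function(fit, sigma_ref_nm, tolerance = 0.3) {
  stopifnot(sigma_ref_nm > 0, tolerance > 0)
  if (!isTRUE(fit$converged)) return(NA)
  dev <- abs(fit$sigma_nm - sigma_ref_nm) / sigma_ref_nm
  flagged <- dev > tolerance
  if (!is.na(fit$sigma_y_nm)) {
    dev_y <- abs(fit$sigma_y_nm - sigma_ref_nm) / sigma_ref_nm
    aniso <- abs(fit$sigma_nm / fit$sigma_y_nm - 1)
    flagged <- flagged || dev_y > tolerance || aniso > tolerance
  }
  flagged
}

#' Summary statistics of a brightness population
#'
#' Median, quartiles (linear-interpolation convention, quantile type 7),
#' mean and standard deviation of a set of normalized brightness values.
#' Right-skewed populations (aggregates) show mean well above median.
#'
#' @param x Numeric vector of brightness values, `n >= 1`.
#' @return A list of class `population_summary`: `n`, `median`, `q1`, `q3`,
#'   `mean`, `sd`.
#' @examples
#' population_stats(c(1, 2, 3, 4, 5))
#' @export
population_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty input")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    n = length(x), median = q[2], q1 = q[1], q3 = q[3],
    mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d  median = %.4g [Q1 %.4g, Q3 %.4g]  mean = %.4g  sd = %.4g\n",
    x$n, x$median, x$q1, x$q3, x$mean, x$sd))
  invisible(x)
}

#' Two-sample comparison of brightness populations
#'
#' Two-sided two-sample t-test of equal means; Welch (unequal variances) by
#' default, with the pooled-variance Student variant as an option. Two
#' degenerate samples (both zero variance, equal means) return `p = 1` by
#' convention.
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A list with `statistic` (t), `p_value`, `df`, `method`.
#' @examples
#' compare_populations(rnorm(50), rnorm(50))
#' @export
compare_populations <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1,
                  df = length(a) + length(b) - 2,
                  method = if (var_equal) "Student" else "Welch"))
    }
    return(list(statistic = Inf * sign(mean(a) - mean(b)), p_value = 0,
                df = length(a) + length(b) - 2,
                method = if (var_equal) "Student" else "Welch"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       method = if (var_equal) "Student" else "Welch")
}

#' Full scan-analysis stage
#'
#' Detects spots, fits the PSF model to each, converts fitted amplitudes to
#' power-normalized brightness, and flags aggregate-like spots. Aggregates
#' are retained in the brightness table (population means deliberately
#' include them) but can be excluded downstream via the flag.
#'
#' @param image Integer count matrix.
#' @param pixel_nm Pixel size (nm).
#' @param dwell_s Dwell time per pixel (s).
#' @param p_exc_mW Scan excitation power (mW).
#' @param psf_sigma_nm Reference PSF standard deviation (nm).
#' @param threshold_sigma Detection threshold ([detect_spots()]).
#' @param min_separation_nm Non-maximum-suppression radius (nm).
#' @param window_px PSF fit window half-width (pixels).
#' @param aggregate_tolerance Width tolerance for [flag_aggregates()].
#' @param shape PSF model shape passed to [fit_psf()].
#' @return A data.frame of accepted spots: `x_nm`, `y_nm`, `amplitude_cps`,
#'   `sigma_nm`, `sigma_y_nm`, `offset_cps`, `brightness` (kcounts s^-1
#'   mW^-2), `aggregate`; attribute `n_rejected` counts failed fits.
#' @examples
#' sc <- generate_scan(10, seed = 3)
#' spots <- analyze_scan(sc$image, sc$meta$pixel_nm, sc$meta$dwell_s,
#'                       sc$meta$p_exc_mW)
#' population_stats(spots$brightness)
#' @export
analyze_scan <- function(image, pixel_nm, dwell_s, p_exc_mW,
                         psf_sigma_nm = 360 / sqrt(2),
                         threshold_sigma = 5,
                         min_separation_nm = 600,
                         window_px = 7,
                         aggregate_tolerance = 0.3,
                         shape = "symmetric") {
  cands <- detect_spots(image, pixel_nm, min_separation_nm, threshold_sigma)
  rows <- list(); n_rej <- 0L
  for (i in seq_len(nrow(cands))) {
    ft <- fit_psf(image, cands[i, ], pixel_nm, dwell_s,
                  window_px = window_px, shape = shape)
    if (!isTRUE(ft$converged)) { n_rej <- n_rej + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      x_nm = ft$x0_nm, y_nm = ft$y0_nm,
      amplitude_cps = ft$amplitude_cps,
      sigma_nm = ft$sigma_nm, sigma_y_nm = ft$sigma_y_nm,
      offset_cps = ft$offset_cps,
      brightness = normalize_brightness(ft$amplitude_cps, p_exc_mW),
      aggregate = flag_aggregates(ft, psf_sigma_nm, aggregate_tolerance)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_nm = numeric(), y_nm = numeric(),
               amplitude_cps = numeric(), sigma_nm = numeric(),
               sigma_y_nm = numeric(), offset_cps = numeric(),
               brightness = numeric(), aggregate = logical())
  attr(out, "n_rejected") <- n_rej
  out
}
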