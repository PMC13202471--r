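# File formats: 16-bit grayscale TIFF for scan rasters (counts per pixel),
# CSV for traces, JSON sidecars for ground truth and metadata, YAML config.

#' Write a scan image as 16-bit TIFF with a JSON sidecar
#'
#' Counts are stored as unsigned 16-bit samples; the sidecar (`<path>.json`)
#' carries the acquisition metadata and, for synthetic scans, the
#' ground-truth particle table and generation seed.
#'
#' @param scan A `synthetic_scan` (from [generate_scan()]) or a bare count
#'   matrix.
#' @param path Output TIFF path.
#' @param meta Metadata list (ignored when `scan` carries its own).
#' @return `path`, invisibly.
#' @export
write_scan_tiff <- function(scan, path, meta = NULL) {
  if (inherits(scan, "synthetic_scan")) {
    img <- scan$image
    meta <- scan$meta
    truth <- scan$truth
  } else {
    img <- scan
    truth <- NULL
  }
  stopifnot(is.matrix(img), all(img >= 0))
  if (max(img) > 65535) {
    warning("counts exceed 16-bit range and will be clipped")
    img <- pmin(img, 65535)
  }
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(meta = meta)
  if (!is.null(truth)) sidecar$truth <- truth
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a scan TIFF (and sidecar, when present)
#'
#' @param path TIFF path written by [write_scan_tiff()] (or any 16-bit
#'   grayscale TIFF of counts).
#' @return A list: `image` (integer count matrix), `meta`, `truth`
#'   (data.frame or NULL).
#' @export
read_scan_tiff <- function(path) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  img <- round(raw)
  storage.mode(img) <- "integer"
  meta <- NULL; truth <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta <- side$meta
    if (!is.null(side$truth) && length(side$truth)) {
      truth <- as.data.frame(side$truth)
    }
  }
  list(image = img, meta = meta, truth = truth)
}

#' Write a power sweep or decay trace as CSV
#'
#' Sweeps get columns `power_mW, counts`; decays get `time_s, counts`.
#' Acquisition attributes (dwell or bin width, power, particle id) are
#' stored as `# key: value` header comments so a trace file is
#' self-describing.
#'
#' @param trace A `sweep_trace` or `decay_trace` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  hdr <- character()
  for (k in c("dwell_s", "bin_s", "p_exc_mW", "particle_id")) {
    v <- attr(trace, k)
    if (!is.null(v)) hdr <- c(hdr, sprintf("# %s: %s", k, format(v)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

read_trace_csv <- function(path, required) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(required %in% names(df))) {
    stop("trace file ", path, " lacks required columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    attr(df, key) <- if (is.na(num)) val else num
  }
  df
}

#' Read a saturation sweep CSV
#'
#' @param path CSV with columns `power_mW, counts` (and optional `# key:
#'   value` header attributes, see [write_trace_csv()]).
#' @return A `sweep_trace` data.frame.
#' @export
read_sweep_csv <- function(path) {
  df <- read_trace_csv(path, c("power_mW", "counts"))
  class(df) <- c("sweep_trace", "data.frame")
  df
}

#' Read a bleaching decay CSV
#'
#' @param path CSV with columns `time_s, counts` (and optional header
#'   attributes).
#' @return A `decay_trace` data.frame.
#' @export
read_decay_csv <- function(path) {
  df <- read_trace_csv(path, c("time_s", "counts"))
  class(df) <- c("decay_trace", "data.frame")
  df
}

.config_schema <- list(
  instrument = c("wavelength_nm", "rep_rate_hz", "pulse_tau_s", "waist_nm",
                 "collection_efficiency", "tau_interpretation",
                 "calibration_psat_mW", "calibration_alpha2_sigma2_GM"),
  species = c("name", "sigma2_GM", "phi", "diameter_nm", "n_molecules",
              "tau_b0_s", "psat_mW", "relative_density", "molar_mass_g_mol",
              "size_modes_nm", "size_sds_nm", "size_weights"),
  generator = c("scan_particles", "scan_width_px", "scan_height_px",
                "pixel_nm", "dwell_s", "scan_power_mW", "background_rate",
                "aggregate_fraction", "detection_scale",
                "sweep_powers_mW", "sweep_dwell_s", "sweep_peak_rate",
                "n_sweeps", "bleach_powers_mW", "bleach_traces_per_power",
                "bleach_bin_s", "bleach_s0_rate"),
  analysis = c("threshold_sigma", "min_separation_nm", "window_px",
               "aggregate_tolerance", "t_test_var_equal", "fit_background"),
  top = c("instrument", "species", "generator", "analysis", "seed",
          "output_dir")
)

#' Read and validate a run configuration
#'
#' The configuration is a YAML (or JSON) document with blocks `instrument`,
#' `species` (a list of family blocks), `generator`, `analysis`, plus `seed`
#' and `output_dir`. Unknown keys anywhere are rejected, so typos fail
#' loudly before any stage runs. Missing values fall back to the package
#' defaults (the printed instrument constants and the two reference
#' families). The instrument geometry factor is calibrated from the
#' `calibration_*` pair of the instrument block (default: the family-1
#' reference pair).
#'
#' @param path Path to a YAML or JSON config file, or `NULL` for the packaged
#'   default (`inst/extdata/default_config.yaml`).
#' @return A list of class `run_config`: `instrument` (calibrated
#'   [instrument_params()]), `species` (named list of [species_params()]),
#'   `size_specs` (named list of [size_population()]), `generator`,
#'   `analysis`, `seed`, `output_dir`.
#' @examples
#' cfg <- read_config()   # packaged defaults
#' names(cfg$species)
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "dfonphot", mustWork = TRUE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  num_vec <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
  }
  check_keys(raw, .config_schema$top, "top level")
  ib <- raw$instrument %||% list()
  check_keys(ib, .config_schema$instrument, "instrument")
  instr <- instrument_params(
    wavelength_nm = ib$wavelength_nm %||% 1030,
    rep_rate_hz = ib$rep_rate_hz %||% 80e6,
    pulse_tau_s = ib$pulse_tau_s %||% 135e-15,
    waist_nm = ib$waist_nm %||% 360,
    collection_efficiency = ib$collection_efficiency %||% 0.8,
    tau_interpretation = ib$tau_interpretation %||% "sech2"
  )
  instr <- calibrate_geometry_factor(
    instr,
    psat_ref_mW = ib$calibration_psat_mW %||% 17.3,
    alpha2_sigma2_ref_GM = ib$calibration_alpha2_sigma2_GM %||% 710
  )
  sp_blocks <- raw$species
  if (is.null(sp_blocks)) {
    species <- list(dFONs1 = dfon_species("dFONs1"),
                    dFONs2 = dfon_species("dFONs2"))
    size_specs <- list(dFONs1 = dfon_size_population("dFONs1"),
                       dFONs2 = dfon_size_population("dFONs2"))
  } else {
    species <- list(); size_specs <- list()
    for (sb in sp_blocks) {
      check_keys(sb, .config_schema$species, "species block")
      nm <- sb$name %||% stop("species block needs a name")
      base <- if (nm %in% c("dFONs1", "dFONs2")) dfon_species(nm) else NULL
      pick <- function(key, fallback) sb[[key]] %||%
        (if (!is.null(base)) base[[key]] else fallback)
      species[[nm]] <- species_params(
        name = nm,
        sigma2_GM = pick("sigma2_GM", stop("sigma2_GM required")),
        phi = pick("phi", stop("phi required")),
        diameter_nm = pick("diameter_nm", stop("diameter_nm required")),
        n_molecules = pick("n_molecules", stop("n_molecules required")),
        tau_b0_s = pick("tau_b0_s", NA_real_),
        psat_mW = pick("psat_mW", NA_real_),
        relative_density = pick("relative_density", 1),
        molar_mass_g_mol = sb$molar_mass_g_mol
      )
      size_specs[[nm]] <- if (!is.null(sb$size_modes_nm)) {
        modes <- num_vec(sb$size_modes_nm)
        size_population(modes,
                        num_vec(sb$size_sds_nm) %||% rep(3, length(modes)),
                        num_vec(sb$size_weights) %||%
                          rep(1, length(modes)))
      } else if (nm %in% c("dFONs1", "dFONs2")) {
        dfon_size_population(nm)
      } else {
        size_population(species[[nm]]$diameter_nm, 3, 1)
      }
    }
  }
  gb <- raw$generator %||% list()
  check_keys(gb, .config_schema$generator, "generator")
  gen <- list(
    scan_particles = gb$scan_particles %||% 20,
    scan_width_px = gb$scan_width_px %||% 100,
    scan_height_px = gb$scan_height_px %||% 100,
    pixel_nm = gb$pixel_nm %||% 100,
    dwell_s = gb$dwell_s %||% 0.010,
    scan_power_mW = gb$scan_power_mW %||% c(dFONs1 = 1.7, dFONs2 = 1.6),
    background_rate = gb$background_rate %||% 100,
    aggregate_fraction = gb$aggregate_fraction %||% 0.1,
    detection_scale = gb$detection_scale %||% 8e-5,
    sweep_powers_mW = num_vec(gb$sweep_powers_mW) %||%
      seq(1, 40, length.out = 15),
    sweep_dwell_s = gb$sweep_dwell_s %||% 1,
    sweep_peak_rate = gb$sweep_peak_rate %||% 1e5,
    n_sweeps = gb$n_sweeps %||% 50,
    bleach_powers_mW = num_vec(gb$bleach_powers_mW),
    bleach_traces_per_power = gb$bleach_traces_per_power %||% 10,
    bleach_bin_s = gb$bleach_bin_s %||% 0.010,
    bleach_s0_rate = gb$bleach_s0_rate %||% 1e5
  )
  ab <- raw$analysis %||% list()
  check_keys(ab, .config_schema$analysis, "analysis")
  ana <- list(
    threshold_sigma = ab$threshold_sigma %||% 5,
    min_separation_nm = ab$min_separation_nm %||% 600,
    window_px = ab$window_px %||% 7,
    aggregate_tolerance = ab$aggregate_tolerance %||% 0.3,
    t_test_var_equal = ab$t_test_var_equal %||% FALSE,
    fit_background = ab$fit_background %||% TRUE
  )
  structure(list(
    instrument = instr, species = species, size_specs = size_specs,
    generator = gen, analysis = ana,
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% "dfonphot-output"
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
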