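# Configuration loading/validation, CSV/JSON interchange and the pipeline
# orchestrator. CSV dialect: comma-separated, '.' decimal, mandatory header,
# UTF-8, units encoded in column names.

.config_keys <- c(
  "mass_amu", "sigma_m2", "alpha_v_m3", "wavelength_nm", "pulse_energy_mJ",
  "area_mm2", "reflectivity", "coherence_factor", "velocity_m_s",
  "divergence_mrad", "tilt_mrad", "order_n", "tau_off_ns", "gravity_m_s2",
  "extra_acceleration_m_s2", "grating_shift_nm", "mirror_offset_nm",
  "n0_eff", "beta", "grating_form", "seed"
)

#' Load and validate an interferometer configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration with
#' unit-suffixed keys (`mass_amu`, `wavelength_nm`, `tau_off_ns`, ...),
#' validates it against the known schema, converts to SI once, and returns
#' the assembled [interferometer_config()] together with a report of the
#' derived quantities (Talbot time, de Broglie wavelength, beta, per-
#' grating strengths). Unknown keys, a missing mass, or an inconsistent
#' double specification of the grating strength (both `n0_eff` and a
#' conflicting energy/area pair) are errors naming the offending key.
#'
#' @param path Path to the configuration file.
#' @param quiet Suppress the derived-quantity report.
#' @return A `tl_config` object; the raw key list is attached as attribute
#'   `raw`, the seed (if present) as attribute `seed`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$mass_amu)) {
    stop("configuration is missing required key 'mass_amu'", call. = FALSE)
  }
  args <- raw[setdiff(names(raw), "seed")]
  cfg <- do.call(interferometer_config, args)
  if (!quiet) {
    message(sprintf(
      paste0("derived quantities: T_T = %.4g us, lambda_dB = %.4g fm, ",
             "d = %.4g nm, beta = %.3g, n0_eff = %s"),
      cfg$timing$T_T * 1e6, cfg$derived$lambda_dB * 1e15,
      cfg$grating$period * 1e9, cfg$beta,
      paste(signif(cfg$n0_eff, 3), collapse = "/")))
  }
  attr(cfg, "raw") <- raw
  attr(cfg, "seed") <- raw$seed
  cfg
}

#' Write / read a fringe scan as CSV
#'
#' Columns `tau_ns`, `S_N`, `S_N_err`.
#' @param scan Data frame with those columns.
#' @param path Output path.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan)[, intersect(
    c("tau_ns", "S_N", "S_N_err", "S_N_model"), names(scan))],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  sc <- utils::read.csv(path)
  if (!all(c("tau_ns", "S_N") %in% names(sc))) {
    stop("scan CSV must have columns 'tau_ns' and 'S_N'", call. = FALSE)
  }
  structure(sc, class = c("tl_fringe_scan", "data.frame"))
}

#' Write a fit report as JSON
#'
#' Serializes a fringe or ionization fit (estimates, 1-sigma errors,
#' covariance, chi-square) to a JSON file.
#'
#' @param fit A `tl_fringe_fit` or `tl_ionization_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  est <- fit[setdiff(names(fit), c("fit", "cov", "se"))]
  out <- list(estimates = est, se = as.list(fit$se),
              covariance = unclass(fit$cov))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest
#'
#' Records the configuration snapshot, package version, seed, invocation
#' label and timestamp that produced a set of output files, so every
#' artifact can be traced to the run that generated it.
#'
#' @param cfg A `tl_config` (its raw key list is embedded when present).
#' @param seed Integer seed governing all randomness of the run.
#' @param command Free-text label of the invocation.
#' @return List of class `tl_manifest`.
#' @export
run_manifest <- function(cfg, seed, command = "") {
  raw <- attr(cfg, "raw")
  list(
    package = "talbotlau",
    version = as.character(utils::packageVersion("talbotlau")),
    command = command,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(raw)) raw else list(
      n0_eff = cfg$n0_eff, beta = cfg$beta,
      velocity_m_s = cfg$beam$v, order_n = cfg$timing$order)
  )
}

#' Run the simulation / fitting / closure pipeline
#'
#' Orchestrates the package stages over a configuration:
#' \describe{
#'   \item{`simulate`}{quantum and classical normalized scans over a delay
#'     grid, written as `scan.csv`.}
#'   \item{`fit`}{fringe fit of a supplied scan CSV, written as `fit.json`.}
#'   \item{`synth-closure`}{generate synthetic count records from the
#'     model, run them through the counting/contrast/fit pipeline, and
#'     report recovered versus configured divergence and tilt angles
#'     (`closure.json`).}
#' }
#' A `manifest.json` describing the run accompanies every output.
#'
#' @param cfg A `tl_config` (e.g. from [load_config()]).
#' @param mode One of `"simulate"`, `"fit"`, `"synth-closure"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param tau_grid_ns Delay grid, ns.
#' @param scan For `mode = "fit"`: a scan data frame or path to a scan CSV.
#' @return Invisibly, a list of output paths plus the computed objects.
#' @export
run_pipeline <- function(cfg, mode = c("simulate", "fit", "synth-closure"),
                         out_dir = ".", seed = 1,
                         tau_grid_ns = seq(-200, 200, by = 10),
                         scan = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- run_manifest(cfg, seed, command = mode)
  res <- tryCatch(
    switch(mode,
      "simulate" = {
        q <- normalized_scan(tau_grid_ns * 1e-9, cfg, "quantum")
        cl <- normalized_scan(tau_grid_ns * 1e-9, cfg, "classical")
        out <- data.frame(tau_ns = tau_grid_ns, S_N_quantum = q$S_N,
                          S_N_classical = cl$S_N)
        p <- file.path(out_dir, "scan.csv")
        utils::write.csv(out, p, row.names = FALSE)
        list(paths = p, scan = out)
      },
      "fit" = {
        if (is.character(scan)) scan <- read_scan_csv(scan)
        if (is.null(scan)) stop("mode 'fit' needs a 'scan'", call. = FALSE)
        ft <- fit_fringe(scan)
        p <- file.path(out_dir, "fit.json")
        write_fit_json(ft, p)
        list(paths = p, fit = ft)
      },
      "synth-closure" = {
        counts <- generate_fringe_counts(cfg, tau_grid_ns, seed = seed)
        sc <- counts_to_scan(counts)
        ft <- fit_fringe(sc)
        d <- cfg$grating$period
        v <- cfg$beam$v
        rec <- list(
          V0 = ft$V0,
          alpha_mrad = divergence_from_width(ft$sigma_w_ns * 1e-9, v, d) * 1e3,
          gamma_mrad = tilt_from_period(ft$sigma_p_ns * 1e-9, v, d) * 1e3,
          alpha_true_mrad = cfg$beam$alpha * 1e3,
          gamma_true_mrad = cfg$beam$gamma * 1e3)
        p <- file.path(out_dir, "closure.json")
        jsonlite::write_json(rec, p, auto_unbox = TRUE, digits = NA)
        list(paths = p, counts = counts, scan = sc, fit = ft, recovered = rec)
      }),
    error = function(e) stop(sprintf("stage '%s' failed: %s", mode,
                                     conditionMessage(e)), call. = FALSE))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(manifest = mp)))
}
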