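# Seeded generators emulating the statistical structure of the experiment:
# frame-wise Poisson detection toggled between resonant and off-resonant
# grating timing, ion-yield saturation curves, and per-conformer
# polarizability spread. All generators are bit-reproducible under a fixed
# seed and restore the caller's RNG state.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate frame-wise fringe count records from the interferometer model
#'
#' Emulates the acquisition structure of the experiment: at each delay on
#' the scan grid the interferometer toggles between the resonant mode
#' (delay `tau`) and the off-resonant reference (`tau_off`), recording
#' `frames_per_point` detector frames in each mode. The number of molecules
#' in a frame is Poisson with mean
#' `lambda(tau) = rate * S(tau) + background`, where `S` is the configured
#' model's detected signal and `rate` is scaled so that the off-resonant
#' mean occupancy equals `mean_occupancy` (sparse by default, so the
#' single-molecule-per-event counting assumption holds; occupancies near or
#' above 1 stress the dead-time correction instead). A frame registers an
#' event when it contains at least one molecule.
#'
#' @param cfg A [interferometer_config()].
#' @param tau_grid_ns Scan delays, ns.
#' @param frames_per_point Frames recorded per mode and delay.
#' @param mean_occupancy Mean molecules per frame in the off-resonant mode.
#' @param background Background events per frame (delay-independent).
#' @param model `"quantum"` or `"classical"`.
#' @param seed Integer seed (mandatory: generators are deterministic).
#' @return Data frame of count records: `tau_ns`, `mode` (`"res"`/`"off"`),
#'   `n_frames`, `n_event`.
#' @export
generate_fringe_counts <- function(cfg, tau_grid_ns = seq(-200, 200, by = 20),
                                   frames_per_point = 3000,
                                   mean_occupancy = 0.3,
                                   background = 0.01,
                                   model = "quantum", seed) {
  stopifnot(frames_per_point >= 1, mean_occupancy >= 0, background >= 0)
  tau <- tau_grid_ns * 1e-9
  S_off <- detected_signal(cfg, cfg$timing$tau_off, model)
  rate <- if (S_off > 0) mean_occupancy / S_off else 0
  lam_res <- rate * detected_signal(cfg, tau, model) + background
  lam_off <- rep(rate * S_off + background, length(tau))
  .with_seed(seed, {
    p_res <- 1 - exp(-lam_res)
    p_off <- 1 - exp(-lam_off)
    ev_res <- stats::rbinom(length(tau), frames_per_point, p_res)
    ev_off <- stats::rbinom(length(tau), frames_per_point, p_off)
    data.frame(
      tau_ns = rep(tau_grid_ns, 2),
      mode = rep(c("res", "off"), each = length(tau)),
      n_frames = frames_per_point,
      n_event = c(ev_res, ev_off)
    )
  })
}

#' Generate a Poisson-noised ion-yield saturation curve
#'
#' Poisson counts around the saturation model at each fluence, with
#' `sqrt(max(N, 1))` error bars (the Poisson counting convention used by
#' [fit_cross_section()]).
#'
#' @param sigma_PI Photoionization cross section, m^2.
#' @param N0 Total molecule number.
#' @param fluence_grid Photon fluences, photons/m^2.
#' @param seed Integer seed.
#' @return Data frame `fluence_per_m2`, `ion_counts`, `err`.
#' @export
generate_ion_yield <- function(sigma_PI, N0, fluence_grid, seed) {
  mu <- saturation_model(fluence_grid, N0, sigma_PI)
  .with_seed(seed, {
    counts <- stats::rpois(length(mu), mu)
    data.frame(fluence_per_m2 = fluence_grid, ion_counts = counts,
               err = sqrt(pmax(counts, 1)))
  })
}

#' Generate a per-conformer polarizability ensemble
#'
#' Normal draws around an ensemble-mean polarizability volume, emulating
#' the spread of per-conformer values whose average enters the grating
#' model (the electronic-structure origin of the spread is outside the
#' scope of this package; only the ensemble statistics matter here).
#'
#' @param mean_m3 Ensemble mean polarizability volume, m^3.
#' @param spread_m3 Per-conformer standard deviation, m^3.
#' @param n Number of conformers (>= 2).
#' @param seed Integer seed.
#' @return List with `values`, `mean` (sample mean) and `se` (standard
#'   error of the mean).
#' @export
generate_polarizability_ensemble <- function(mean_m3, spread_m3, n, seed) {
  .assert_pos(mean_m3, "mean_m3")
  .assert_nonneg(spread_m3, "spread_m3")
  stopifnot(n >= 2)
  .with_seed(seed, {
    vals <- stats::rnorm(n, mean_m3, spread_m3)
    list(values = vals, mean = mean(vals), se = stats::sd(vals) / sqrt(n))
  })
}
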