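# Near-resonant three-grating signal model: free propagation (phase-space
# shearing), grating transmission via Talbot coefficients, and the reduction
# of the full (k, l) index sum to k = -l close to the Talbot resonance.

#' Interferometer configuration
#'
#' Assembles the molecule, the three-grating light field, the beam
#' kinematics and the timing/geometry of a time-domain three-pulse
#' interferometer into a single validated object, with all derived
#' quantities (Talbot time, de Broglie wavelength, per-grating strengths,
#' beta) computed once.
#'
#' The grating strength may be specified either physically, via
#' `pulse_energy_mJ` and `area_mm2` (with `sigma_m2`/`alpha_v_m3` from the
#' molecule), or directly via `n0_eff` (with `beta` from the molecule's
#' optical properties or given explicitly). Supplying both routes with
#' inconsistent values is an error.
#'
#' @param mass_amu Molecular mass, amu.
#' @param wavelength_nm Grating laser wavelength, nm (period is half of it).
#' @param sigma_m2,alpha_v_m3 Molecular optical response (see
#'   [molecule_optics()]); optional when `n0_eff` and `beta` are given.
#' @param n0_eff Effective antinode photon number (scalar, or length 3 for
#'   unequal gratings). If `NULL`, derived from pulse energy and area.
#' @param beta Absorption-to-phase ratio; if `NULL`, derived from
#'   `sigma_m2`, `alpha_v_m3`, wavelength.
#' @param pulse_energy_mJ Per-grating pulse energy, mJ (scalar or length 3).
#' @param area_mm2 Illuminated area, mm^2.
#' @param reflectivity,coherence_factor Mirror reflectivity R and grating
#'   coherence factor C in (0, 1].
#' @param velocity_m_s Beam velocity, m/s.
#' @param divergence_mrad Beam divergence angle alpha, mrad.
#' @param tilt_mrad Beam tilt gamma relative to the mirror surface, mrad.
#' @param order_n Talbot order (1, 1/2, or any positive value); the pulse
#'   separation is `T = order_n * T_T` unless `pulse_separation_s` is given.
#' @param pulse_separation_s Pulse separation T, s (overrides `order_n`).
#' @param tau_off_ns Off-resonant reference delay, ns.
#' @param gravity_m_s2 Gravitational acceleration along the grating vector.
#' @param extra_acceleration_m_s2 Additional constant acceleration.
#' @param grating_shift_nm Relative grating shift
#'   `Dx_s = Dx_1 - 2 Dx_2 + Dx_3`, nm.
#' @param mirror_offset_nm Constant mirror offset b, nm.
#' @param grating_form `"realistic"` (default) or `"ideal"`: whether the
#'   diffraction grating's coefficients include the `(1+R)/(2RC)` running-
#'   wave enhancement of absorption (see [transmission_function()]).
#' @return Object of class `tl_config`.
#' @export
#' @examples
#' cfg <- interferometer_config(n0_eff = 3, beta = 0.6)
#' cfg$timing$T_T * 1e6  # Talbot time in microseconds, ~29.3
interferometer_config <- function(mass_amu = 1882,
                                  wavelength_nm = 157.63,
                                  sigma_m2 = 4.7e-20,
                                  alpha_v_m3 = 157e-30,
                                  n0_eff = 3,
                                  beta = NULL,
                                  pulse_energy_mJ = NULL,
                                  area_mm2 = NULL,
                                  reflectivity = 0.97,
                                  coherence_factor = 0.76,
                                  velocity_m_s = 600,
                                  divergence_mrad = 0.4,
                                  tilt_mrad = 1.7,
                                  order_n = 1,
                                  pulse_separation_s = NULL,
                                  tau_off_ns = 200,
                                  gravity_m_s2 = .tl$g_std,
                                  extra_acceleration_m_s2 = 0,
                                  grating_shift_nm = 0,
                                  mirror_offset_nm = 0,
                                  grating_form = c("realistic", "ideal")) {
  grating_form <- match.arg(grating_form)
  mol <- molecule_optics(mass_amu = mass_amu, sigma_m2 = sigma_m2,
                         alpha_v_m3 = alpha_v_m3)
  lam <- wavelength_nm * 1e-9
  d <- lam / 2
  R <- reflectivity; C <- coherence_factor
  if (is.null(beta)) beta <- beta_parameter(sigma_m2, alpha_v_m3, lam)

  energy_route <- !is.null(pulse_energy_mJ) && !is.null(area_mm2)
  if (energy_route) {
    E <- rep_len(pulse_energy_mJ * 1e-3, 3)
    A <- area_mm2 * 1e-6
    n0_bare <- photons_absorbed_antinode(sigma_m2, E, lam, A)
    n0_eff_derived <- R * C * n0_bare
    if (!is.null(n0_eff)) {
      if (any(abs(rep_len(n0_eff, 3) - n0_eff_derived) >
              1e-6 * pmax(1, n0_eff_derived))) {
        stop("inconsistent specification: 'n0_eff' conflicts with the value ",
             "derived from 'pulse_energy_mJ' and 'area_mm2'", call. = FALSE)
      }
    }
    n0_eff <- n0_eff_derived
  } else if (is.null(n0_eff)) {
    stop("supply either 'n0_eff' or both 'pulse_energy_mJ' and 'area_mm2'",
         call. = FALSE)
  }
  n0_eff <- rep_len(n0_eff, 3)
  phi0_eff <- n0_eff / (2 * beta)
  strengths <- lapply(1:3, function(k) {
    grating_strength(n0_eff[k] / (R * C), phi0_eff[k] / (R * C), R, C)
  })

  beam <- beam_kinematics(velocity_m_s = velocity_m_s,
                          divergence_rad = divergence_mrad * 1e-3,
                          tilt_rad = tilt_mrad * 1e-3,
                          gravity_m_s2 = gravity_m_s2,
                          extra_acceleration_m_s2 = extra_acceleration_m_s2)
  T_T <- talbot_time(mol$mass, d)
  if (is.null(pulse_separation_s)) {
    .assert_pos(order_n, "order_n")
    pulse_separation_s <- order_n * T_T
  }
  structure(list(
    molecule = mol,
    grating = grating_field(lam, reflectivity = R, coherence_factor = C),
    strengths = strengths,
    n0_eff = n0_eff, phi0_eff = phi0_eff, beta = beta,
    beam = beam,
    timing = list(order = order_n, T_T = T_T, T = pulse_separation_s,
                  tau_off = tau_off_ns * 1e-9),
    geometry = list(dxs = grating_shift_nm * 1e-9,
                    b = mirror_offset_nm * 1e-9),
    derived = list(lambda_dB = de_broglie_wavelength(mol$mass, beam$v),
                   p_gamma = mol$mass * beam$v * tan(beam$gamma)),
    form = grating_form
  ), class = "tl_config")
}

# Momentum-distribution width calibration. The transverse momentum
# distribution is a zero-mean normal of width sigma_p = m v alpha_eff. Its
# Fourier transform D~(x) = exp(-sigma_p^2 x^2 / (2 hbar^2)) multiplies the
# l-th signal harmonic at x = l tau d / T_T, so the l = 1 envelope is
# Gaussian in tau with width sigma_w = hbar T_T / (d sigma_p). Requiring
# the divergence relation alpha = arcsin(d / (2 v sigma_w sqrt(2 ln 10)))
# to hold exactly fixes alpha_eff = sin(alpha) sqrt(2 ln 10) / pi.
.alpha_eff <- function(alpha) sin(alpha) * sqrt(2 * log(10)) / pi

.dtilde <- function(x, cfg) {
  sigp <- cfg$molecule$mass * cfg$beam$v * .alpha_eff(cfg$beam$alpha)
  exp(-(sigp * x)^2 / (2 * .tl$hbar^2))
}

# Grating-2 coefficient parameters under the configured functional form.
.g2_params <- function(cfg) {
  if (cfg$form == "ideal") {
    list(n0 = cfg$n0_eff[2], beta = cfg$beta)
  } else {
    fac <- (1 + cfg$grating$R) / (2 * cfg$grating$R * cfg$grating$C)
    list(n0 = cfg$n0_eff[2] * fac, beta = cfg$beta * fac)
  }
}

#' Fourier component S_l of the detected fringe signal
#'
#' In the near-resonant, symmetric approximation the detected signal is a
#' Fourier series in the fringe phase with components
#' `S_l = D~(l tau d / T_T) B_{-l}^{(1)}(0) B_{2l}^{(2)}(l (T + tau)/T_T)
#' B_{-l}^{(3)}(0)`.
#' The outer gratings act as purely absorptive masks (coefficients at
#' `chi = 0`); the central grating carries the full quantum or classical
#' coefficient. `beta2` optionally overrides the central grating's beta
#' (used by the classical-mimicry scan, which varies the eikonal phase
#' only).
#'
#' @param l Integer harmonic order.
#' @param cfg A [interferometer_config()].
#' @param model `"quantum"` or `"classical"`.
#' @param tau Delay of the third grating, s.
#' @param beta2 Optional override of the central grating's beta.
#' @return Real S_l (S_l = S_{-l} for this symmetric configuration, so the
#'   signal sum is real).
#' @export
fringe_fourier_component <- function(l, cfg, model = "quantum", tau = 0,
                                     beta2 = NULL) {
  tm <- cfg$timing
  g2 <- .g2_params(cfg)
  if (!is.null(beta2)) {
    stopifnot(beta2 > 0)
    g2$beta <- if (cfg$form == "ideal") beta2 else
      beta2 * (1 + cfg$grating$R) / (2 * cfg$grating$R * cfg$grating$C)
  }
  chi2 <- l * (tm$T + tau) / tm$T_T
  .dtilde(l * tau * cfg$grating$period / tm$T_T, cfg) *
    absorptive_coefficient(-l, cfg$n0_eff[1]) *
    talbot_coefficient(model, 2 * l, chi2, g2$n0, g2$beta) *
    absorptive_coefficient(-l, cfg$n0_eff[3])
}

# Net fringe displacement entering the phase factor exp(2 pi i l Dx / d):
# grating shift and mirror offset minus the tilt-induced drift and the
# gravitational sag accumulated between the grating pulses.
.fringe_shift <- function(cfg, tau) {
  g <- cfg$beam$g
  Tsep <- cfg$timing$T
  cfg$geometry$dxs + cfg$geometry$b -
    cfg$derived$p_gamma * tau / cfg$molecule$mass -
    g * Tsep^2 - 2 * g * tau * Tsep - g * tau^2 / 2
}

#' Detected signal behind the third grating
#'
#' Sums the harmonic components `S_l exp(2 pi i l Dx / d)` with the fringe
#' displacement `Dx` assembled from the grating shift, mirror offset, tilt
#' drift and gravitational sag. The sum is truncated adaptively: orders are
#' added until `|S_l| < 1e-8 |S_0|`, with a hard cap at `l = 16`.
#'
#' @param cfg A [interferometer_config()].
#' @param tau Delay(s) of the third grating, s. The near-resonant reduction
#'   requires `|tau| < 0.1 T_T`.
#' @param model `"quantum"` or `"classical"`.
#' @param dxs Optional override of the grating shift, m.
#' @param beta2 Optional override of the central grating's beta.
#' @return Numeric vector of signals (arbitrary units, positive).
#' @export
detected_signal <- function(cfg, tau, model = "quantum", dxs = NULL,
                            beta2 = NULL) {
  stopifnot(inherits(cfg, "tl_config"))
  if (any(abs(tau) >= 0.1 * cfg$timing$T_T)) {
    stop("near-resonant approximation requires |tau| < 0.1 T_T", call. = FALSE)
  }
  if (!is.null(dxs)) {
    cfg$geometry$dxs <- dxs
  }
  d <- cfg$grating$period
  vapply(tau, function(tt) {
    dx <- .fringe_shift(cfg, tt)
    S0 <- fringe_fourier_component(0, cfg, model, tt, beta2)
    tot <- S0
    for (l in 1:16) {
      Sl <- fringe_fourier_component(l, cfg, model, tt, beta2)
      # S_{-l} = S_l here (real coefficients, symmetric outer gratings)
      tot <- tot + 2 * Sl * cos(2 * pi * l * dx / d)
      if (abs(Sl) < 1e-8 * abs(S0)) break
      if (l == 16 && abs(Sl) >= 1e-6 * abs(S0)) {
        stop("harmonic sum did not converge within l_max = 16", call. = FALSE)
      }
    }
    tot
  }, numeric(1))
}

#' Normalized fringe scan S_N(tau)
#'
#' Emulates the experiment's toggling between the resonant mode (delay
#' `tau`) and the off-resonant reference (fixed delay `tau_off`):
#' `S_N(tau) = (S(tau) - S(tau_off)) / S(tau_off)`.
#'
#' @param tau_grid Delays, s.
#' @param cfg A [interferometer_config()].
#' @param model `"quantum"` or `"classical"`.
#' @param beta2 Optional override of the central grating's beta.
#' @return Data frame with columns `tau`, `S_N`, of class
#'   `tl_fringe_prediction`, with attributes `model` and `peak_visibility`
#'   (the maximum of S_N over the grid).
#' @export
#' @examples
#' cfg <- interferometer_config()
#' sc <- normalized_scan(seq(-200e-9, 200e-9, by = 5e-9), cfg)
#' attr(sc, "peak_visibility")  # ~0.2
normalized_scan <- function(tau_grid, cfg, model = "quantum", beta2 = NULL) {
  S_off <- detected_signal(cfg, cfg$timing$tau_off, model, beta2 = beta2)
  if (S_off <= 0) stop("degenerate reference: S(tau_off) <= 0", call. = FALSE)
  S <- detected_signal(cfg, tau_grid, model, beta2 = beta2)
  out <- data.frame(tau = tau_grid, S_N = (S - S_off) / S_off)
  structure(out, model = model, peak_visibility = max(out$S_N),
            class = c("tl_fringe_prediction", "data.frame"))
}

#' Beta required for the classical model to mimic the quantum contrast
#'
#' Computes the quantum peak contrast at the configured beta, then scans
#' beta upward in the classical model (absorptive strength held fixed, i.e.
#' only the eikonal phase is reduced) for the smallest beta at which the
#' classical peak contrast matches it. Because the classical peak
#' approaches the quantum resonance value only asymptotically from below,
#' "matches" is defined as agreement to `match_tol` relative precision
#' (default 5%, the one-significant-figure precision at which fringe
#' visibilities are quoted). The crossing is bracketed on a logarithmic
#' beta grid and refined by bisection.
#'
#' @param cfg A [interferometer_config()] (first Talbot order).
#' @param tau_grid Delays over which peaks are evaluated, s.
#' @param target_visibility Optional explicit target; default is the
#'   quantum peak at the configured beta.
#' @param match_tol Relative matching tolerance.
#' @param beta_range Search interval for beta.
#' @return The matching beta, with attributes `quantum_peak` and
#'   `classical_peak`.
#' @export
classical_mimicry_beta <- function(cfg,
                                   tau_grid = seq(-200e-9, 200e-9, by = 2e-9),
                                   target_visibility = NULL,
                                   match_tol = 0.05,
                                   beta_range = c(cfg$beta, 1e4)) {
  if (is.null(target_visibility)) {
    target_visibility <- attr(normalized_scan(tau_grid, cfg, "quantum"),
                              "peak_visibility")
  }
  cpeak <- function(b) {
    attr(normalized_scan(tau_grid, cfg, "classical", beta2 = b),
         "peak_visibility")
  }
  goal <- (1 - match_tol) * target_visibility
  f <- function(b) cpeak(b) - goal
  if (f(beta_range[1]) >= 0) return(structure(beta_range[1],
    quantum_peak = target_visibility, classical_peak = cpeak(beta_range[1])))
  # bracket on a log grid, then bisect
  grid <- 10^seq(log10(beta_range[1]), log10(beta_range[2]), length.out = 25)
  fg <- vapply(grid, f, numeric(1))
  ix <- which(fg >= 0)[1]
  if (is.na(ix)) {
    stop("no classical beta in the searched range reaches the quantum peak",
         call. = FALSE)
  }
  lo <- grid[ix - 1]; hi <- grid[ix]
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-3 * hi)$root
  structure(root, quantum_peak = target_visibility,
            classical_peak = cpeak(root))
}

#' Molecular density pattern at the third grating
#'
#' Evaluates the position-space molecular density just before the third
#' grating fires (the quantity the third grating masks), normalized to unit
#' mean, and reports the amplitudes of its `d`-periodic and `d/2`-periodic
#' harmonics. At the half Talbot order a binary grating would halve the
#' fringe period; for optical depletion gratings the `d/2` harmonic grows
#' with grating strength instead.
#'
#' @param x_grid Positions, m (should span at least two periods).
#' @param cfg A [interferometer_config()].
#' @param model `"quantum"` or `"classical"`.
#' @param tau Delay, s.
#' @return Data frame `x`, `density`, with attribute `harmonics`: named
#'   amplitudes `c(d = ..., d_half = ...)` relative to the mean.
#' @export
density_pattern <- function(x_grid, cfg, model = "quantum", tau = 0) {
  tm <- cfg$timing
  d <- cfg$grating$period
  g2 <- .g2_params(cfg)
  w0 <- .dtilde(0, cfg) * absorptive_coefficient(0, cfg$n0_eff[1]) *
    talbot_coefficient(model, 0, 0, g2$n0, g2$beta)
  dens <- rep(w0, length(x_grid))
  amps <- numeric(2)
  for (l in 1:16) {
    wl <- .dtilde(l * tau * d / tm$T_T, cfg) *
      absorptive_coefficient(-l, cfg$n0_eff[1]) *
      talbot_coefficient(model, 2 * l, l * (tm$T + tau) / tm$T_T,
                         g2$n0, g2$beta)
    dens <- dens + 2 * wl * cos(2 * pi * l * (x_grid + .fringe_shift(cfg, tau)) / d)
    if (l <= 2) amps[l] <- 2 * abs(wl) / abs(w0)
    if (abs(wl) < 1e-8 * abs(w0)) break
  }
  structure(data.frame(x = x_grid, density = dens / w0),
            harmonics = c(d = amps[1], d_half = amps[2]),
            model = model, class = c("tl_density_pattern", "data.frame"))
}

#' Gravity-induced fringe phase versus pulse separation
#'
#' At fixed fringe visibility the normalized contrast depends on the pulse
#' separation `T` through the gravitational sag:
#' `S_N(T) = V0 sin(2 pi (b - g T^2) / d)` with `b` a constant mirror
#' offset. Over the ~100 ns fringe envelope around the Talbot time the
#' variation of `g T^2` is far below a fringe period, so gravity shifts the
#' absolute fringe height without adding a time dependence.
#'
#' @param T_sep Pulse separation(s), s.
#' @param b Constant offset, m.
#' @param g Gravitational acceleration, m/s^2.
#' @param V0 Fringe visibility.
#' @param d Grating period, m.
#' @return S_N value(s).
#' @export
gravity_fringe_phase <- function(T_sep, b, g, V0, d) {
  V0 * sin(2 * pi * (b - g * T_sep^2) / d)
}
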