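# Elementary molecule/grating/beam quantities consumed by every other stage.

#' Optical properties of the interfering molecule
#'
#' Bundles the molecular mass with its VUV optical response at the grating
#' wavelength: the total depletion cross section `sigma` (photoionization plus
#' photodissociation; for gramicidin the photoionization part dominates) and
#' the optical polarizability volume `alpha_v`. These two numbers control,
#' respectively, the amplitude (absorptive) and phase (dipole) action of a
#' standing-wave grating on the matter wave.
#'
#' @param mass_amu Mass in atomic mass units (alternative to `mass_kg`).
#' @param mass_kg Mass in kg.
#' @param sigma_m2 Absorption (depletion) cross section at the grating
#'   wavelength, m^2.
#' @param alpha_v_m3 Optical polarizability volume at the grating wavelength,
#'   m^3 (SI polarizability is `4 pi eps0` times this volume).
#' @return Object of class `tl_molecule` with fields `mass` (kg), `sigma`
#'   (m^2), `alpha_v` (m^3).
#' @export
#' @examples
#' gram <- molecule_optics(mass_amu = 1882, sigma_m2 = 4.7e-20,
#'                         alpha_v_m3 = 157e-30)
#' gram$mass   # 3.13e-24 kg
molecule_optics <- function(mass_amu = NULL, mass_kg = NULL,
                            sigma_m2, alpha_v_m3) {
  if (is.null(mass_kg)) {
    if (is.null(mass_amu)) stop("supply 'mass_amu' or 'mass_kg'", call. = FALSE)
    mass_kg <- mass_amu * .tl$amu
  }
  .assert_pos(mass_kg, "mass")
  .assert_nonneg(sigma_m2, "sigma_m2")
  .assert_pos(alpha_v_m3, "alpha_v_m3")
  structure(list(mass = mass_kg, sigma = sigma_m2, alpha_v = alpha_v_m3),
            class = "tl_molecule")
}

#' One pulsed standing-wave grating
#'
#' A retro-reflected laser pulse of wavelength `lambda` forms a standing wave
#' of period `d = lambda/2`. The pulse energy and illuminated area set the
#' photon dose; the mirror reflectivity `R` and grating coherence factor `C`
#' reduce the coherent (standing-wave) part of the light field.
#'
#' @param wavelength_m Laser wavelength, m.
#' @param pulse_energy_J Pulse energy, J (default 0: strength supplied
#'   directly elsewhere).
#' @param area_m2 Illuminated area, m^2.
#' @param reflectivity Mirror reflectivity R in (0, 1].
#' @param coherence_factor Grating coherence factor C in (0, 1].
#' @return Object of class `tl_grating` with `lambda`, `period`, `energy`,
#'   `area`, `R`, `C`.
#' @export
grating_field <- function(wavelength_m, pulse_energy_J = 0, area_m2 = 1e-5,
                          reflectivity = 1, coherence_factor = 1) {
  .assert_pos(wavelength_m, "wavelength_m")
  .assert_nonneg(pulse_energy_J, "pulse_energy_J")
  .assert_pos(area_m2, "area_m2")
  for (nm in c("reflectivity", "coherence_factor")) {
    val <- get(nm)
    if (!is.numeric(val) || val <= 0 || val > 1) {
      stop(sprintf("'%s' must lie in (0, 1]", nm), call. = FALSE)
    }
  }
  structure(list(lambda = wavelength_m, period = wavelength_m / 2,
                 energy = pulse_energy_J, area = area_m2,
                 R = reflectivity, C = coherence_factor),
            class = "tl_grating")
}

#' Molecular beam kinematics
#'
#' @param velocity_m_s Mean forward velocity, m/s.
#' @param velocity_spread Relative velocity spread (dimensionless), optional.
#' @param divergence_rad Half divergence angle alpha, rad.
#' @param tilt_rad Beam tilt gamma with respect to the mirror surface, rad.
#'   The tilt adds a constant transverse momentum `p_gamma = m v tan(gamma)`.
#' @param gravity_m_s2 Gravitational acceleration along the grating vector.
#' @param extra_acceleration_m_s2 Additional constant acceleration `a`.
#' @return Object of class `tl_beam`.
#' @export
beam_kinematics <- function(velocity_m_s, velocity_spread = 0.005,
                            divergence_rad = 0, tilt_rad = 0,
                            gravity_m_s2 = .tl$g_std,
                            extra_acceleration_m_s2 = 0) {
  .assert_pos(velocity_m_s, "velocity_m_s")
  .assert_nonneg(divergence_rad, "divergence_rad")
  if (abs(tilt_rad) >= pi / 2) stop("|tilt_rad| must be < pi/2", call. = FALSE)
  structure(list(v = velocity_m_s, dv_v = velocity_spread,
                 alpha = divergence_rad, gamma = tilt_rad,
                 g = gravity_m_s2, a = extra_acceleration_m_s2),
            class = "tl_beam")
}

#' de Broglie wavelength
#'
#' `lambda_dB = h / (m v)`. For gramicidin (1882 amu) at 600 m/s this is
#' about 350 fm, some four orders of magnitude below the molecular size.
#'
#' @param mass_kg Mass, kg.
#' @param velocity_m_s Velocity, m/s.
#' @return Wavelength, m.
#' @export
#' @examples
#' de_broglie_wavelength(1882 * tl_constants()$amu, 600)  # ~3.5e-13 m
de_broglie_wavelength <- function(mass_kg, velocity_m_s) {
  .assert_pos(mass_kg, "mass_kg")
  .assert_pos(velocity_m_s, "velocity_m_s")
  .tl$h / (mass_kg * velocity_m_s)
}

#' Talbot time of a grating period
#'
#' `T_T = m d^2 / h`, the time after which a matter wave of mass `m`
#' re-images a grating of period `d` in the time domain. The three-pulse
#' interferometer is operated at pulse separations near integer or
#' half-integer multiples of `T_T`.
#'
#' @param mass_kg Mass, kg.
#' @param period_m Grating period, m.
#' @return Talbot time, s.
#' @export
#' @examples
#' talbot_time(1882 * tl_constants()$amu, 78.8e-9)  # ~2.93e-5 s
talbot_time <- function(mass_kg, period_m) {
  .assert_pos(mass_kg, "mass_kg")
  .assert_pos(period_m, "period_m")
  mass_kg * period_m^2 / .tl$h
}

#' Mean photons absorbed at a standing-wave antinode
#'
#' `n0 = 4 sigma E lambda / (h c A)`: the expected number of photons a
#' molecule sitting at an antinode absorbs during one grating pulse of
#' energy `E` spread over area `A`.
#'
#' @param sigma_m2 Absorption cross section, m^2.
#' @param energy_J Pulse energy, J.
#' @param wavelength_m Laser wavelength, m.
#' @param area_m2 Illuminated area, m^2 (> 0).
#' @return Dimensionless expected photon number.
#' @export
photons_absorbed_antinode <- function(sigma_m2, energy_J, wavelength_m,
                                      area_m2) {
  .assert_nonneg(sigma_m2, "sigma_m2")
  .assert_nonneg(energy_J, "energy_J")
  .assert_pos(wavelength_m, "wavelength_m")
  .assert_pos(area_m2, "area_m2")
  4 * sigma_m2 * energy_J * wavelength_m / (.tl$h * .tl$c * area_m2)
}

#' Eikonal phase imprinted at a standing-wave antinode
#'
#' `phi0 = 16 pi^2 E alpha_V / (h c A)`: the phase the optical dipole
#' potential imprints on the matter wave at an antinode, integrated over the
#' pulse.
#'
#' @param alpha_v_m3 Polarizability volume, m^3.
#' @param energy_J Pulse energy, J.
#' @param area_m2 Illuminated area, m^2 (> 0).
#' @return Phase, rad.
#' @export
eikonal_phase_antinode <- function(alpha_v_m3, energy_J, area_m2) {
  .assert_nonneg(alpha_v_m3, "alpha_v_m3")
  .assert_nonneg(energy_J, "energy_J")
  .assert_pos(area_m2, "area_m2")
  16 * pi^2 * energy_J * alpha_v_m3 / (.tl$h * .tl$c * area_m2)
}

#' Absorption-to-phase ratio beta of an optical grating
#'
#' `beta = n0 / (2 phi0) = (lambda / 8 pi^2) (sigma / alpha_V)`. This single
#' dimensionless number governs how strongly the quantum and classical
#' fringe predictions differ: small beta means the grating acts mostly as a
#' phase mask, whose classical (dipole-force) fringes are weak.
#'
#' @param sigma_m2 Absorption cross section, m^2.
#' @param alpha_v_m3 Polarizability volume, m^3 (> 0).
#' @param wavelength_m Laser wavelength, m.
#' @return Dimensionless beta.
#' @export
#' @examples
#' beta_parameter(4.7e-20, 157e-30, 157.63e-9)  # ~0.6
beta_parameter <- function(sigma_m2, alpha_v_m3, wavelength_m) {
  .assert_nonneg(sigma_m2, "sigma_m2")
  .assert_pos(alpha_v_m3, "alpha_v_m3")
  .assert_pos(wavelength_m, "wavelength_m")
  (wavelength_m / (8 * pi^2)) * (sigma_m2 / alpha_v_m3)
}

#' Effective grating strength after mirror and coherence losses
#'
#' The coherent (standing-wave) parts of the photon number and eikonal phase
#' are reduced by the mirror reflectivity `R` and the grating coherence
#' factor `C`: `n0_eff = R C n0`, `phi0_eff = R C phi0`.
#'
#' @param n0 Antinode photon number.
#' @param phi0 Antinode eikonal phase, rad.
#' @param R Mirror reflectivity in (0, 1].
#' @param C Coherence factor in (0, 1].
#' @return List with `n0_eff` and `phi0_eff`.
#' @export
effective_grating_strength <- function(n0, phi0, R, C) {
  .assert_nonneg(n0, "n0")
  .assert_nonneg(phi0, "phi0")
  for (nm in c("R", "C")) {
    val <- get(nm)
    if (!is.numeric(val) || any(val <= 0) || any(val > 1)) {
      stop(sprintf("'%s' must lie in (0, 1]", nm), call. = FALSE)
    }
  }
  list(n0_eff = R * C * n0, phi0_eff = R * C * phi0)
}

#' Grating strength record
#'
#' Collects the antinode photon number and eikonal phase of one grating
#' together with their effective (R C reduced) values and the derived beta.
#'
#' @param n0 Antinode photon number.
#' @param phi0 Antinode eikonal phase, rad.
#' @param R,C Mirror reflectivity and coherence factor in (0, 1].
#' @return Object of class `tl_strength` with fields `n0`, `phi0`, `n0_eff`,
#'   `phi0_eff`, `beta` (NA when `phi0 = 0`, i.e. a purely absorptive mask).
#' @export
grating_strength <- function(n0, phi0, R = 1, C = 1) {
  eff <- effective_grating_strength(n0, phi0, R, C)
  structure(list(n0 = n0, phi0 = phi0,
                 n0_eff = eff$n0_eff, phi0_eff = eff$phi0_eff,
                 beta = if (phi0 > 0) n0 / (2 * phi0) else NA_real_,
                 R = R, C = C),
            class = "tl_strength")
}
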