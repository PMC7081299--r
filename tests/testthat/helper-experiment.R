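# Shared fixtures: the gramicidin working-point configuration and an
# independent plane-wave (Bloch-decomposition) simulation of the
# three-grating sequence, used as a small-instance oracle for the
# near-resonant closed-form signal.

gram_config <- function(...) {
  interferometer_config(...)
}

# Independent quantum oracle: decompose each incident plane wave of
# transverse momentum p0 into grating diffraction orders, propagate the
# order amplitudes exactly through grating convolution (Fourier
# coefficients of the transmission functions) and quadratic free-flight
# phases, and average the transmitted intensity over the Gaussian momentum
# distribution. Shares no code with the Talbot-coefficient closed forms
# beyond the transmission-function Fourier expansion.
bloch_oracle_signal <- function(cfg, tau, dxs = 0, J = 20,
                                p_halfwidth_sigma = 4, p_step_frac = 1 / 8) {
  stopifnot(cfg$beam$gamma == 0, cfg$beam$g == 0)
  d <- cfg$grating$period
  m <- cfg$molecule$mass
  hbar <- tl_constants()$hbar
  h <- tl_constants()$h
  T1 <- cfg$timing$T
  T2 <- cfg$timing$T + tau
  jj <- -J:J
  b_abs <- function(n0a) {
    fourier_coefficients(transmission_profile(n0a, 0), "ideal", j_max = J)
  }
  b1 <- b_abs(cfg$n0_eff[1])
  b3 <- b_abs(cfg$n0_eff[3]) * exp(-2i * pi * jj * dxs / d)
  pr2 <- transmission_profile(cfg$n0_eff[2], cfg$phi0_eff[2],
                              R = cfg$grating$R, C = cfg$grating$C)
  b2 <- fourier_coefficients(pr2, cfg$form, j_max = J)
  sigp <- m * cfg$beam$v * sin(cfg$beam$alpha) * sqrt(2 * log(10)) / pi
  pk <- h / d
  p0 <- seq(-p_halfwidth_sigma * sigp, p_halfwidth_sigma * sigp,
            by = p_step_frac * pk)
  wts <- exp(-p0^2 / (2 * sigp^2))
  wts <- wts / sum(wts)
  conv <- function(b, cmat) {
    out <- matrix(0i, nrow = length(jj), ncol = ncol(cmat))
    for (k in seq_along(jj)) {
      idx <- jj[k] - jj
      ok <- idx >= -J & idx <= J
      out[k, ] <- colSums(b[ok] * cmat[idx[ok] + J + 1, , drop = FALSE])
    }
    out
  }
  free <- function(cmat, t) {
    phase <- exp(-1i * outer(jj * pk, p0, function(jp, pp) (pp + jp)^2) *
                   t / (2 * m * hbar))
    cmat * phase
  }
  cmat <- matrix(0i, length(jj), length(p0))
  cmat[J + 1, ] <- 1
  cmat <- free(conv(b2, free(conv(b1, cmat), T1)), T2)
  cmat <- conv(b3, cmat)
  sum(wts * colSums(Mod(cmat)^2))
}
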