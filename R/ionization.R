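# Single-photon VUV photoionization saturation model and cross-section fit.

#' Saturation model for the single-photon ion yield
#'
#' `N_I = N0 (1 - exp(-sigma_PI * phi))`: out of `N0` molecules in the
#' detection volume, each is ionized with probability `1 - exp(-sigma phi)`
#' at photon fluence `phi` (photons per unit area integrated over the
#' pulse). The small-fluence slope is `N0 sigma_PI`; the curve saturates at
#' `N0`.
#'
#' @param phi Photon fluence(s), photons/m^2.
#' @param N0 Total number of molecules.
#' @param sigma_PI Photoionization cross section, m^2.
#' @return Expected ion counts.
#' @export
saturation_model <- function(phi, N0, sigma_PI) {
  .assert_nonneg(phi, "phi"); .assert_nonneg(N0, "N0")
  .assert_nonneg(sigma_PI, "sigma_PI")
  N0 * (1 - exp(-sigma_PI * phi))
}

#' Fit the photoionization cross section from an ion-yield curve
#'
#' Weighted nonlinear least squares of the saturation model to measured ion
#' counts versus photon fluence, with `sigma_PI` and `N0` as fit
#' parameters. Weights follow Poisson counting statistics,
#' `sigma = sqrt(max(N, 1))`, unless explicit errors are supplied. When all
#' fluence points lie in the linear regime (`sigma_PI * max(phi) < 0.5`)
#' `sigma_PI` and `N0` are nearly degenerate; the fit then warns and the
#' returned interval is correspondingly wide.
#'
#' @param curve Data frame with columns `fluence_per_m2`, `ion_counts` and
#'   optionally `err`.
#' @return Object of class `tl_ionization_fit`: list with `sigma_PI`, `N0`,
#'   their standard errors, covariance, `chisq`, `dof` and the `nls` fit.
#' @export
#' @examples
#' phi <- seq(0, 8e19, length.out = 8)
#' curve <- data.frame(fluence_per_m2 = phi,
#'                     ion_counts = saturation_model(phi, 300, 4.7e-20))
#' fit_cross_section(curve)$sigma_PI  # 4.7e-20
fit_cross_section <- function(curve) {
  need <- c("fluence_per_m2", "ion_counts")
  if (!all(need %in% names(curve))) {
    stop("curve must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(curve) < 4) stop("need at least 4 fluence points", call. = FALSE)
  phi <- curve$fluence_per_m2
  y <- curve$ion_counts
  err <- if (!is.null(curve$err)) curve$err else sqrt(pmax(y, 1))
  w <- 1 / err^2
  # starts: N0 slightly above the largest count, sigma from the mid-curve
  N0_0 <- max(y) * 1.1 + 1
  imid <- which.min(abs(y - 0.5 * max(y)))
  frac <- min(y[imid] / N0_0, 0.95)
  sig_0 <- if (phi[imid] > 0) -log(1 - frac) / phi[imid] else 1 / max(phi)
  df <- data.frame(phi = phi, y = y)
  fit <- minpack.lm::nlsLM(y ~ N0 * (1 - exp(-sig * phi)), data = df,
                           weights = w,
                           start = list(N0 = N0_0, sig = sig_0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  # Poisson error bars are absolute: unscaled covariance (J' W J)^-1
  vc <- summary(fit)$cov.unscaled
  if (cf["sig"] * max(phi) < 0.5) {
    warning("all fluence points lie in the linear regime: sigma_PI and N0 ",
            "are nearly degenerate and the confidence interval is wide")
  }
  resid <- stats::resid(fit)
  structure(list(sigma_PI = unname(cf["sig"]), N0 = unname(cf["N0"]),
                 se = c(sigma_PI = sqrt(vc["sig", "sig"]),
                        N0 = sqrt(vc["N0", "N0"])),
                 cov = vc,
                 chisq = sum(w * resid^2),
                 dof = length(y) - 2L,
                 fit = fit),
            class = "tl_ionization_fit")
}

#' @export
print.tl_ionization_fit <- function(x, ...) {
  cat("Photoionization saturation fit: N_I = N0 (1 - exp(-sigma_PI phi))\n")
  cat(sprintf("  sigma_PI = %.3g +/- %.2g m^2\n", x$sigma_PI, x$se["sigma_PI"]))
  cat(sprintf("  N0       = %.4g +/- %.3g\n", x$N0, x$se["N0"]))
  cat(sprintf("  chi^2/dof = %.2f / %d\n", x$chisq, x$dof))
  invisible(x)
}
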