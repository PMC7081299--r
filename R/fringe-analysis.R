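# Data-side pipeline: per-frame detection counts -> normalized contrast with
# 1-sigma errors -> fitted visibility, envelope width and fringe period ->
# divergence and tilt angles.

#' Expected molecule count from frame-wise event counts
#'
#' Every detector frame either records at least one accepted event or none.
#' Assuming Poissonian molecule numbers per frame with mean `lambda_P`, the
#' empty-frame fraction estimates `P_zero = 1 - N_event / N_frames =
#' exp(-lambda_P)`, so the dead-time-corrected total molecule count is
#' `N = N_frames * (-log(P_zero))`, which always exceeds the raw event
#' count. The 1-sigma error follows by Gaussian propagation of the binomial
#' uncertainty of the empty-frame fraction.
#'
#' @param n_event Number(s) of frames with at least one accepted event.
#' @param n_frames Total number(s) of frames (> 0).
#' @return Data frame with columns `N` (expected molecule count) and `err`.
#' @export
#' @examples
#' molecules_from_counts(100, 1000)  # N = -1000 log(0.9) ~ 105.4
molecules_from_counts <- function(n_event, n_frames) {
  .assert_pos(n_frames, "n_frames")
  .assert_nonneg(n_event, "n_event")
  m <- max(length(n_event), length(n_frames))
  n_event <- rep_len(n_event, m); n_frames <- rep_len(n_frames, m)
  if (any(n_event > n_frames)) {
    stop("'n_event' cannot exceed 'n_frames'", call. = FALSE)
  }
  if (any(n_event == n_frames)) {
    stop("saturated record: no empty frames, dead-time correction diverges",
         call. = FALSE)
  }
  p0 <- 1 - n_event / n_frames
  N <- n_frames * (-log(p0))
  # Var(n_event) = N_frames p (1 - p); dN/dn_event = 1/p0
  err <- sqrt(n_frames * (1 - p0) * p0) / p0
  data.frame(N = N, err = err)
}

#' Normalized fringe contrast with propagated error
#'
#' `S_N = (S_res - S_off) / S_off`, with first-order Gaussian error
#' propagation of independent errors on the resonant and off-resonant
#' signals.
#'
#' @param S_res,S_off Resonant and off-resonant signals (`S_off > 0`).
#' @param err_res,err_off 1-sigma errors.
#' @return Data frame with columns `S_N`, `err`.
#' @export
normalized_contrast <- function(S_res, S_off, err_res = 0, err_off = 0) {
  if (any(S_off <= 0)) {
    stop("degenerate reference: 'S_off' must be > 0", call. = FALSE)
  }
  S_N <- (S_res - S_off) / S_off
  err <- sqrt((err_res / S_off)^2 + (S_res * err_off / S_off^2)^2)
  data.frame(S_N = S_N, err = err)
}

#' Collapse raw per-frame count records into a fringe scan
#'
#' Takes a table of count records (columns `tau_ns`, `mode` in
#' `{"res", "off"}`, `n_frames`, `n_event`), applies the Poisson dead-time
#' correction per record, pairs each resonant point with its interleaved
#' off-resonant reference at the same scan position, and returns the
#' normalized contrast scan.
#'
#' @param counts Data frame of count records.
#' @return Data frame `tau_ns`, `S_N`, `S_N_err` (class `tl_fringe_scan`).
#' @export
counts_to_scan <- function(counts) {
  need <- c("tau_ns", "mode", "n_frames", "n_event")
  if (!all(need %in% names(counts))) {
    stop("count table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  res <- counts[counts$mode == "res", ]
  off <- counts[counts$mode == "off", ]
  off <- off[match(res$tau_ns, off$tau_ns), ]
  if (anyNA(off$tau_ns)) {
    stop("every resonant scan point needs an interleaved off-resonant record",
         call. = FALSE)
  }
  nr <- molecules_from_counts(res$n_event, res$n_frames)
  no <- molecules_from_counts(off$n_event, off$n_frames)
  sn <- normalized_contrast(nr$N, no$N, nr$err, no$err)
  structure(data.frame(tau_ns = res$tau_ns, S_N = sn$S_N, S_N_err = sn$err),
            class = c("tl_fringe_scan", "data.frame"))
}

#' Fit the sinusoidal-modulation-with-Gaussian-envelope fringe model
#'
#' Weighted nonlinear least squares of
#' `S_N(tau) = V0 exp[-(tau / (sigma_w sqrt(2)))^2]
#'            cos(2 pi (tau - tau_off) / sigma_p)`
#' to a fringe scan. Starting values are data-driven and deterministic:
#' `V0` from the largest |S_N|, `sigma_p` from the dominant discrete-Fourier
#' period, `sigma_w` from the second moment of |S_N|, and the phase from a
#' linear cosine/sine regression at those starts.
#'
#' @param scan Data frame with columns `tau_ns`, `S_N` and optionally
#'   `S_N_err` (1-sigma; if absent the fit is unweighted, with a warning).
#' @return Object of class `tl_fringe_fit`: list with `V0`, `sigma_w_ns`,
#'   `sigma_p_ns`, `tau_off_ns`, their 1-sigma errors (`se`), the parameter
#'   covariance (`cov`), `chisq`, degrees of freedom and the `nls` fit.
#' @export
fit_fringe <- function(scan) {
  if (!all(c("tau_ns", "S_N") %in% names(scan))) {
    stop("scan must have columns 'tau_ns' and 'S_N'", call. = FALSE)
  }
  if (nrow(scan) < 8) {
    stop("need at least 8 scan points spanning the envelope", call. = FALSE)
  }
  tau <- scan$tau_ns
  y <- scan$S_N
  weighted <- !is.null(scan$S_N_err)
  if (!weighted) {
    warning("no 'S_N_err' column: performing unweighted fit")
    w <- rep(1, length(y))
  } else {
    if (any(scan$S_N_err <= 0)) stop("errors must be > 0", call. = FALSE)
    w <- 1 / scan$S_N_err^2
  }
  # deterministic starts
  V0_0 <- max(abs(y))
  # dominant period from the DFT of the (uniformly-gridded) scan
  dt <- stats::median(diff(sort(tau)))
  n <- length(y)
  sp <- Mod(stats::fft(y - mean(y)))[2:floor(n / 2)]
  kstar <- which.max(sp) + 1L
  sigma_p_0 <- n * dt / (kstar - 1L)
  sw2 <- sum(abs(y) * tau^2) / sum(abs(y))
  sigma_w_0 <- sqrt(max(sw2, dt^2)) # second-moment envelope scale
  env0 <- exp(-(tau / (sigma_w_0 * sqrt(2)))^2)
  X <- cbind(env0 * cos(2 * pi * tau / sigma_p_0),
             env0 * sin(2 * pi * tau / sigma_p_0))
  ab <- unname(stats::lm.wfit(X, y, w)$coefficients)
  tau_off_0 <- atan2(ab[2], ab[1]) * sigma_p_0 / (2 * pi)
  V0_0 <- max(sqrt(sum(ab^2)), 0.1 * V0_0)

  df <- data.frame(tau = tau, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ V0 * exp(-(tau / (sigma_w * sqrt(2)))^2) *
      cos(2 * pi * (tau - tau_off) / sigma_p),
    data = df, weights = w,
    start = list(V0 = V0_0, sigma_w = sigma_w_0, sigma_p = sigma_p_0,
                 tau_off = tau_off_0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  # report widths/periods as positive (the model is even in both)
  cf["sigma_w"] <- abs(cf["sigma_w"]); cf["sigma_p"] <- abs(cf["sigma_p"])
  # supplied 1-sigma errors are absolute, so the parameter covariance is the
  # unscaled (J' W J)^-1, not rescaled by the reduced chi-square
  vc <- if (weighted) summary(fit)$cov.unscaled else stats::vcov(fit)
  se <- sqrt(diag(vc))
  resid <- stats::resid(fit)
  structure(list(V0 = unname(cf["V0"]),
                 sigma_w_ns = unname(cf["sigma_w"]),
                 sigma_p_ns = unname(cf["sigma_p"]),
                 tau_off_ns = unname(cf["tau_off"]),
                 se = c(V0 = unname(se["V0"]), sigma_w_ns = unname(se["sigma_w"]),
                        sigma_p_ns = unname(se["sigma_p"]),
                        tau_off_ns = unname(se["tau_off"])),
                 cov = vc,
                 chisq = sum(w * resid^2),
                 dof = length(y) - 4L,
                 fit = fit),
            class = "tl_fringe_fit")
}

#' @export
print.tl_fringe_fit <- function(x, ...) {
  cat("Fringe fit: V0 exp[-(tau/(sigma_w sqrt(2)))^2] cos(2 pi (tau - tau_off)/sigma_p)\n")
  cat(sprintf("  V0       = %.4f +/- %.4f\n", x$V0, x$se["V0"]))
  cat(sprintf("  sigma_w  = %.2f +/- %.2f ns\n", x$sigma_w_ns, x$se["sigma_w_ns"]))
  cat(sprintf("  sigma_p  = %.2f +/- %.2f ns\n", x$sigma_p_ns, x$se["sigma_p_ns"]))
  cat(sprintf("  tau_off  = %.2f +/- %.2f ns\n", x$tau_off_ns, x$se["tau_off_ns"]))
  cat(sprintf("  chi^2/dof = %.2f / %d\n", x$chisq, x$dof))
  invisible(x)
}

#' Beam divergence angle from the fitted envelope width
#'
#' `alpha = arcsin(d / (2 v sigma_w sqrt(2 ln 10)))`: the resonance-dip
#' envelope narrows as the beam divergence grows.
#'
#' @param sigma_w_s Envelope width, s.
#' @param v Beam velocity, m/s.
#' @param d Grating period, m.
#' @return Divergence angle alpha, rad.
#' @export
#' @examples
#' divergence_from_width(76.5e-9, 600, 78.8e-9) * 1e3  # ~0.4 mrad
divergence_from_width <- function(sigma_w_s, v, d) {
  .assert_pos(sigma_w_s, "sigma_w_s"); .assert_pos(v, "v"); .assert_pos(d, "d")
  arg <- d / (2 * v * sigma_w_s * sqrt(2 * log(10)))
  if (any(arg > 1)) {
    stop("envelope width too small: arcsin argument exceeds 1", call. = FALSE)
  }
  asin(arg)
}

#' Beam tilt angle from the fitted fringe period
#'
#' `gamma = arcsin(d / (v sigma_p))`: a tilted beam sweeps the fringe
#' pattern across the third grating at transverse speed `v sin(gamma)`, so
#' one fringe period in the delay corresponds to one grating period of
#' sweep.
#'
#' @param sigma_p_s Fringe period in the delay, s.
#' @param v Beam velocity, m/s.
#' @param d Grating period, m.
#' @return Tilt angle gamma, rad.
#' @export
#' @examples
#' tilt_from_period(77.3e-9, 600, 78.8e-9) * 1e3  # ~1.7 mrad
tilt_from_period <- function(sigma_p_s, v, d) {
  .assert_pos(sigma_p_s, "sigma_p_s"); .assert_pos(v, "v"); .assert_pos(d, "d")
  arg <- d / (v * sigma_p_s)
  if (any(arg > 1)) {
    stop("fringe period too small: arcsin argument exceeds 1", call. = FALSE)
  }
  asin(arg)
}
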