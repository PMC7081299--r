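# Counting, contrast and fringe-fit pipeline.

test_that("Poisson dead-time correction: empty-frame fraction to molecule count", {
  expect_equal(molecules_from_counts(0, 1000)$N, 0)
  r <- molecules_from_counts(100, 1000)
  expect_equal(r$N, -1000 * log(0.9))
  expect_equal(r$N, 105.4, tolerance = 0.001)
  # dead-time correction only inflates: N >= N_event
  set.seed(3)
  ne <- sample(0:990, 50)
  expect_true(all(molecules_from_counts(ne, 1000)$N >= ne))
  expect_error(molecules_from_counts(1000, 1000), "saturated")
  expect_error(molecules_from_counts(10, 5), "cannot exceed")
})

test_that("counting error bars match the binomial sampling spread", {
  # Monte-Carlo oracle: repeated frame sets at known occupancy
  lam <- 0.25; nf <- 2000
  set.seed(7)
  ne <- stats::rbinom(4000, nf, 1 - exp(-lam))
  r <- molecules_from_counts(ne, nf)
  expect_equal(mean(r$N) / nf, lam, tolerance = 0.01)
  expect_equal(stats::sd(r$N), mean(r$err), tolerance = 0.05)
})

test_that("normalized contrast and its propagated error", {
  expect_equal(normalized_contrast(5, 5)$S_N, 0)
  expect_equal(normalized_contrast(1.2 * 7, 7)$S_N, 0.2)
  expect_error(normalized_contrast(1, 0), "degenerate reference")
  # propagated 1-sigma agrees with a resampling estimate at <= 10% errors
  set.seed(21)
  for (case in list(c(100, 90, 5, 4), c(50, 60, 5, 6), c(200, 180, 20, 10))) {
    draws_res <- stats::rnorm(2e5, case[1], case[3])
    draws_off <- stats::rnorm(2e5, case[2], case[4])
    mc <- stats::sd((draws_res - draws_off) / draws_off)
    prop <- normalized_contrast(case[1], case[2], case[3], case[4])$err
    expect_equal(prop, mc, tolerance = 0.05)
  }
})

test_that("raw count records collapse into a paired contrast scan", {
  counts <- data.frame(
    tau_ns = rep(c(-20, 0, 20), 2),
    mode = rep(c("res", "off"), each = 3),
    n_frames = 1000,
    n_event = c(220, 260, 220, 200, 200, 200))
  sc <- counts_to_scan(counts)
  expect_s3_class(sc, "tl_fringe_scan")
  expect_equal(sc$tau_ns, c(-20, 0, 20))
  expect_equal(sc$S_N[2], (-log(0.74)) / (-log(0.8)) - 1, tolerance = 1e-12)
  expect_true(all(sc$S_N_err > 0))
  expect_error(counts_to_scan(counts[1:4, ]), "interleaved")
  # exchangeability: the estimator depends on counts only through totals
  perm <- counts[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(counts_to_scan(perm)$S_N[order(counts_to_scan(perm)$tau_ns)],
               sc$S_N)
})

test_that("fringe fit recovers exact parameters from a noiseless scan", {
  tau <- seq(-200, 200, by = 10)
  truth <- list(V0 = 0.2, sw = 76.5, sp = 77.3, t0 = 8)
  y <- truth$V0 * exp(-(tau / (truth$sw * sqrt(2)))^2) *
    cos(2 * pi * (tau - truth$t0) / truth$sp)
  ft <- fit_fringe(data.frame(tau_ns = tau, S_N = y, S_N_err = 0.01))
  expect_equal(ft$V0, truth$V0, tolerance = 1e-6)
  expect_equal(ft$sigma_w_ns, truth$sw, tolerance = 1e-6)
  expect_equal(ft$sigma_p_ns, truth$sp, tolerance = 1e-6)
  expect_equal(ft$tau_off_ns %% truth$sp, truth$t0, tolerance = 1e-4)
  expect_warning(fit_fringe(data.frame(tau_ns = tau, S_N = y)), "unweighted")
  expect_error(fit_fringe(data.frame(tau_ns = 1:5, S_N = rep(0, 5))),
               "at least 8")
})

test_that("fringe fit covers the truth at 2 sigma under scan noise", {
  tau <- seq(-200, 200, by = 10)
  truth <- list(V0 = 0.2, sw = 76.5, sp = 77.3, t0 = 8)
  mu <- truth$V0 * exp(-(tau / (truth$sw * sqrt(2)))^2) *
    cos(2 * pi * (tau - truth$t0) / truth$sp)
  err <- 0.02
  hits <- matrix(FALSE, 50, 3)
  for (i in 1:50) {
    set.seed(1000 + i)
    y <- mu + stats::rnorm(length(tau), 0, err)
    ft <- fit_fringe(data.frame(tau_ns = tau, S_N = y, S_N_err = err))
    hits[i, ] <- c(abs(ft$V0 - truth$V0) <= 2 * ft$se["V0"],
                   abs(ft$sigma_w_ns - truth$sw) <= 2 * ft$se["sigma_w_ns"],
                   abs(ft$sigma_p_ns - truth$sp) <= 2 * ft$se["sigma_p_ns"])
  }
  expect_true(all(colMeans(hits) >= 0.8))
})

test_that("divergence and tilt angles invert the width and period relations", {
  a <- divergence_from_width(76.5e-9, 600, 78.8e-9)
  expect_equal(a * 1e3, 0.4, tolerance = 0.01)
  g <- tilt_from_period(77.3e-9, 600, 78.8e-9)
  expect_equal(g * 1e3, 1.7, tolerance = 0.01)
  # monotone decreasing in the width/period; velocity scaling of sin(alpha)
  sw <- seq(40e-9, 200e-9, length.out = 20)
  expect_true(all(diff(divergence_from_width(sw, 600, 78.8e-9)) < 0))
  expect_true(all(diff(tilt_from_period(sw, 600, 78.8e-9)) < 0))
  expect_equal(sin(divergence_from_width(76.5e-9, 1200, 78.8e-9)),
               sin(a) / 2)
  expect_lt(tilt_from_period(1, 600, 78.8e-9), 1e-9)
  expect_error(divergence_from_width(1e-12, 600, 78.8e-9), "exceeds 1")
})
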