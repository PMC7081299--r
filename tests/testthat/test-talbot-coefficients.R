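# Grating transmission functions and their Talbot coefficients.

test_that("transmission function: nodes transmit fully, zero strength is unity", {
  pr <- transmission_profile(3, 2.5, R = 0.97, C = 0.76)
  expect_equal(transmission_function(pr$d / 2, pr, "ideal"), 1 + 0i)
  pr0 <- transmission_profile(0, 0)
  x <- seq(0, pr0$d, length.out = 11)
  expect_equal(transmission_function(x, pr0, "ideal"), rep(1 + 0i, 11))
  expect_equal(transmission_function(x, pr0, "realistic"), rep(1 + 0i, 11))
  # d-periodicity of the squared modulus
  expect_equal(Mod(transmission_function(x + pr$d, pr, "realistic")),
               Mod(transmission_function(x, pr, "realistic")))
})

test_that("realistic absorption exponent carries the (1+R)/(4RC) factor", {
  pr <- transmission_profile(3, 2.5, R = 0.97, C = 0.76)
  t0 <- transmission_function(0, pr, "realistic")
  expect_equal(Mod(t0), exp(-3 * 1.97 / (4 * 0.97 * 0.76)), tolerance = 1e-12)
  expect_equal(Arg(t0), 2.5)  # eikonal phase unaffected by the mirror loss
})

test_that("Fourier expansion: trivial grating, symmetry, Parseval", {
  b0 <- fourier_coefficients(transmission_profile(0, 0), "ideal", j_max = 10)
  expect_equal(unname(b0["0"]), 1 + 0i)
  expect_true(all(Mod(b0[names(b0) != "0"]) < 1e-12))
  # purely absorptive grating: real, even coefficients
  pr <- transmission_profile(3, 0)
  b <- fourier_coefficients(pr, "ideal", j_max = 20)
  expect_true(all(abs(Im(b)) < 1e-12))
  expect_equal(unname(b[as.character(1:10)]), unname(b[as.character(-(1:10))]))
  # Parseval: sum |b_j|^2 equals the x-average of |t|^2
  prc <- transmission_profile(3, 2.5)
  bc <- fourier_coefficients(prc, "ideal", j_max = 40)
  xg <- seq(0, prc$d, length.out = 4097)[-4097]
  expect_equal(sum(Mod(bc)^2),
               mean(Mod(transmission_function(xg, prc, "ideal"))^2),
               tolerance = 1e-10)
  # spectral reconstruction accuracy
  j <- as.integer(names(bc))
  recon <- as.vector(exp(2i * pi * outer(xg / prc$d, j)) %*% bc)
  expect_lt(max(Mod(recon - transmission_function(xg, prc, "ideal"))), 1e-10)
})

test_that("absorptive coefficient matches the modified-Bessel closed form", {
  expect_equal(absorptive_coefficient(0, 0), 1)
  expect_equal(absorptive_coefficient(1, 3), -exp(-1.5) * besselI(1.5, 1))
  expect_equal(absorptive_coefficient(1, 3), -0.219, tolerance = 0.005)
  expect_equal(absorptive_coefficient(-2, 5), absorptive_coefficient(2, 5))
})

test_that("quantum and classical coefficients reduce to the absorptive form at chi = 0", {
  for (n0 in c(0.5, 3, 6)) for (beta in c(0.3, 0.6, 2, Inf)) for (n in -3:3) {
    expect_equal(talbot_coefficient("quantum", n, 0, n0, beta),
                 absorptive_coefficient(n, n0), tolerance = 1e-12)
    expect_equal(talbot_coefficient("classical", n, 0, n0, beta),
                 absorptive_coefficient(n, n0), tolerance = 1e-12)
  }
  expect_equal(talbot_coefficient("quantum", 0, 0, 3, 0.6),
               exp(-1.5) * besselI(1.5, 0))
  expect_equal(talbot_coefficient("quantum", 0, 0, 3, 0.6), 0.367,
               tolerance = 0.002)
})

test_that("quantum coefficients are 2-periodic in chi; classical are not", {
  chis <- c(-0.8, -0.3, 0.21, 0.47, 0.9)
  for (n in c(-2, 0, 1, 3)) {
    expect_equal(talbot_coefficient("quantum", n, chis + 2, 3, 0.6),
                 talbot_coefficient("quantum", n, chis, 3, 0.6),
                 tolerance = 1e-10)
  }
  expect_gt(abs(talbot_coefficient("classical", 2, 2, 3, 0.6) -
                talbot_coefficient("classical", 2, 0, 3, 0.6)), 1e-3)
})

test_that("closed form matches the brute-force Fourier construction on a grid", {
  # both radicand branches are exercised across this grid
  for (n0 in c(0.5, 3, 6)) for (beta in c(0.3, 0.6, 2)) {
    for (n in -4:4) for (chi in seq(-1, 1, by = 0.25)) {
      bf <- talbot_coefficient_numeric(n, chi, n0, beta)
      expect_lt(abs(Im(bf)), 1e-10)
      expect_equal(talbot_coefficient("quantum", n, chi, n0, beta), Re(bf),
                   tolerance = 1e-8)
    }
  }
})

test_that("pure-absorption limit: large beta approaches the beta = Inf form", {
  for (chi in c(0.25, 0.5, 1)) for (n in 0:2) {
    lim <- talbot_coefficient("quantum", n, chi, 3, Inf)
    expect_equal(talbot_coefficient("quantum", n, chi, 3, 1e8), lim,
                 tolerance = 1e-6)
    # classical absorptive grating is chi-independent (pure Moire mask)
    expect_equal(talbot_coefficient("classical", n, chi, 3, Inf),
                 absorptive_coefficient(n, 3), tolerance = 1e-12)
  }
})

test_that("extreme grating strength raises an explicit range error", {
  expect_error(talbot_coefficient("quantum", 1, 0.3, 2000, 0.6),
               "supported range")
})
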