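#!/usr/bin/env Rscript
# Quantum vs classical fringe scans at the first and half Talbot orders,
# and the fitted visibility / divergence / tilt of the quantum curve.
suppressMessages(library(talbotlau))

dir.create("results", showWarnings = FALSE)

# first Talbot order: argon seeding, 600 m/s
cfg1 <- interferometer_config()
tau1 <- seq(-200, 200, by = 2)
q1 <- normalized_scan(tau1 * 1e-9, cfg1, "quantum")
c1 <- normalized_scan(tau1 * 1e-9, cfg1, "classical")

# half Talbot order: helium seeding, 1200 m/s, 100 ns reference
cfg05 <- interferometer_config(order_n = 0.5, velocity_m_s = 1200,
                               tau_off_ns = 100)
tau05 <- seq(-100, 100, by = 1)
q05 <- normalized_scan(tau05 * 1e-9, cfg05, "quantum")
c05 <- normalized_scan(tau05 * 1e-9, cfg05, "classical")

scans <- rbind(
  data.frame(order = 1, tau_ns = tau1, S_N_quantum = q1$S_N,
             S_N_classical = c1$S_N),
  data.frame(order = 0.5, tau_ns = tau05, S_N_quantum = q05$S_N,
             S_N_classical = c05$S_N))
write.csv(scans, "results/fringe_scans.csv", row.names = FALSE)

ft <- fit_fringe(data.frame(tau_ns = tau1, S_N = q1$S_N, S_N_err = 1e-3))
alpha <- divergence_from_width(ft$sigma_w_ns * 1e-9, cfg1$beam$v,
                               cfg1$grating$period)
gamma <- tilt_from_period(ft$sigma_p_ns * 1e-9, cfg1$beam$v,
                          cfg1$grating$period)

cat(sprintf("n = 1:   quantum peak S_N = %.3f, classical = %.3f (ratio %.1f)\n",
            attr(q1, "peak_visibility"), attr(c1, "peak_visibility"),
            attr(q1, "peak_visibility") / attr(c1, "peak_visibility")))
cat(sprintf("n = 1/2: quantum peak S_N = %.3f, classical = %.3f (ratio %.1f)\n",
            attr(q05, "peak_visibility"), attr(c05, "peak_visibility"),
            attr(q05, "peak_visibility") / attr(c05, "peak_visibility")))
cat(sprintf("quantum n = 1 fit: V0 = %.3f, sigma_w = %.1f ns, sigma_p = %.1f ns\n",
            ft$V0, ft$sigma_w_ns, ft$sigma_p_ns))
cat(sprintf("inverted angles: alpha = %.3f mrad, gamma = %.3f mrad\n",
            alpha * 1e3, gamma * 1e3))
cat("The classical trajectory model misses the first-order amplitude by\n",
    "almost an order of magnitude; at the half order the two converge.\n",
    sep = "")
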