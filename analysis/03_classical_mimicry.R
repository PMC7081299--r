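#!/usr/bin/env Rscript
# How large must beta be for the classical model to mimic the quantum
# fringe contrast? Scans the classical peak versus beta (eikonal phase
# reduced at fixed absorption) and locates the matching point.
suppressMessages(library(talbotlau))

dir.create("results", showWarnings = FALSE)
cfg <- interferometer_config()
tau <- seq(-200e-9, 200e-9, by = 2e-9)
qpeak <- attr(normalized_scan(tau, cfg, "quantum"), "peak_visibility")

betas <- 10^seq(log10(0.6), 3.5, length.out = 30)
cpeaks <- vapply(betas, function(b) {
  attr(normalized_scan(tau, cfg, "classical", beta2 = b), "peak_visibility")
}, numeric(1))
write.csv(data.frame(beta = betas, classical_peak = cpeaks,
                     quantum_peak = qpeak),
          "results/mimicry_scan.csv", row.names = FALSE)

bstar <- classical_mimicry_beta(cfg, tau_grid = tau)
cat(sprintf("quantum peak S_N = %.4f at beta = 0.6\n", qpeak))
cat(sprintf("classical peak reaches it (5%% matching band) at beta* = %.1f\n",
            as.numeric(bstar)))
cat("The classical curve approaches the quantum one only asymptotically;\n",
    "matching the observed contrast classically would demand beta two\n",
    "orders of magnitude above the measured 0.6 - excluded by the\n",
    "molecule's optical properties.\n", sep = "")
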