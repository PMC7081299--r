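Package: talbotlau
Title: Time-Domain Talbot-Lau Interferometry with Pulsed Photo-Depletion Gratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-space models and data analysis for time-domain Talbot-Lau
    matter-wave interferometry of heavy molecules diffracted at pulsed
    standing-wave photo-depletion (single-photon ionization) gratings.
    Implements the complex grating transmission functions and their quantum
    and classical Talbot coefficients in Bessel-function closed form, the
    near-resonant three-grating fringe signal including beam divergence,
    mirror tilt and gravity, fringe-contrast and photoionization saturation
    fitting, Poisson molecule counting with dead-time correction, and seeded
    synthetic-data generators so that every analysis stage can be exercised
    without access to the experiment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
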