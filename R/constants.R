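# Centralized physical constants (CODATA 2018 exact/recommended values).
# All internal computation is strict SI; unit-suffixed arguments are converted
# once at the constructor/config boundary.

.tl <- list(
  h     = 6.62607015e-34,      # Planck constant [J s]
  hbar  = 6.62607015e-34 / (2 * pi),
  c     = 299792458,           # speed of light [m/s]
  amu   = 1.66053906660e-27,   # atomic mass unit [kg]
  g_std = 9.81                 # standard gravity [m/s^2]; overridable per config
)

#' Physical constants used throughout the package
#'
#' Returns the frozen set of physical constants (SI units) used by all
#' derived quantities: Planck constant `h`, reduced Planck constant `hbar`,
#' speed of light `c`, atomic mass unit `amu` and the default gravitational
#' acceleration `g_std` (9.81 m/s^2, overridable in a configuration).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' tl_constants()$h
tl_constants <- function() .tl

.assert_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

.assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and >= 0", name), call. = FALSE)
  }
  invisible(x)
}
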