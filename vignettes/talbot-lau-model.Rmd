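---
title: "Phase-space modeling of time-domain Talbot-Lau interferometry with photo-depletion gratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-space modeling of time-domain Talbot-Lau interferometry with photo-depletion gratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical system

A heavy molecule (the package defaults describe gramicidin A1, a linear
15-residue polypeptide of 1882 amu) is launched in a collimated beam at
velocity $v$ and passes three pulsed standing light waves $G^{(1)}$,
$G^{(2)}$, $G^{(3)}$ formed by retro-reflecting a VUV laser
($\lambda_L = 157.63$ nm) off a common mirror. Each standing wave is a
*photo-depletion grating* of period $d = \lambda_L/2$: at the antinodes a
molecule absorbs on average $n_0$ photons, and a single absorbed photon
ionizes it and removes it from the beam, so the grating acts as an
absorptive mask; simultaneously the optical dipole potential imprints an
eikonal phase $\phi_0$ on the surviving amplitude. The timing is resonant
when the pulse separations equal a multiple $n$ of the Talbot time

$$T_\mathrm{T} = \frac{m d^2}{h} \approx 29.3\ \mu\mathrm{s},$$

at which the matter wave re-images the grating structure. Delaying the
third pulse by a small $\tau$ while toggling against an off-resonant
reference delay $\tau_\mathrm{off}$ yields the normalized contrast
$S_\mathrm{N}(\tau) = (S(\tau) - S(\tau_\mathrm{off}))/S(\tau_\mathrm{off})$,
a damped sinusoid whose envelope width encodes the beam divergence
$\alpha$ and whose period encodes the beam tilt $\gamma$ relative to the
mirror.

## Transmission functions and Talbot coefficients

A grating of effective strength $(n_{0,\mathrm{eff}}, \phi_{0,\mathrm{eff}})
= RC\,(n_0, \phi_0)$ (mirror reflectivity $R$, coherence factor $C$) has
the ideal transmission function

$$t(x) = \exp\!\left[\left(-\tfrac{n_{0,\mathrm{eff}}}{2}
  + i\phi_{0,\mathrm{eff}}\right)\cos^2\!\frac{\pi x}{d}\right],$$

and, accounting for the running-wave (incoherent) part of the light that
depletes molecules without contributing to the coherent modulation, the
realistic form multiplies the absorption exponent by $(1+R)/(2RC)$. The
ratio

$$\beta = \frac{n_0}{2\phi_0}
        = \frac{\lambda_L}{8\pi^2}\frac{\sigma}{\alpha_V}$$

is fixed by the molecule's absorption cross section $\sigma$ and
polarizability volume $\alpha_V$; the defaults
($\sigma = 4.7\times10^{-20}\ \mathrm{m^2}$,
$\alpha_V = 157\times10^{-30}\ \mathrm{m^3}$) give $\beta \simeq 0.6$.

The effect of a grating on the transverse Wigner function is a momentum
convolution whose kernel is built from *Talbot coefficients* $B_n(\chi)$ —
the Fourier coefficients of the two-point product
$t(x-\chi d/2)\,t^*(x+\chi d/2)$. For the $\cos^2$ grating they have a
closed Bessel form: an $e^{-n_0/2}$ damping, a half-integer power of
$(\sin\pi\chi - \beta\cos\pi\chi)/(\sin\pi\chi + \beta\cos\pi\chi)$, and a
$J_n$ of argument $(n_0/2\beta)\sqrt{\sin^2\pi\chi - \beta^2\cos^2\pi\chi}$.
The classical (ballistic trajectories under the dipole force) counterparts
$C_n(\chi)$ replace $\sin\pi\chi \to \pi\chi$ and $\cos\pi\chi \to 1$; they
are not periodic in $\chi$, whereas the quantum coefficients have period 2.
At $\chi = 0$ both reduce to the purely absorptive
$B_n(0) = (-1)^n e^{-n_0/2} I_n(n_0/2)$. Keeping quantum and classical
dynamics in one formalism with a single substitution is what makes the
model comparison clean: every other ingredient is shared.

**Branch handling.** Where the radicand is negative the closed form is
continued analytically: the ratio power is evaluated through the principal
complex logarithm and $J_n$ of a purely imaginary argument through
$I_n$, with exponential scaling against the $e^{-n_0/2}$ prefactor so the
evaluation stays finite up to $n_{0,\mathrm{eff}} = 1400$ (an explicit
range error beyond). The residual imaginary part is asserted below
$10^{-10}$ and the real part returned; a single code path covers both
branches, so a branch error cannot pass silently. `sign(0)` is taken as
$+1$ (continuity from the right; a measure-zero set). The degenerate
point $\sin\pi\chi = -\beta\cos\pi\chi$, where the ratio diverges while the
Bessel argument vanishes, is evaluated by its finite product limit.

Every closed-form value is cross-checked against an independent
brute-force construction (`talbot_coefficient_numeric()`): FFT Fourier
expansion of $t(x)$ followed by the bilinear coefficient sum. The test
grid spans $n \in [-4,4]$, $\chi \in [-1,1]$,
$n_{0,\mathrm{eff}} \in \{0.5, 3, 6\}$, $\beta \in \{0.3, 0.6, 2\}$ at
$10^{-8}$ agreement, exercising both radicand branches.

## The near-resonant signal and its grating treatment

Close to resonance ($T_1 = T$, $T_2 = T+\tau$, $|\tau| \ll T_\mathrm{T}$;
enforced as $|\tau| < 0.1\,T_\mathrm{T}$) the double index sum over
diffraction orders collapses to harmonics

$$S_l = \tilde D\!\left(\frac{l\tau d}{T_\mathrm{T}}\right)
  B^{(1)}_{-l}(0)\, B^{(2)}_{2l}\!\left(\frac{l(T+\tau)}{T_\mathrm{T}}\right)
  B^{(3)}_{-l}(0),
\qquad
S = \sum_l S_l\, e^{2\pi i l \Delta x / d},$$

with $\Delta x = \Delta x_\mathrm{s} + b - p_\gamma\tau/m - gT^2 - 2g\tau T
- g\tau^2/2$ collecting grating shift, mirror offset, tilt drift
($p_\gamma = mv\tan\gamma$) and gravitational sag. $\tilde D$ is the
Fourier transform of the transverse momentum distribution. The sum is
truncated adaptively when $|S_l| < 10^{-8}|S_0|$ (hard cap $l = 16$;
non-convergence is an explicit error) — at the working point the
coefficients decay so fast that $l \le 6$ contributes.

**Which transmission form enters where.** The outer gratings act as
position masks: the first projects a position comb out of an incoherent
beam, the third samples the arrival pattern, and both are therefore
treated as purely absorptive, $B_{\pm l}(0)$ evaluated at the quoted
working strength $n_{0,\mathrm{eff}}$. The central grating is the
diffractive element and carries the full coefficient, built from the
*realistic* transmission function (absorption enhanced by $(1+R)/(2RC)$,
phase unchanged). With the default `grating_form = "realistic"` this
reproduces the ~20% working-point visibility; applying the running-wave
enhancement to all three gratings would raise the predicted peak to ~0.30,
and the fully ideal form would lower it to ~0.15, both inconsistent with
the observed contrast that the realistic mixed treatment matches. The
`"ideal"` form is retained for sensitivity studies.

**Independent verification.** The near-resonant reduction is validated
against a plane-wave Bloch-decomposition simulation (test helper
`bloch_oracle_signal()`): each incident momentum component is expanded in
grating diffraction orders, propagated exactly through the three
convolution/free-flight steps, and averaged over the Gaussian momentum
distribution. The two agree to well within 1% at the working point —
the oracle shares nothing with the Talbot-coefficient algebra except the
transmission function itself.

## Parameters, defaults, and the momentum-width convention

| Parameter | Default | Units | Role |
|---|---|---|---|
| `mass_amu` | 1882 | amu | sets $T_\mathrm{T}$ and $\lambda_{dB}$ |
| `wavelength_nm` | 157.63 | nm | grating period $d = \lambda_L/2$ |
| `sigma_m2` | 4.7e-20 | m$^2$ | depletion cross section |
| `alpha_v_m3` | 1.57e-28 | m$^3$ | polarizability volume |
| `n0_eff` | 3 | — | effective antinode photon number |
| `reflectivity`, `coherence_factor` | 0.97, 0.76 | — | mirror/grating quality |
| `velocity_m_s` | 600 | m/s | argon seeding (1200 for helium) |
| `divergence_mrad` | 0.4 | mrad | envelope width |
| `tilt_mrad` | 1.7 | mrad | fringe period in $\tau$ |
| `tau_off_ns` | 200 | ns | off-resonant reference (100 at $n=1/2$) |
| `gravity_m_s2` | 9.81 | m/s$^2$ | sag; overridable |

The published pulse energy (4 mJ) and waist (10 × 1 mm$^2$) do not fix the
energy actually deposited in the interaction region, so the configuration
accepts either the physical route (`pulse_energy_mJ`, `area_mm2`) or
`n0_eff` directly; supplying both inconsistently is an error. The quoted
working point is $n_{0,\mathrm{eff}} = 3$.

The transverse momentum distribution is a zero-mean normal of width
$\sigma_p = m v \alpha_\mathrm{eff}$. The divergence angle is *defined*
through the envelope relation
$\alpha = \arcsin\!\left(d / (2 v \sigma_\mathrm{w}\sqrt{2\ln 10})\right)$,
which uses a decimal-width convention rather than a Gaussian sigma, so the
two definitions are reconciled once analytically:
$\alpha_\mathrm{eff} = \sin(\alpha)\sqrt{2\ln 10}/\pi$ makes the fitted
envelope of a noiseless scan satisfy the relation by construction. A test
confirms the round trip (configured $\alpha$ recovered from the fitted
envelope within 5%; in practice it closes to 0.1%).

## Classical mimicry: a matching criterion is required

Could ballistic trajectories reproduce the quantum contrast with different
molecular optics? Scanning $\beta$ upward in the classical model (fixed
absorption, weaker dipole phase) raises the classical peak monotonically
beyond $\beta \gtrsim 3$ — but its $\beta \to \infty$ limit is exactly the
absorptive-mask value that the quantum model already attains at resonance,
so the classical peak approaches the quantum one *asymptotically from
below* and never equals it exactly. "Matching" therefore needs a finite
band: the package declares a match at 5% relative agreement, the
one-significant-figure precision at which fringe visibilities are quoted.
Under that criterion the crossing lands near $\beta^* \approx 10^2$, two
orders of magnitude above the measured $\beta \simeq 0.6$ — the
quantitative content of the statement that no plausible classical
parameter choice reproduces the observation. The bracketing runs on a
logarithmic grid refined by bisection; the fixed point (targeting the
classical model's own visibility) returns the configured $\beta$
unchanged.

## Data-side estimators

*Counting.* A detector frame either contains an accepted event or not.
With Poissonian molecule numbers, the empty-frame fraction estimates
$P_\mathrm{zero} = 1 - N_\mathrm{event}/N_\mathrm{frames} = e^{-\lambda_P}$
and $N = N_\mathrm{frames}(-\ln P_\mathrm{zero})$ corrects the worst-case
one-molecule-per-event undercount (only the empty-fraction convention
gives $N \to N_\mathrm{event}$ in the sparse limit, which fixes an
ambiguity in how $P_\mathrm{zero}$ is sometimes written). Saturated
records (no empty frames) are an explicit error rather than an infinite
correction.

*Contrast and fits.* $S_\mathrm{N}$ errors follow first-order propagation
(verified against Monte-Carlo resampling to 5% at ≤10% relative errors).
The fringe fit is weighted Levenberg-Marquardt on
$V_0\,e^{-(\tau/\sigma_\mathrm{w}\sqrt2)^2}\cos(2\pi(\tau-\tau_\mathrm{off})/\sigma_\mathrm{p})$
with deterministic, data-driven starts (peak amplitude, DFT-dominant
period, second-moment width, linear cosine/sine phase regression) so
results are seed-independent. When explicit 1$\sigma$ errors are supplied
they are treated as *absolute*: the parameter covariance is the unscaled
$(J^\top W J)^{-1}$, not rescaled by the reduced chi-square. With known
Poisson errors this is the calibrated choice — the 2$\sigma$ coverage
criteria below would fail systematically with the rescaled convention at
few degrees of freedom. Unweighted fits (missing error column, with a
warning) keep the standard residual-variance scaling.

*Ionization.* $N_I = N_0(1 - e^{-\sigma_\mathrm{PI}\phi})$ fitted with
Poisson weights ($\sigma = \sqrt{\max(N,1)}$). If all points lie in the
linear regime ($\sigma_\mathrm{PI}\phi_\mathrm{max} < 0.5$) the two
parameters are nearly degenerate; the fit warns and the interval widens
accordingly (restricting a synthetic curve to the linear regime inflates
the relative interval more than fivefold).

## What the synthetic generators emulate — and what they do not

`generate_fringe_counts()` reproduces the acquisition *structure*:
resonant/off-resonant toggling per scan point, frame-wise Bernoulli events
from Poisson molecule numbers with mean proportional to the model signal
plus a delay-independent background, sparse occupancy by default
(mean 0.3 molecules/frame) so the single-molecule assumption of the
estimator is approximately valid — a dense mode stresses the dead-time
correction instead. `generate_ion_yield()` draws Poisson counts around the
saturation curve; `generate_polarizability_ensemble()` draws normal
per-conformer polarizabilities around an ensemble mean. All generators
are bit-reproducible under a fixed seed and restore the caller's RNG
state.

They do *not* emulate mass-spectrometric peak shapes, background
subtraction internals, velocity-spread chromaticity, mirror corrugation,
vibrations or Coriolis dephasing. Passing closure tests therefore shows
that the estimators are unbiased and correctly calibrated *under the
model's own statistical assumptions* — not that those assumptions exhaust
a real apparatus. The detection threshold applied to real mass spectra is
outside the generator; its effect enters only through the accepted-event
counts.

## Problem sizes and reproducibility

The shipped analyses and checks use delay grids of 101–201 points,
harmonic sums to $|l| \le 16$, FFT grids of 1024 points, Bloch oracles
with 41 diffraction orders and a momentum grid of an eighth of a grating
momentum over $\pm4\sigma_p$, and 50–200 seeded repetitions for the
coverage studies — sizes chosen so the full suite documents the model's
behavior in well under an hour on a laptop while keeping every
statistical assertion comfortably away from its threshold.
`scripts/acceptance.R` recomputes the headline numbers ($\beta$, the
first-order quantum peak contrast, the mimicry $\beta^*$) from scratch at
any seed.

## Known limitations

- The model is one-dimensional along the grating vector; longitudinal
  velocity spread enters only through the ensemble values of $v$.
- Decoherence channels (thermal emission, collisions) and the
  vibration/Coriolis dephasing of a real mirror are not modeled.
- The exact multi-index $(k,l)$ sums beyond the near-resonant $k = -l$
  reduction are available only through the Bloch oracle, which assumes an
  untilted beam in zero gravity (tilt and sag enter analytically as phase
  shifts, per the model's own reduction).
- $\sigma$ and $\alpha_V$ are inputs; computing them from electronic
  structure is explicitly out of scope.
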