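---
title: "Frequency-domain fluorescence as analog filtering: models, pipeline, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain fluorescence as analog filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdfluor)
```

## The model

A fluorophore excited by a time-varying source \(g(t)\) obeys, to first
order, \(\dot n + \Gamma n = g(t)\): the excited-state population \(n\) is a
low-pass-filtered copy of the excitation, with corner rate equal to the decay
rate \(\Gamma = 1/\tau\). In the Laplace domain the response is
\(N(s) = G(s)/(s+\Gamma)\); the factor \(1/(s+\Gamma)\) is exactly a
first-order analog low-pass filter. Everything in this package follows from
taking this equivalence seriously:

* **Phase and modulation.** Restricting \(s\) to \(i\omega\), a single
  lifetime lags the drive by \(\Phi = \arctan(\omega\tau)\) and demodulates
  as \(Mod = 1/\sqrt{1+(\omega\tau)^2}\) (we normalize \(Mod\) to 1 at DC;
  the raw \(|F(i\omega)| = 1/\sqrt{\Gamma^2+\omega^2}\) carries units of
  time). Phases are lags and are *reported positive*, the plotting
  convention of the frequency-domain fluorescence literature; internally
  they are negative arguments of complex transfer values.
* **Mixtures.** Emission collected from several non-interacting excited
  populations through one detector is the parallel sum
  \(F(i\omega)=\sum_k f_k/(1+i\omega\tau_k)\), where \(f_k\) are the DC
  amplitude weights. Fractions are *not* forced to sum to one; only
  normalization by \(F(0)\) inside `phase_mod()` matters. A parallel sum
  keeps the phase strictly inside \([0^\circ, 90^\circ)\); the
  characteristic signature of a fast/slow mixture is a phase maximum below
  90° followed by a turnover, because the slow component demodulates into a
  DC light level while the fast one keeps following the drive.
* **Three-level systems.** Pump into level 3, fast relaxation into the
  emitting level 2, slow return to ground. Under weak pumping the level-2
  response is second order: gain \(\Gamma_{32}\), poles at \(-\Gamma_{21}\)
  and \(-(\Gamma_{31}+\Gamma_{32})\). Turn-on transients (initial
  populations) are deliberately excluded from the transfer function — they
  do not depend on the drive — but are fully retained in the time-domain
  integrator `three_level_integrate()`, which solves the complete rate
  equations including ground-state depletion. When
  \(\Gamma_{32}\gg\Gamma_{21}\) the far pole's wing cancels the gain and the
  system collapses onto the single-pole curve; with comparable rates the two
  stages cascade and the lag extends to 180°.
* **Cascades.** Driver electronics, fluorophore, and band-limited detector
  multiply in the frequency domain (`cascade()`); phases add. A single RC
  low-pass stage emulates a lifetime via \(\tau = 2\pi RC\)
  (`lifetime_from_rc()`); `rc_stage_presets()` exposes both quoted
  fast-stage component sets without arbitrating their inconsistent curve
  labels (the quoted fast rates imply the opposite pairing from the quoted
  R and C values, so we decline to pick).

## Closed-form responses and two corrected formulas

`closed_form`-style operations give residue-theorem inversions for delta,
sine, biased-cosine, and square-wave drives. Two printed forms required
care, and in both cases the package gates its choice on an unambiguous
boundary condition plus agreement with the independent numeric oracle:

* **Biased cosine.** For the drive \(g(t)=A(1-\cos\omega t)/2\) starting
  from an empty excited state, the inversion consistent with \(n(0)=0\) is
  \[n(t) = \frac{A}{2\Gamma}\left(1-\frac{(\omega/\Gamma)^2 e^{-\Gamma t}
  + \cos\omega t + (\omega/\Gamma)\sin\omega t}{1+(\omega/\Gamma)^2}\right),\]
  i.e. with a *positive* cosine term. A variant with the opposite cosine
  sign circulates; it violates \(n(0)=0\) and disagrees with the
  convolution oracle, and is kept only behind `literal = TRUE` for
  comparison.
* **Square wave.** For the 0-to-2 biased unit square wave, the residue sum
  over the odd imaginary-axis poles gives oscillatory terms with
  coefficient \(4/\pi\) when the sum runs over *positive* odd orders (a
  \(2/\pi\) coefficient corresponds to counting signed orders \(\pm k\)
  separately — the \(+k\) and \(-k\) terms are equal). The turn-on factor
  is evaluated as \(1/(1+e^{\pi\Gamma/\omega})\); the full residue at
  \(-\Gamma\) would double it and make \(r(0)\) exactly zero, while the
  evaluated form leaves the small positive residual
  \(r(0)=1/(\Gamma(1+e^{\pi\Gamma/\omega}))\). Since the transient is not
  part of any steady-state quantity we validate the series against the
  oracle at steady state and document the residual rather than re-derive.
  The default truncation of 200 odd harmonics leaves a Gibbs wiggle below
  typical plotting resolution; edge-adjacent truncation error is about
  \(2/(\pi K \omega)\) for \(K\) retained orders, which the tests bound
  explicitly.

## Waveform harmonics

A rectangular pulse train of duty cycle \(D\) has harmonic amplitudes
\(D\,|\sin(\pi k D)/(\pi k D)|\), nulls wherever \(kD\) is an integer, and
phase delays linear in the order, \(\Phi_k = 180\,kD\) degrees — an
18°-per-harmonic staircase at \(D=1/10\), with every tenth order missing.
The square wave is the \(D=1/2\) special case (odd orders, \(1/k\) weights);
its fundamental is \(4/\pi \approx 1.273\) times that of a sine from the
same rails, the practical argument for square-wave driving. In the comb
limit \(D\to 0\) all orders approach equal intensity.

Discrete sampling matters at the 0.01° level: rectangle edges are aligned to
sample boundaries (pulse widths round to whole samples), so the sampled
pulse effectively starts half a sample early. `harmonic_content()` corrects
FFT phases by \(180k/N\) degrees so that exact-duty synthesized trains
reproduce the continuous law to machine precision, and documents the
discrete Dirichlet-kernel amplitude as the exact expectation with the
continuous sinc as its fine-sampling limit. FFT magnitudes are unsigned, so
sinc lobes of negative sign appear as 180° phase flips; comparisons are made
modulo 180° where that matters.

## The numeric oracle

Every closed form is checked against a brute-force forward simulator that
never shares code with it:

* `convolve_response()` convolves the drive with
  \(\sum_k f_k e^{-\Gamma_k t}\) using an exponential-integrator recursion
  that is *exact* for a piecewise-linear drive. There is no stability
  constraint: with rates separated by four decades the fast component simply
  tracks the drive quasi-statically. Accuracy in the true (continuous)
  drive is second order in the sampling step; a guard warns when the step
  exceeds a twentieth of the fastest lifetime.
* `three_level_integrate()` solves the full linear system with the
  time-varying pump \(\Gamma_{13}(t)\) using a stiff-capable ODE solver
  (`deSolve::lsoda`) with the drive interpolated linearly. We chose lsoda
  over per-step matrix exponentials: for a 3×3 system in pure R the
  exponential-step scheme costs orders of magnitude more per sample and
  buys nothing at the tolerances used (total population is conserved to
  better than \(10^{-8}\) relative in the tests).

Steady-state comparisons always skip a settle window of at least ten
lifetimes — turn-on transients persist over multiple cycles, and the tests
showed that a single contaminated averaging block can bias phases by
degrees.

## The digital lock-in pipeline

`harmonic_phases()` mirrors a digitizer-plus-FFT measurement: the driver and
response records are cut into blocks of (typically) 100 fundamental cycles,
the cycles within each block are averaged pointwise (residual white noise
falls as \(1/\sqrt{N_\text{cycles}}\)), each averaged cycle is Fourier
transformed with a rectangular window over exact cycles, and the phase delay
\(\arg D_k - \arg R_k\) and modulation ratio \(|R_k|/|D_k|\) are computed
per block and aggregated across blocks. Choices that were genuinely open:

* **Synchronization.** Non-integer samples-per-cycle records are linearly
  resampled onto the nearest integer-cycle grid; without this, spectral
  leakage dominates the phase error.
* **Power floor.** An order is reported only when the driver bin carries at
  least \(10^{-6}\) of the fundamental bin power — phase is undefined at
  nulled comb orders and absent even square-wave orders.
* **Phase statistics.** Aggregation uses the circular mean, with standard
  deviations computed on angles unwrapped around that mean, avoiding wrap
  artifacts near ±90°. Reporting conventions: principal value (default),
  the arctangent-compatible \([-90^\circ, 90^\circ]\) sawtooth, or
  cumulative unwrapping across orders (needed for transport delays). The
  multi-decade curves assembled from several fundamentals stay below 90°
  for parallel mixtures, so wrapping is moot there; both wrapped and
  unwrapped outputs exist because the measurement itself does not dictate
  one.
* **Modulation normalization.** The ratio is normalized by the DC-bin
  ratio, making it gain- and offset-invariant and equal to 1 at low
  frequency. (Measurement practice does not fix a normalization; this is the choice
  that makes the quantity dimensionless and comparable across detectors.)

`build_frequency_response()` merges sweeps from several fundamentals into
one curve, inverse-variance averaging estimates that land on the same
absolute frequency; merged uncertainties therefore never exceed individual
ones.

## Lifetime fitting

`fit_lifetimes()` performs weighted nonlinear least squares of the predicted
phase (optionally also modulation) curve. Parameters are \(\log\tau_k\) and
softmax-transformed fractions — positivity without constrained solvers, and
comfortable with lifetimes four decades apart. The two-component phase
objective is multimodal, so the optimizer restarts from eight random
log-uniform lifetime draws across the curve's frequency span (fixed seed)
plus one deterministic quantile-spread start. Phase-only fitting is the
default because the mixture modulation curve differs only subtly from a
single-exponential one. Standard errors come from the weighted Jacobian at
the optimum; lifetime intervals are formed on the log scale. Guards: a
request whose component count exceeds what the curve's frequency span can
identify is flagged with a warning, as is a fitted fraction below
\(10^{-4}\). The Monte-Carlo tests (100 replicates of 0.5° phase noise on an
80-point curve) check both accuracy (median relative lifetime error below
5 %) and calibration (nominal 68 % intervals covering truth at a binomially
plausible rate).

## The synthetic acquisition chain

`simulate_acquisition()` emulates the full experiment: generate the drive,
forward-simulate the fluorophore with the oracle, pass the result through a
pole-only detector filter, add seeded white Gaussian noise. Identical specs
give bit-identical records; noise-free runs consume no randomness.
`mixture_fixture()` reproduces the two-fluorophore bench configuration: a
0.5 ms slow emitter (uranyl-like) plus an effectively instantaneous fast
emitter (picosecond, coumarin-like), square-wave drives at 10 Hz, 250 Hz,
and 2.5 kHz, harmonics to order 50 spanning 10 Hz–125 kHz. Deliberate
modelling choices:

* The picosecond component is a zero-lag frequency-flat path: at the
  highest probed frequency its true lag would be of order
  \(10^{-7}\) degrees, far below anything measurable here, so the flat
  model is numerically exact across the band. A finite fast lifetime can
  still be simulated through an ordinary model component.
* The detector defaults to a single pole 100× above the highest probed
  harmonic — effectively transparent (its residual lag at the top harmonic,
  about half a degree, is included in the truth model whenever tests
  compare against the full chain).
* Noise is additive white Gaussian on the response only, default standard
  deviation 0.01 of the DC response level. No noise magnitude is available for the emulated bench setup; this value
  is an arbitrary choice at a realistic error-bar scale, and nothing
  downstream is tuned to it. There is
  no shot-noise (photon-counting) model, because no photon counts exist in
  this setting.
* Sampling uses 512 samples per cycle (4096 at 10 Hz, keeping the drive
  step below a twentieth of the slow lifetime), 4 blocks of 20 cycles per
  fundamental, plus a settle window of ten slow lifetimes rounded up to
  whole cycles. These sizes make the full loop — simulate, demodulate,
  merge, fit — run in a few seconds while leaving phase errors well inside
  the fitted uncertainties.

What passing these tests does *not* show about real data: the generator has
no drive-waveform distortion (laser threshold nonlinearity, slew limits), no
detector saturation, no 1/f or interference noise, no trigger jitter, and
its noise level is assumed known only through the scatter it produces. Real
acquisitions violating those assumptions will degrade the phase estimates in
ways the synthetic suite cannot certify.

## A worked example

```{r example, eval = FALSE}
library(fdfluor)

# the masking family: slow fraction from 10 % to 100 %
fam <- mixture_phase_family(seq(0.1, 1, 0.1), tau_slow_s = 5e-4,
                            tau_fast_s = 1e-12,
                            omega = 10^seq(1, 6, length.out = 200))

# synthetic three-fundamental acquisition and recovery
fx <- mixture_fixture(slow_fraction = 0.9, seed = 1)
curve <- reconstruct_phase_curve(fx)
fit <- fit_lifetimes(curve, n_components = 2)
tidy(fit)
autoplot(fit)
```

## Known limitations

* Time-domain detector filtering supports real poles only (cascaded RC
  stages); complex pole pairs and zeros are available in the frequency
  domain but not in `apply_filter()`.
* `square_response()` evaluates the commonly quoted transient factor, so its
  turn-on differs from the oracle at the \(1/(\Gamma(1+e^{\pi\Gamma/\omega}))\)
  level; use the oracle when transients matter.
* The fitter is a point estimator with Gaussian uncertainties; it does not
  do model selection across component counts (nested-fit objectives are
  monotone, so compare them yourself) nor lifetime-distribution inversion.
* Phase unwrapping across fundamentals assumes parallel-sum mixtures
  (phase < 90°); cascaded systems analyzed over many decades may need the
  explicit `wrap = "unwrap"` mode and care at block boundaries.
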