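---
title: "The vital-sign detection chain: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vital-sign detection chain: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalradar)
```

vitalradar implements the complete baseband processing chain of a
continuous-wave Doppler radar that monitors heart and respiration rates
without body contact: scene synthesis, moving-target-indication (MTI)
clutter filtering, constant-false-alarm-rate (CA-CFAR) presence
detection, an overflow-controlled FFT, and phase-based rate estimation.
This vignette explains the models behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.

## Signal model

A chest at standoff $d_0$ moves as the sum of two sinusoids,

$$x(t) = A_r \sin(2\pi f_r t + \varphi_r) + A_h \sin(2\pi f_h t + \varphi_h),$$

with respiration $f_r \in [0.1, 0.5]$ Hz at $A_r$ = 4–12 mm of chest
excursion and heartbeat $f_h \in [0.6, 2]$ Hz at $A_h$ = 0.15–0.5 mm
(never above 0.6 mm, the largest displacement a heartbeat produces).
A zero-IF (homodyne) receiver mixes the echo with the transmit carrier,
so the complex baseband sample is a unit phasor carrying the two-way
path phase

$$s(n) = \exp\left(j\,\frac{4\pi\, x(n/f_s)}{\lambda}\right) + c + \ell + w(n),$$

where $\lambda = c/f_c$ is the carrier wavelength (12.5 mm at the
24 GHz default), $c$ is a constant complex static-clutter term (ground
and furniture echoes, all at zero Doppler), $\ell$ a constant
transmit-to-receive leakage term, and $w(n)$ circular complex Gaussian
noise of total power $\sigma_w^2$. Because the target phasor has unit
amplitude, $\sigma_w^2$ is the inverse linear SNR; the default
$10^{-15/10}$ is a 15 dB scene.

Radial velocity $v$ maps to the Doppler shift $f_d = 2 v f_c / c$; a
displacement of half a wavelength advances the echo phase by a full
turn, which is why unwrapped phase recovers multi-centimetre breathing
strokes at a 12.5 mm wavelength.

**What the generator emulates and what it does not.** The two-tone
model reproduces the essential nonlinearity — the phase-to-I/Q map
spreads respiration energy into a harmonic comb, which is precisely
what makes the weak heartbeat line hard to find — plus static clutter,
leakage, and thermal noise. It does not model the RF chain (mixers,
image frequencies), body scattering, non-sinusoidal breathing
waveforms, motion artefacts, multiple subjects, or range migration.
Passing the test suite therefore demonstrates correctness of the
algorithms under the stated interference model, not field performance
on arbitrary subjects.

The default slow-time rate is 20 Hz: comfortably above twice the 2 Hz
heart-band top, small enough that two minutes of data are 2400 samples.
The generator refuses sub-Nyquist configurations. An optional
multi-channel mode replicates the scene with independent noise per
fast-time channel purely so N-channel MTI filtering is exercisable.

## MTI clutter filter

Static clutter concentrates at zero frequency, so MTI is a high-pass
along slow time. The specification — passband edge $0.02\pi$
rad/sample at $-3$ dB, stopband edge $0.002\pi$ at $-20$ dB — needs a
Butterworth order of

$$N = \frac{\lg\left[(10^{|\alpha_s|/10} - 1)/(10^{|\alpha_p|/10} - 1)\right]}
{2 \lg(\omega_p/\omega_s)} = 0.9988 \approx 1,$$

so a first-order filter suffices. The analog prototype
$H(s) = s/(s+\Omega_p)$ maps through the bilinear transform (the
sampling period cancels; no pre-warping is applied, the design point
being the digital edge itself) to

$$y(n) = b_0\,[x(n) - x(n-1)] + a_1\, y(n-1), \qquad
b_0 = \frac{1}{1+\omega_p/2},\quad a_1 = \frac{1-\omega_p/2}{1+\omega_p/2},$$

giving $b_0 = 0.9695$, $a_1 = 0.9391$ at the default edge. For a
hardware-style coefficient store, `quantize_coeffs()` rounds to the
$2^{-B}$ grid (ties away from zero, for determinism); at 5 bits the
pair becomes $31/32$ and $30/32$, and the response moves by less than
0.5 dB anywhere above $0.01\pi$. Only the coefficients are quantized;
the arithmetic stays in double precision, as the filter's internal word
length is a hardware concern outside this model.

The realization is a transposed direct form II with one delay register
per fast-time channel, duplicated for the I and Q branches (two
identical real N-channel filters). State is explicit and caller-owned,
so block-wise streaming is bit-identical to one-shot filtering. The
filter's nonlinear phase is harmless here: a fixed-frequency input
keeps its per-sample phase increment, so Doppler measurements are
unaffected — only the constant offset changes.

## Square-law CA-CFAR detection

Narrowband Gaussian noise has a Rayleigh envelope and uniform phase;
after square-law detection (power = sum of squared quadratures, the
hardware-friendly high-SNR approximation of the optimal $\ln I_0$
detector) the per-bin power is exponential with mean $\sigma_w^2$. A
threshold $T$ then gives the false-alarm probability
$P_{FA} = e^{-T/\sigma_w^2}$, inverted as $T = -\sigma_w^2 \ln P_{FA}$.

The noise power is estimated per cell as the arithmetic mean of
`num_train` cells (default 32, in the conventional 30–40 range) on the
leading side of the cell under test, past `num_guard` guard cells
(default 2, keeping target energy out of the mean; 0 recovers the bare
cell-averaging description). At array edges the window reflects to the
available side; two-sided mode averages both flanks. The mean is the
maximum-likelihood estimate for exponential cells, and because the
threshold is proportional to it, the detected set is invariant to any
overall rescaling of the spectrum — the CFAR property.

Using an M-cell *estimate* in the threshold inflates the realized
alarm rate to $(1 + \ln(1/P_{FA})/M)^{-M}$ (about 0.0135 for
$P_{FA} = 0.01$, $M = 32$). The package implements the plug-in
threshold exactly and documents and tests this finite-M rate rather
than "correcting" it.

Inside the pipeline the gate uses $P_{FA} = 10^{-6}$: across the ~4096
spectrum bins of a two-minute record the expected number of
noise-induced alarms stays far below one even after finite-M inflation,
so a purely static scene does not trigger, while a breathing subject's
spectral lines exceed the threshold by orders of magnitude.

## Overflow-controlled FFT

The radix-2 decimation-in-frequency butterfly is
$a' = a + b$, $b' = (a - b) W$ with $|W| = 1$, so
$\max(|a'|,|b'|) \le |a| + |b| \le \max(2|a|, 2|b|)$: data grow by at
most a factor of two per stage. Halving every stage's outputs
therefore guarantees a fixed-point word never overflows, at the cost
of a known overall $1/N$ scale (the accumulated exponent is reported in
the result). Crucially, rounding noise injected at stage $k$ is halved
at each later stage, so the error is far smaller than pre-scaling the
input by $1/N$ would produce.

Fixed-point emulation quantizes every stage to a symmetric
two's-complement grid; the default format is 16 bits total with 14
fractional bits, spanning roughly $(-2, 2)$. Inputs must keep both
components at or below half the representable maximum, because the
twiddle rotation can grow a single component by up to $\sqrt 2$ before
the halving; under that rule saturation can never trigger. At
$N = 1024$ the emulated spectrum stays within $8 \cdot 2^{-14}$ of the
float result per component (per-stage rounding accumulation bound,
verified against a brute-force DFT oracle in the tests). Only radix-2
sizes are implemented; other lengths are zero-padded upward.

## Phase-based rate estimation

The strongest fast-time channel (mean power along slow time, ties to
the lowest index) supplies the slow-time series. Its four-quadrant
phase is unwrapped by forcing successive differences into
$(-\pi, \pi]$, and first differences turn the phase into a
velocity-like series with no slow drift. Rates are then read from the
band-limited magnitude spectrum: optional Savitzky–Golay smoothing
(window 11, order 3 — gentle enough to pass 2 Hz at a 20 Hz rate,
exposed as arguments since no canonical values exist), mean removal,
zero-padding to the next power of two, the scaled FFT, and the
strongest bin inside the physiological band. The reported rate is
$60 \times$ the peak frequency, always accompanied by the spectral
resolution $f_s/N$ (about 0.3 per minute for two-minute records); the
peak is *not* interpolated, so the estimate is honest about its grid. A
confidence flag drops when the band peak is under three times the band
median, i.e. when no clear line exists.

**Respiration harmonics and the heartbeat line.** The nonlinear
phase-to-I/Q map plus clutter filtering leaves a comb of distortion
lines at integer multiples of the respiration fundamental, often
comparable to the heartbeat line. The heart-band search therefore
treats comb positions specially, centred on a three-point
parabolic refinement of the respiration peak (an error in the
fundamental shifts its $k$-th harmonic $k$ times as far, so the centre
must be better than one bin): if the band peak lies within two
resolution bins of a comb position, it is accepted only when it
exceeds three times the strongest *sibling* tooth — a genuine
heartbeat line dwarfs the comb it happens to sit on, while a
distortion tooth is comparable to its siblings — otherwise the search
repeats with comb positions excluded. This discrimination, rather than
blanket exclusion, is what keeps heartbeats that legitimately sit on a
harmonic. The behaviour is toggleable (`exclude_resp_harmonics`).

## The assembled pipeline

`run_pipeline()` executes: synthesize (or load I/Q text) → MTI →
spectrum of the dominant channel + CA-CFAR presence gate → phase
unwrap → phase differences → respiration estimate → heartbeat estimate
with comb discrimination. The CFAR acts purely as a presence gate
(rates still come from the phase of the strongest channel, not from
CFAR output); a static scene reports no rates at all. Reported
per-minute rates are rounded to the nearest integer, matching how such
tables are printed; raw values, peak frequencies, and resolutions stay
available via `tidy()`. Every stage error is re-signalled with the
stage name attached. Configurations serialize to YAML and round-trip
exactly (15-digit precision; complex amplitudes stored as re/im pairs).

Without MTI, two things break, and the test suite demonstrates both:
the static clutter bin passes the detection threshold (a stationary
scene is mistaken for a target), and under strong clutter the
clutter-induced harmonic comb swamps the heartbeat line (respiration,
by contrast, is largely clutter-immune in a phase-based chain: the
respiration line and the noise floor both scale as the inverse clutter
amplitude).

Relative errors against a reference monitor are computed as
$100\,|r_{\text{radar}} - r_{\text{ref}}|/r_{\text{ref}}$ — the
reference-denominator convention used by the bundled session table —
with a documented switch to the measured-value denominator. Printed
percentages round half away from zero, matching published tables
(6.25 → 6.3).

## Numerical choices and degenerate inputs

* Rounding ties: away from zero, everywhere a printed-style value is
  produced (coefficient grids, error percentages, reported rates).
* The high-pass magnitude response returns $-\infty$ dB at exact DC
  (the zero at $z = 1$), not an error.
* `cfar_threshold(pfa = 1)` is 0 (always alarm); `pfa = 0` is rejected
  as an infinite threshold.
* CFAR spectra shorter than `num_train + num_guard + 1` are rejected;
  in the narrow regime where neither one-sided window fits a middle
  bin, the nearest non-guard cells from both sides keep the training
  count at exactly M.
* Zero-magnitude samples make phase undefined and are rejected rather
  than silently producing 0.
* Tie-breaks in peak and channel selection go to the lowest index.
* All random generation flows from one integer seed per scene; the
  generator restores the caller's RNG stream afterwards.

## Problem sizes

The package's own studies use two-minute records at 20 Hz (2400
samples, 4096-point padded spectra, 0.29 per-minute resolution):
long enough to separate a heartbeat line from the respiration comb,
short enough that a hundred-scene recovery study runs in seconds.
CFAR calibration uses $10^5$–$10^6$ simulated noise bins, which pins
the empirical alarm rate to three binomial standard errors of theory.

## Known limitations

* A heartbeat whose line is *both* weak and within two bins of a
  respiration harmonic of comparable strength is genuinely ambiguous
  in a single two-minute window; the comb discrimination then picks
  the harmonic. Roughly 0–2 scenes in 100 at 10 dB SNR.
* Respiration rates below ~0.15 Hz sit close to the MTI passband edge
  (0.2 Hz at the default rate) and are attenuated, though the peak
  location is preserved.
* The fixed-point path emulates word-length effects of the FFT only;
  the MTI filter quantizes coefficients but not its internal
  arithmetic.
* Rates are grid-quantized (no peak interpolation); at two minutes the
  grid is 0.29 per minute.
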