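# vitalradar

Non-contact vital-sign monitoring turns a continuous-wave Doppler radar
into a heart-rate and respiration monitor: chest-wall motion modulates
the phase of the reflected carrier, and the baseband I/Q signal of a
zero-IF receiver carries that phase directly. vitalradar implements the
complete baseband chain for researchers and students in biomedical
signal processing who want a tested, reproducible reference for each
stage:

* **Scene synthesis** — complex baseband echoes
  `s(n) = exp(j 4π x(t)/λ) + clutter + leakage + noise` from a two-tone
  chest model `x(t)` (respiration 0.1–0.5 Hz at 4–12 mm, heartbeat
  0.6–2 Hz at 0.15–0.5 mm), with seeded, bit-reproducible noise.
* **MTI clutter filtering** — first-order IIR high-pass designed by
  bilinear transform, `y(n) = b0 [x(n) − x(n−1)] + a1 y(n−1)` with
  `b0 = 1/(1+ωp/2)`, `a1 = (1−ωp/2)/(1+ωp/2)`; optional fixed-point
  coefficient quantization (5 bits → 31/32 and 30/32); N-channel
  transposed direct form II with explicit streaming state.
* **CA-CFAR detection** — square-law power, cell-averaging
  maximum-likelihood noise estimate, threshold `T = −σ̂² ln P_FA`; the
  finite-M plug-in alarm rate `(1 + ln(1/P_FA)/M)^−M` is documented and
  tested, not hidden.
* **Overflow-controlled FFT** — radix-2 butterflies with divide-by-two
  per stage (growth bound `max(|a′|,|b′|) ≤ max(2|a|,2|b|)`), optional
  16-bit fixed-point emulation.
* **Rate estimation** — phase unwrapping, phase differencing,
  Savitzky–Golay smoothing, band-limited spectral peaks with
  respiration-harmonic discrimination; rates in per-minute units with
  explicit spectral resolution.

Everything is tibble-first: signals, spectra, detections and rate
tables are tibbles, fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(vitalradar)

cfg <- pipeline_config(radar = radar_params(seed = 1))
rep <- run_pipeline(cfg)
rep
#> <vital_sign_report>
#>   detection: triggered (101 bin(s) above threshold)
#>   heart rate: 83 per minute
#>   respiration rate: 16 per minute

tidy(rep)
#> # A tibble: 2 × 5
#>   band  rate_per_min peak_freq_hz resolution_hz confident
#>   <chr>        <dbl>        <dbl>         <dbl> <lgl>
#> 1 resp          16.1        0.269       0.00488 TRUE
#> 2 heart         82.9        1.38        0.00488 TRUE
```

The default scene is a subject breathing at 0.2667 Hz (16 per minute,
8 mm excursion) with a 1.3833 Hz heartbeat (83 per minute, 0.4 mm),
15 dB SNR, static clutter and antenna leakage, observed for 120 s at
20 frames/s. The chain removes the clutter with the MTI filter, gates
target presence with CA-CFAR (101 spectrum bins clear the threshold),
and reads both rates off the phase spectrum: 83 beats and 16 breaths
per minute, each at a 0.29 per-minute spectral resolution. A purely
static scene (`chest_motion(resp_amp = 0, heart_amp = 0)`) triggers no
detection and reports no rates.

The filter behind the clutter rejection:

```r
design_highpass(0.02 * pi)
#> <first_order_iir> y(n) = 0.969541 [x(n) - x(n-1)] + 0.939082 y(n-1)
quantize_coeffs(design_highpass(0.02 * pi), 5)
#> <first_order_iir> y(n) = 0.96875 [x(n) - x(n-1)] + 0.9375 y(n-1) (coefficients 5-bit)
```

Evaluating radar measurements against a reference monitor (the package
bundles 15 paired radar/wrist-band sessions):

```r
summarize_errors(dplyr::filter(rate_sessions(), band == "heart"))
#> # A tibble: 1 × 2
#>   min_error_pct max_error_pct
#>           <dbl>         <dbl>
#> 1             0           6.3
```

A command-line front end with `generate`, `design-filter`, `detect`,
`run` and `evaluate` subcommands is installed at
`system.file("cli", "vitalradar.R", package = "vitalradar")`.

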