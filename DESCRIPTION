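Package: vitalradar
Title: Non-Contact Vital-Sign Detection from Doppler Radar Baseband Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis chain for non-contact heart-rate and
    respiration monitoring with a continuous-wave Doppler radar. Generates
    physically parameterized complex baseband echoes from chest-wall motion,
    removes static clutter with a first-order IIR moving-target-indication
    (MTI) high-pass filter designed by bilinear transform, gates target
    presence with square-law cell-averaging constant-false-alarm-rate
    (CA-CFAR) detection, computes spectra with an overflow-controlled
    radix-2 FFT (optional fixed-point emulation with per-stage scaling),
    and estimates per-minute heart and respiration rates from the unwrapped
    echo phase. Results are tibbles; fitted objects have tidy(), glance()
    and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
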