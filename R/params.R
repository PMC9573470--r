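#' Radar front-end parameters
#'
#' Describes the continuous-wave radar used to illuminate the chest:
#' carrier frequency, propagation speed, the slow-time (frame) sampling
#' rate of the demodulated baseband, and the record duration. The
#' wavelength is derived as `c / carrier_freq`.
#'
#' @param carrier_freq Transmit carrier frequency in Hz. Default 24 GHz,
#'   the band of the modelled mm-wave front end.
#' @param c Propagation speed in m/s.
#' @param slow_sample_rate Slow-time sampling rate (frames per second) of
#'   the baseband series, in Hz. Must exceed twice the highest simulated
#'   motion frequency. Default 20 Hz.
#' @param duration Record duration in seconds. Default 120 s.
#' @param seed Integer seed controlling every random draw in
#'   [synthesize_baseband()].
#' @return An object of class `radar_params`: a validated list with the
#'   above fields plus the derived `wavelength` (m).
#' @export
#' @examples
#' radar_params()$wavelength # about 12.5 mm
radar_params <- function(carrier_freq = 2.4e10,
                         c = 2.9979e8,
                         slow_sample_rate = 20,
                         duration = 120,
                         seed = 1L) {
  check_scalar(carrier_freq, "carrier_freq", lower = 0, strict_lower = TRUE)
  check_scalar(c, "c", lower = 0, strict_lower = TRUE)
  check_scalar(slow_sample_rate, "slow_sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  structure(
    list(
      carrier_freq = carrier_freq,
      c = c,
      wavelength = c / carrier_freq,
      slow_sample_rate = slow_sample_rate,
      duration = duration,
      seed = as.integer(seed)
    ),
    class = "radar_params"
  )
}

#' Chest-wall motion parameters
#'
#' Two-tone sinusoidal model of thoracic displacement: a respiration
#' component and a smaller, faster heartbeat component superimposed on a
#' constant standoff distance. Default frequencies and amplitudes sit
#' inside the normal adult bands (heartbeat 0.6--2 Hz at 0.15--0.5 mm,
#' respiration 0.1--0.5 Hz at 4--12 mm of chest excursion).
#'
#' @param resp_freq,heart_freq Respiration and heartbeat frequencies, Hz.
#' @param resp_amp,heart_amp Displacement amplitudes, mm. The heartbeat
#'   amplitude is capped at 0.6 mm, the maximum chest displacement a
#'   heartbeat produces.
#' @param resp_phase,heart_phase Initial phases, rad.
#' @param d0 Standoff distance between antenna and chest, m.
#' @return An object of class `chest_motion`.
#' @export
chest_motion <- function(resp_freq = 0.2667, resp_amp = 8,
                         heart_freq = 1.3833, heart_amp = 0.4,
                         resp_phase = 0, heart_phase = 0,
                         d0 = 0.5) {
  check_scalar(resp_freq, "resp_freq", lower = 0)
  check_scalar(heart_freq, "heart_freq", lower = 0)
  check_scalar(resp_amp, "resp_amp", lower = 0)
  check_scalar(heart_amp, "heart_amp", lower = 0, upper = 0.6)
  check_scalar(resp_phase, "resp_phase")
  check_scalar(heart_phase, "heart_phase")
  check_scalar(d0, "d0", lower = 0, strict_lower = TRUE)
  if (resp_freq > 0 && (resp_freq < 0.1 || resp_freq > 0.5)) {
    warn("`resp_freq` is outside the normal adult band [0.1, 0.5] Hz.")
  }
  if (heart_freq > 0 && (heart_freq < 0.6 || heart_freq > 2)) {
    warn("`heart_freq` is outside the normal adult band [0.6, 2] Hz.")
  }
  structure(
    list(
      resp_freq = resp_freq, resp_amp = resp_amp,
      heart_freq = heart_freq, heart_amp = heart_amp,
      resp_phase = resp_phase, heart_phase = heart_phase,
      d0 = d0
    ),
    class = "chest_motion"
  )
}

#' Interference parameters
#'
#' Additive terms corrupting the baseband echo: circular complex Gaussian
#' noise of total power `noise_power`, a constant complex static-clutter
#' term (ground and furniture echoes, concentrated at zero frequency),
#' and a constant complex transmit-to-receive antenna leakage term. The
#' moving-target phasor has unit amplitude, so `noise_power` is the
#' inverse of the linear signal-to-noise ratio.
#'
#' @param noise_power Total noise power (linear). Default `10^(-15/10)`,
#'   i.e. 15 dB SNR against the unit-amplitude target.
#' @param clutter_amp Complex amplitude of the zero-frequency clutter.
#' @param leakage_amp Complex amplitude of the direct antenna leakage.
#' @return An object of class `interference_params`.
#' @export
interference_params <- function(noise_power = 10^(-15 / 10),
                                clutter_amp = 2 + 0i,
                                leakage_amp = 1 + 0i) {
  check_scalar(noise_power, "noise_power", lower = 0)
  if (length(clutter_amp) != 1L || length(leakage_amp) != 1L) {
    abort("`clutter_amp` and `leakage_amp` must be single (complex) values.")
  }
  structure(
    list(
      noise_power = noise_power,
      clutter_amp = as.complex(clutter_amp),
      leakage_amp = as.complex(leakage_amp)
    ),
    class = "interference_params"
  )
}

#' @export
print.radar_params <- function(x, ...) {
  cat(sprintf(
    "<radar_params> %.3g GHz carrier (lambda %.3g mm), %g Hz slow-time rate, %g s, seed %d\n",
    x$carrier_freq / 1e9, x$wavelength * 1e3, x$slow_sample_rate, x$duration, x$seed
  ))
  invisible(x)
}

#' @export
print.chest_motion <- function(x, ...) {
  cat(sprintf(
    "<chest_motion> resp %.4g Hz / %.3g mm; heart %.4g Hz / %.3g mm; standoff %.3g m\n",
    x$resp_freq, x$resp_amp, x$heart_freq, x$heart_amp, x$d0
  ))
  invisible(x)
}

#' @export
print.interference_params <- function(x, ...) {
  cat(sprintf(
    "<interference_params> noise power %.4g, clutter %s, leakage %s\n",
    x$noise_power, format(x$clutter_amp), format(x$leakage_amp)
  ))
  invisible(x)
}
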