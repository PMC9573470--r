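#' Chest-wall displacement at time t
#'
#' Two-tone sinusoidal displacement model: standoff plus a respiration
#' sine plus a heartbeat sine (amplitudes given in mm, output in metres).
#'
#' @param motion A [chest_motion()] object.
#' @param t Time(s) in seconds, vectorized.
#' @return Distance(s) from the antenna in metres.
#' @export
#' @examples
#' chest_displacement(chest_motion(), t = seq(0, 5, by = 0.05))
chest_displacement <- function(motion, t) {
  stopifnot(inherits(motion, "chest_motion"))
  if (any(t < 0)) abort("`t` must be nonnegative.")
  motion$d0 +
    motion$resp_amp * 1e-3 * sin(2 * pi * motion$resp_freq * t + motion$resp_phase) +
    motion$heart_amp * 1e-3 * sin(2 * pi * motion$heart_freq * t + motion$heart_phase)
}

#' Doppler shift of an echo from a moving target
#'
#' @param v Radial velocity in m/s (positive toward the radar), vectorized.
#' @param carrier_freq Carrier frequency in Hz.
#' @param c Propagation speed in m/s.
#' @return Frequency shift `2 v carrier_freq / c` in Hz; its sign follows `v`.
#' @export
doppler_shift <- function(v, carrier_freq, c = 2.9979e8) {
  check_scalar(c, "c", lower = 0, strict_lower = TRUE)
  2 * v * carrier_freq / c
}

#' Round-trip echo phase for a given displacement
#'
#' The two-way path modulates the echo phase by `4 * pi * displacement /
#' wavelength`: one displacement period of half a wavelength advances the
#' phase by a full turn.
#'
#' @param displacement Displacement in metres, vectorized.
#' @param wavelength Carrier wavelength in metres.
#' @return Phase in radians.
#' @export
echo_phase <- function(displacement, wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0) {
    abort("`wavelength` must be a single positive number: invalid radar configuration.")
  }
  4 * pi * displacement / wavelength
}

new_baseband_signal <- function(z, sample_rate, seed = NA_integer_,
                                provenance = "synthetic") {
  z <- as.matrix(z)
  n <- nrow(z)
  n_ch <- ncol(z)
  out <- tibble(
    time_s = rep((seq_len(n) - 1) / sample_rate, times = n_ch),
    channel = rep(seq_len(n_ch), each = n),
    i = as.vector(Re(z)),
    q = as.vector(Im(z))
  )
  class(out) <- c("baseband_signal", class(out))
  attr(out, "sample_rate") <- sample_rate
  attr(out, "seed") <- seed
  attr(out, "provenance") <- provenance
  out
}

#' Build a baseband signal from raw complex samples
#'
#' Wraps an existing complex vector or matrix (slow time in rows,
#' fast-time channels in columns) in the `baseband_signal` container so
#' it can enter the processing chain.
#'
#' @param samples Complex (or numeric) vector or matrix.
#' @param sample_rate Slow-time sampling rate in Hz.
#' @param provenance Provenance tag, default `"loaded"`.
#' @return A `baseband_signal` tibble.
#' @export
as_baseband_signal <- function(samples, sample_rate = 20,
                               provenance = "loaded") {
  z <- as.matrix(samples)
  if (!all(is.finite(Re(z))) || !all(is.finite(Im(z)))) {
    abort("`samples` must be finite.")
  }
  new_baseband_signal(z, sample_rate, seed = NA_integer_,
                      provenance = provenance)
}

#' Extract the complex sample matrix of a baseband signal
#'
#' @param x A `baseband_signal` tibble.
#' @return A complex matrix, slow time in rows, fast-time channels in columns.
#' @export
bb_matrix <- function(x) {
  stopifnot(inherits(x, "baseband_signal"))
  n_ch <- max(x$channel)
  matrix(complex(real = x$i, imaginary = x$q), ncol = n_ch)
}

#' @rdname bb_matrix
#' @export
bb_sample_rate <- function(x) attr(x, "sample_rate")

#' @export
print.baseband_signal <- function(x, ...) {
  cat(sprintf(
    "<baseband_signal> %d samples x %d channel(s) at %g Hz (%s, seed %s)\n",
    length(unique(x$time_s)), max(x$channel), bb_sample_rate(x),
    attr(x, "provenance"), format(attr(x, "seed"))
  ))
  NextMethod()
}

#' Synthesize a complex baseband radar echo of a breathing subject
#'
#' Builds the slow-time quadrature baseband series a zero-IF receiver
#' would deliver: a unit-amplitude phasor `exp(1i * 4 * pi * x(t) /
#' lambda)` phase-modulated by the chest displacement `x(t)`, plus
#' constant static-clutter and antenna-leakage terms, plus circular
#' complex Gaussian noise of total power `noise_power`. The same seed and
#' parameters always reproduce the identical record.
#'
#' @param radar A [radar_params()] object (rate, duration, wavelength, seed).
#' @param motion A [chest_motion()] object; use zero amplitudes for a
#'   stationary target.
#' @param interference An [interference_params()] object.
#' @param n_channels Number of fast-time channels to emit. The default 1
#'   is the continuous-wave view; larger values replicate the scene with
#'   independent noise per channel so N-channel MTI filtering can be
#'   exercised (no range migration is modelled).
#' @return A `baseband_signal` tibble with columns `time_s`, `channel`,
#'   `i`, `q`.
#' @export
#' @examples
#' sig <- synthesize_baseband(radar_params(duration = 10), chest_motion(),
#'                            interference_params())
synthesize_baseband <- function(radar, motion, interference = interference_params(),
                                n_channels = 1L) {
  stopifnot(inherits(radar, "radar_params"), inherits(motion, "chest_motion"),
            inherits(interference, "interference_params"))
  f_max <- max(motion$resp_freq, motion$heart_freq)
  if (radar$slow_sample_rate <= 2 * f_max) {
    abort(sprintf(
      "slow_sample_rate (%g Hz) must exceed twice the highest motion frequency (%g Hz).",
      radar$slow_sample_rate, f_max
    ))
  }
  n <- round(radar$duration * radar$slow_sample_rate)
  t <- (seq_len(n) - 1) / radar$slow_sample_rate

  ## freeze the RNG stream locally so generation is seed-reproducible
  ## without disturbing the caller's stream
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(radar$seed)

  phi <- echo_phase(chest_displacement(motion, t) - motion$d0, radar$wavelength)
  target <- exp(1i * phi)
  sd_part <- sqrt(interference$noise_power / 2)
  z <- vapply(seq_len(n_channels), function(ch) {
    target + interference$clutter_amp + interference$leakage_amp +
      complex(real = rnorm(n, sd = sd_part), imaginary = rnorm(n, sd = sd_part))
  }, complex(n))
  new_baseband_signal(matrix(z, nrow = n), radar$slow_sample_rate,
                      seed = radar$seed, provenance = "synthetic")
}

#' Write / read I/Q records as delimited text
#'
#' Columnar tab-separated text with a header; columns `time_s`, `channel`
#' (only when more than one), `i`, `q`. Values survive a round trip to at
#' least 12 significant digits.
#'
#' @param x A `baseband_signal` tibble.
#' @param path File path.
#' @return `write_iq()` returns `x` invisibly; `read_iq()` returns a
#'   `baseband_signal` with provenance `"loaded"`.
#' @export
write_iq <- function(x, path) {
  stopifnot(inherits(x, "baseband_signal"))
  df <- as_tibble(x)
  if (max(df$channel) == 1L) df$channel <- NULL
  readr::write_tsv(df, path)
  invisible(x)
}

#' @rdname write_iq
#' @param sample_rate Sampling rate in Hz; if `NULL`, inferred from the
#'   median spacing of `time_s`.
#' @export
read_iq <- function(path, sample_rate = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("time_s", "i", "q") %in% names(df))) {
    abort("I/Q file must have columns time_s, i, q (and optionally channel).")
  }
  if (!"channel" %in% names(df)) df$channel <- 1L
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(sort(unique(df$time_s))))
    sample_rate <- 1 / dt
  }
  n_ch <- max(df$channel)
  df <- dplyr::arrange(df, .data$channel, .data$time_s)
  z <- matrix(complex(real = df$i, imaginary = df$q), ncol = n_ch)
  new_baseband_signal(z, sample_rate, seed = NA_integer_, provenance = "loaded")
}
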