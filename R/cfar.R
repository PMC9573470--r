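#' CA-CFAR configuration
#'
#' Cell-averaging constant-false-alarm-rate settings: the design
#' false-alarm probability, the number of training cells averaged into
#' the local noise estimate (30--40 is typical; default 32), the number
#' of guard cells skipped next to the cell under test, and whether the
#' training window sits on the leading side only or on both flanks.
#'
#' @param pfa Design false-alarm probability, in `(0, 1)`.
#' @param num_train Training cells, at least 1.
#' @param num_guard Guard cells, at least 0.
#' @param sidedness `"one-sided-leading"` (default) or `"two-sided"`.
#' @return An object of class `cfar_config`.
#' @export
cfar_config <- function(pfa = 0.01, num_train = 32L, num_guard = 2L,
                        sidedness = c("one-sided-leading", "two-sided")) {
  check_scalar(pfa, "pfa", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_scalar(num_train, "num_train", lower = 1)
  check_scalar(num_guard, "num_guard", lower = 0)
  structure(
    list(pfa = pfa, num_train = as.integer(num_train),
         num_guard = as.integer(num_guard),
         sidedness = match.arg(sidedness)),
    class = "cfar_config"
  )
}

new_power_spectrum <- function(power, bin_width = NA_real_, freq_hz = NULL) {
  if (any(!is.finite(power)) || any(power < 0)) {
    abort("Power spectrum values must be finite and nonnegative.")
  }
  out <- tibble(
    bin = seq_along(power),
    freq_hz = freq_hz %||% (seq_along(power) - 1) * bin_width,
    power = as.numeric(power)
  )
  class(out) <- c("power_spectrum", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Square-law detection of complex spectrum bins
#'
#' Power per bin as the sum of squared real and imaginary parts --- the
#' hardware-friendly approximation to the optimal `ln I0` detector at
#' high SNR, equivalent to taking the power spectrum. Under circular
#' Gaussian noise the Rayleigh envelope becomes exponentially
#' distributed power.
#'
#' @param bins Complex vector of spectrum bins, or an [fft_scaled()]
#'   result (its scaling is kept as-is).
#' @param bin_width Frequency step between bins in Hz (optional metadata).
#' @return A `power_spectrum` tibble with columns `bin`, `freq_hz`, `power`.
#' @export
square_law <- function(bins, bin_width = NA_real_) {
  freq <- NULL
  if (inherits(bins, "fft_result")) {
    bin_width <- bins$sample_rate / bins$n
    freq <- fft_bin_freqs(bins$n, bins$sample_rate)
    bins <- bins$bins
  }
  if (any(!is.finite(Re(bins))) || any(!is.finite(Im(bins)))) {
    abort("`bins` must be finite.")
  }
  new_power_spectrum(Re(bins)^2 + Im(bins)^2, bin_width = bin_width,
                     freq_hz = freq)
}

#' Rayleigh and exponential noise densities
#'
#' Narrowband Gaussian noise of power `sigma2` has a Rayleigh-distributed
#' envelope, `x / sigma2 * exp(-x^2 / (2 sigma2))`; after square-law
#' detection the power is exponential, `1 / sigma2 * exp(-x / sigma2)`.
#'
#' @param x Amplitude (Rayleigh) or power (exponential), nonnegative.
#' @param sigma2 Noise power, positive.
#' @return Density values.
#' @export
rayleigh_pdf <- function(x, sigma2) {
  check_scalar(sigma2, "sigma2", lower = 0, strict_lower = TRUE)
  if (any(x < 0)) abort("`x` must be nonnegative.")
  x / sigma2 * exp(-x^2 / (2 * sigma2))
}

#' @rdname rayleigh_pdf
#' @export
exponential_pdf <- function(x, sigma2) {
  check_scalar(sigma2, "sigma2", lower = 0, strict_lower = TRUE)
  if (any(x < 0)) abort("`x` must be nonnegative.")
  exp(-x / sigma2) / sigma2
}

#' CFAR detection threshold for a given noise power
#'
#' Under square-law detection the false-alarm probability at threshold
#' `T` over exponential noise of power `sigma2` is `exp(-T / sigma2)`,
#' so the threshold achieving a design `pfa` is `T = -sigma2 * log(pfa)`.
#'
#' @param noise_power Noise power estimate(s), nonnegative (vectorized).
#' @param pfa False-alarm probability in `(0, 1]`.
#' @return Threshold(s) in power units.
#' @export
cfar_threshold <- function(noise_power, pfa) {
  if (any(noise_power < 0)) abort("`noise_power` must be nonnegative.")
  if (length(pfa) != 1L || !is.finite(pfa) || pfa <= 0 || pfa > 1) {
    abort("`pfa` must be a single value in (0, 1]; pfa = 0 would need an infinite threshold.")
  }
  -noise_power * log(pfa)
}

## Vectorized sliding training means. Returns the per-bin noise estimate.
## Leading side = lower bin indices. Where a full window does not fit on
## the preferred side the window reflects to the other side; in the rare
## middle regime of a very short spectrum the nearest non-guard cells
## from both sides are used so every bin keeps exactly M training cells.
cfar_noise_estimates <- function(power, config) {
  n <- length(power)
  m <- config$num_train
  g <- config$num_guard
  if (n < m + g + 1) {
    abort(sprintf(
      "Spectrum length %d is below num_train + num_guard + 1 = %d.",
      n, m + g + 1
    ))
  }
  cs <- c(0, cumsum(power))
  winmean <- function(a, b) (cs[b + 1] - cs[a]) / (b - a + 1)
  i <- seq_len(n)
  lead_ok <- i - g - m >= 1
  trail_ok <- i + g + m <= n
  lead <- rep(NA_real_, n)
  trail <- rep(NA_real_, n)
  li <- which(lead_ok)
  if (length(li)) lead[li] <- (cs[li - g] - cs[li - g - m]) / m
  ti <- which(trail_ok)
  if (length(ti)) trail[ti] <- (cs[ti + g + m + 1] - cs[ti + g + 1]) / m
  est <- if (config$sidedness == "two-sided") {
    ifelse(lead_ok & trail_ok, (lead + trail) / 2,
           ifelse(lead_ok, lead, trail))
  } else {
    ifelse(lead_ok, lead, trail)
  }
  ## short-spectrum middle bins: neither full one-sided window fits
  for (k in which(is.na(est))) {
    cand <- setdiff(seq_len(n), (k - g):(k + g))
    cand <- cand[order(abs(cand - k))][seq_len(m)]
    est[k] <- mean(power[cand])
  }
  est
}

#' Maximum-likelihood local noise estimate for CFAR
#'
#' The arithmetic mean of the training cells adjacent to the cell under
#' test (beyond the guard cells) --- the maximum-likelihood estimate of
#' the clutter-plus-noise power for exponentially distributed cells. The
#' leading (lower-index) side is used by default; at array edges the
#' window reflects to the available side, and two-sided mode averages
#' both flanks.
#'
#' @param spectrum A `power_spectrum` tibble (from [square_law()]) or a
#'   nonnegative numeric vector.
#' @param bin Bin index (1-based), vectorized.
#' @param config A [cfar_config()].
#' @return Noise power estimate(s), one per requested bin.
#' @export
#' @examples
#' estimate_noise(c(1:32, 100, 1:32), bin = 33, cfar_config(num_guard = 0))
estimate_noise <- function(spectrum, bin, config = cfar_config()) {
  power <- if (inherits(spectrum, "power_spectrum")) spectrum$power else spectrum
  est <- cfar_noise_estimates(power, config)
  est[bin]
}

#' Cell-averaging CFAR detection over a power spectrum
#'
#' For every bin: estimate the local noise power from the training
#' cells, scale it to the threshold `-sigma2_hat * log(pfa)`, and flag
#' the bin when its power exceeds the threshold. The threshold tracks
#' the local noise level, which keeps the false-alarm probability fixed
#' and makes the detected set invariant to any overall rescaling of the
#' spectrum.
#'
#' @param spectrum A `power_spectrum` tibble or nonnegative numeric vector.
#' @param config A [cfar_config()].
#' @param noise_power Optional known noise power; when supplied the
#'   cell-averaging estimate is bypassed and this value is used for
#'   every bin (useful for calibration studies).
#' @return A `cfar_detection` tibble with columns `bin`, `freq_hz`,
#'   `power`, `noise_estimate`, `threshold`, `detected`.
#' @export
cfar_detect <- function(spectrum, config = cfar_config(), noise_power = NULL) {
  stopifnot(inherits(config, "cfar_config"))
  if (inherits(spectrum, "power_spectrum")) {
    power <- spectrum$power
    freq <- spectrum$freq_hz
  } else {
    power <- spectrum
    freq <- rep(NA_real_, length(spectrum))
  }
  est <- if (is.null(noise_power)) {
    cfar_noise_estimates(power, config)
  } else {
    rep(noise_power, length(power))
  }
  thr <- cfar_threshold(est, config$pfa)
  out <- tibble(
    bin = seq_along(power),
    freq_hz = freq,
    power = power,
    noise_estimate = est,
    threshold = thr,
    detected = power > thr
  )
  class(out) <- c("cfar_detection", class(out))
  attr(out, "config") <- config
  out
}

#' One-row summary of a CFAR detection table
#'
#' @param x A `cfar_detection` tibble.
#' @param ... Unused.
#' @return A tibble with the number of bins tested, the number detected,
#'   the empirical alarm fraction and the design `pfa`.
#' @method glance cfar_detection
#' @export
glance.cfar_detection <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_bins = nrow(x),
    n_detected = sum(x$detected),
    alarm_fraction = mean(x$detected),
    pfa = cfg$pfa,
    num_train = cfg$num_train,
    num_guard = cfg$num_guard
  )
}
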