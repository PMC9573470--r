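#' High-pass design specification for the MTI clutter filter
#'
#' Frequencies are digital, in rad/sample; attenuations are negative dB.
#' Defaults are the clutter-rejection point of the vital-sign chain:
#' passband edge `0.02*pi` at -3 dB, stopband edge `0.002*pi` at -20 dB.
#'
#' @param passband_cutoff,stopband_cutoff Passband / stopband edge
#'   frequencies, rad/sample, `0 < stopband < passband < pi`.
#' @param passband_atten,stopband_atten Attenuations in dB (negative;
#'   stopband more attenuated than passband).
#' @return An object of class `highpass_spec`.
#' @export
highpass_spec <- function(passband_cutoff = 0.02 * pi,
                          stopband_cutoff = 0.002 * pi,
                          passband_atten = -3,
                          stopband_atten = -20) {
  check_scalar(passband_cutoff, "passband_cutoff", lower = 0, upper = pi,
               strict_lower = TRUE)
  check_scalar(stopband_cutoff, "stopband_cutoff", lower = 0,
               upper = passband_cutoff, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(passband_atten, "passband_atten", upper = 0, strict_upper = TRUE)
  check_scalar(stopband_atten, "stopband_atten", upper = passband_atten,
               strict_upper = TRUE)
  structure(
    list(
      passband_cutoff = passband_cutoff, stopband_cutoff = stopband_cutoff,
      passband_atten = passband_atten, stopband_atten = stopband_atten
    ),
    class = "highpass_spec"
  )
}

#' Butterworth order required by a high-pass specification
#'
#' Standard closed form
#' `N = log10((10^(|as|/10) - 1) / (10^(|ap|/10) - 1)) / (2 * log10(wp / ws))`
#' for a high-pass (passband above stopband). The -3 dB / -20 dB,
#' ratio-10 clutter specification yields 0.9988, rounded up to a
#' first-order filter.
#'
#' @param spec A [highpass_spec()] object.
#' @return A list with `order_real` (the value before rounding) and
#'   `order` (`ceiling`, at least 1).
#' @export
#' @examples
#' butterworth_order(highpass_spec())$order_real # 0.9988
butterworth_order <- function(spec) {
  stopifnot(inherits(spec, "highpass_spec"))
  ratio <- spec$passband_cutoff / spec$stopband_cutoff
  if (ratio == 1) abort("Degenerate specification: equal cutoff frequencies.")
  num <- (10^(abs(spec$stopband_atten) / 10) - 1) /
    (10^(abs(spec$passband_atten) / 10) - 1)
  order_real <- log10(num) / (2 * log10(ratio))
  list(order_real = order_real, order = max(1L, as.integer(ceiling(order_real))))
}

new_first_order_iir <- function(b0, a1, quant_bits = NULL, sample_period = 1) {
  if (abs(a1) >= 1) {
    abort(sprintf("Unstable filter: |a1| = %g >= 1.", abs(a1)))
  }
  if (b0 <= 0) abort("`b0` must be positive.")
  structure(
    list(b0 = b0, a1 = a1, quant_bits = quant_bits, sample_period = sample_period),
    class = "first_order_iir"
  )
}

#' Design the first-order IIR MTI high-pass by bilinear transform
#'
#' Maps the analog prototype `H(s) = s / (s + Omega_p)` through the
#' bilinear transform `s = (2/T) (1 - z^-1) / (1 + z^-1)` (the sampling
#' period cancels), giving
#' `H(z) = b0 (1 - z^-1) / (1 - a1 z^-1)` with
#' `b0 = 1 / (1 + wp/2)` and `a1 = (1 - wp/2) / (1 + wp/2)`,
#' i.e. the recursion `y(n) = b0 * (x(n) - x(n-1)) + a1 * y(n-1)`.
#' No frequency pre-warping is applied; the design point is the digital
#' passband edge itself.
#'
#' @param passband_cutoff Digital passband edge, rad/sample, in `(0, pi)`.
#' @param sample_period Slow-time sampling period in seconds (bookkeeping
#'   only; the coefficients do not depend on it).
#' @return A `first_order_iir` object with fields `b0` and `a1`.
#' @export
#' @examples
#' design_highpass(0.02 * pi) # b0 = 0.9695, a1 = 0.9391
design_highpass <- function(passband_cutoff = 0.02 * pi, sample_period = 1) {
  check_scalar(passband_cutoff, "passband_cutoff", lower = 0, upper = pi,
               strict_lower = TRUE, strict_upper = TRUE)
  half <- passband_cutoff / 2
  new_first_order_iir(
    b0 = 1 / (1 + half),
    a1 = (1 - half) / (1 + half),
    sample_period = sample_period
  )
}

#' Quantize IIR coefficients to a power-of-two grid
#'
#' Rounds each coefficient to the nearest multiple of `2^-bits` (ties
#' away from zero), emulating a fixed-point hardware coefficient store.
#' At 5 bits the clutter filter becomes `y(n) = 31/32 (x(n) - x(n-1)) +
#' 30/32 y(n-1)`. Stability is re-checked after rounding.
#'
#' @param filter A `first_order_iir` object.
#' @param bits Number of fractional bits, at least 1.
#' @return A `first_order_iir` with quantized coefficients and
#'   `quant_bits` recorded.
#' @export
quantize_coeffs <- function(filter, bits) {
  stopifnot(inherits(filter, "first_order_iir"))
  check_scalar(bits, "bits", lower = 1)
  b0q <- round_to_grid(filter$b0, bits)
  a1q <- round_to_grid(filter$a1, bits)
  if (abs(a1q) >= 1) {
    abort(sprintf("Quantization to %d bits yields an unstable filter (a1 = %g).",
                  bits, a1q))
  }
  new_first_order_iir(b0q, a1q, quant_bits = as.integer(bits),
                      sample_period = filter$sample_period)
}

#' Magnitude response of the MTI filter in dB
#'
#' Evaluates `20 log10 |b0 (1 - e^{-jw}) / (1 - a1 e^{-jw})|`. The
#' high-pass zero at `z = 1` makes the response `-Inf` at exact DC.
#'
#' @param filter A `first_order_iir` object.
#' @param omega Digital frequency(ies) in rad/sample, in `[0, pi]`.
#' @return Gain in dB (vectorized); `-Inf` at `omega = 0`.
#' @export
magnitude_response <- function(filter, omega) {
  stopifnot(inherits(filter, "first_order_iir"))
  if (any(omega < 0 | omega > pi)) abort("`omega` must lie in [0, pi].")
  z1 <- exp(-1i * omega)
  20 * log10(Mod(filter$b0 * (1 - z1) / (1 - filter$a1 * z1)))
}

#' Sampled frequency-response table
#'
#' @param filter A `first_order_iir` object.
#' @param n Number of frequency points over `(0, pi]`.
#' @return A tibble with columns `omega_rad` and `gain_db`.
#' @export
frequency_response <- function(filter, n = 512) {
  omega <- seq(0, pi, length.out = n + 1)[-1]
  tibble(omega_rad = omega, gain_db = magnitude_response(filter, omega))
}

#' Fresh per-channel MTI filter state
#'
#' The filter runs as a transposed direct form II: one delay register per
#' channel, kept separately for the in-phase and quadrature branches so a
#' complex slow-time record is filtered by two identical real N-channel
#' filters. State is explicit and caller-owned so block-wise streaming
#' equals one-shot processing.
#'
#' @param n_channels Number of fast-time channels.
#' @return An object of class `mti_state` (all-zero registers).
#' @export
mti_state <- function(n_channels = 1L) {
  structure(
    list(d_re = numeric(n_channels), d_im = numeric(n_channels),
         n_channels = as.integer(n_channels)),
    class = "mti_state"
  )
}

## Transposed direct form II recursion for H(z) = b0 (1 - z^-1)/(1 - a1 z^-1):
##   y[n] = b0 * x[n] + d[n-1]
##   d[n] = -b0 * x[n] + a1 * y[n]
tdf2_filter_real <- function(x, b0, a1, d0) {
  n <- length(x)
  y <- numeric(n)
  d <- d0
  for (k in seq_len(n)) {
    y[k] <- b0 * x[k] + d
    d <- -b0 * x[k] + a1 * y[k]
  }
  list(y = y, d = d)
}

#' Apply the MTI clutter filter along slow time
#'
#' Filters every fast-time channel of a complex baseband record
#' independently along slow time, in-phase and quadrature branches
#' through identical coefficient sets. The updated delay registers are
#' attached to the result (retrieve with [mti_state_of()]) so a long
#' record can be processed in blocks with carried state.
#'
#' @param signal A `baseband_signal` tibble.
#' @param filter A `first_order_iir` object.
#' @param state An [mti_state()] whose channel count matches the signal;
#'   defaults to a fresh all-zero state.
#' @return A filtered `baseband_signal` with attribute `mti_state`.
#' @export
mti_apply <- function(signal, filter, state = NULL) {
  stopifnot(inherits(signal, "baseband_signal"), inherits(filter, "first_order_iir"))
  z <- bb_matrix(signal)
  n_ch <- ncol(z)
  if (is.null(state)) state <- mti_state(n_ch)
  stopifnot(inherits(state, "mti_state"))
  if (state$n_channels != n_ch) {
    abort(sprintf("Filter state has %d channel(s) but the signal has %d.",
                  state$n_channels, n_ch))
  }
  out <- z
  new_state <- state
  for (ch in seq_len(n_ch)) {
    re <- tdf2_filter_real(Re(z[, ch]), filter$b0, filter$a1, state$d_re[ch])
    im <- tdf2_filter_real(Im(z[, ch]), filter$b0, filter$a1, state$d_im[ch])
    out[, ch] <- complex(real = re$y, imaginary = im$y)
    new_state$d_re[ch] <- re$d
    new_state$d_im[ch] <- im$d
  }
  res <- new_baseband_signal(out, bb_sample_rate(signal),
                             seed = attr(signal, "seed"),
                             provenance = attr(signal, "provenance"))
  attr(res, "mti_state") <- new_state
  res
}

#' @rdname mti_apply
#' @param x A filtered `baseband_signal`.
#' @export
mti_state_of <- function(x) attr(x, "mti_state")

#' @export
print.first_order_iir <- function(x, ...) {
  cat(sprintf(
    "<first_order_iir> y(n) = %.6g [x(n) - x(n-1)] + %.6g y(n-1)%s\n",
    x$b0, x$a1,
    if (is.null(x$quant_bits)) "" else sprintf(" (coefficients %d-bit)", x$quant_bits)
  ))
  invisible(x)
}

#' Tidy an MTI filter into a coefficient table
#'
#' @param x A `first_order_iir` object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @method tidy first_order_iir
#' @export
tidy.first_order_iir <- function(x, ...) {
  tibble(term = c("b0", "a1"), estimate = c(x$b0, x$a1))
}

#' @rdname tidy.first_order_iir
#' @return `glance()`: a one-row summary with the DC gain, the -3 dB
#'   check frequencies and stability flag.
#' @method glance first_order_iir
#' @export
glance.first_order_iir <- function(x, ...) {
  tibble(
    b0 = x$b0, a1 = x$a1,
    quant_bits = x$quant_bits %||% NA_integer_,
    stable = abs(x$a1) < 1
  )
}
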