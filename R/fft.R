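#' Fixed-point number format
#'
#' Symmetric two's-complement fixed-point grid with `total_bits` total
#' and `frac_bits` fractional bits: representable values are integer
#' multiples of `2^-frac_bits` with magnitude at most
#' `(2^(total_bits - 1) - 1) * 2^-frac_bits`. The default 16-bit format
#' with 14 fractional bits spans roughly (-2, 2), so the rule that FFT
#' input components stay below half the representable maximum means
#' components of magnitude at most about 1.
#'
#' @param total_bits Total word length, default 16.
#' @param frac_bits Fractional bits, default 14.
#' @return An object of class `fixed_point_format`.
#' @export
fixed_point_format <- function(total_bits = 16L, frac_bits = 14L) {
  check_scalar(total_bits, "total_bits", lower = 2)
  check_scalar(frac_bits, "frac_bits", lower = 0, upper = total_bits)
  structure(
    list(total_bits = as.integer(total_bits), frac_bits = as.integer(frac_bits)),
    class = "fixed_point_format"
  )
}

#' @rdname fixed_point_format
#' @param fmt A `fixed_point_format`.
#' @return `fp_max()`: the largest representable magnitude.
#' @export
fp_max <- function(fmt) (2^(fmt$total_bits - 1) - 1) * 2^(-fmt$frac_bits)

## Round-to-nearest onto the fixed-point grid, saturating at the rails.
fp_quantize <- function(z, fmt) {
  lim <- fp_max(fmt)
  q <- function(v) pmin(pmax(round_to_grid(v, fmt$frac_bits), -lim), lim)
  complex(real = q(Re(z)), imaginary = q(Im(z)))
}

#' Radix-2 FFT butterfly
#'
#' The primitive of the decimation-in-frequency FFT:
#' `a' = a + b`, `b' = (a - b) * twiddle`, with a unit-modulus twiddle
#' factor. Output magnitudes obey `|a'| <= |a| + |b|` and
#' `|b'| <= |a| + |b|`, hence `max(|a'|, |b'|) <= max(2|a|, 2|b|)`:
#' per-stage growth is at most a factor of two, which is what per-stage
#' halving exploits to prevent fixed-point overflow.
#'
#' @param a,b Complex inputs (vectorized).
#' @param twiddle Unit-modulus complex twiddle factor(s).
#' @return A list with components `a_prime` and `b_prime`.
#' @export
butterfly <- function(a, b, twiddle) {
  if (any(abs(Mod(twiddle) - 1) > 1e-12)) {
    abort("`twiddle` must have unit modulus.")
  }
  a_prime <- a + b
  b_prime <- (a - b) * twiddle
  grow <- pmax(Mod(a_prime), Mod(b_prime)) <=
    pmax(2 * Mod(a), 2 * Mod(b)) + 1e-12
  if (!all(grow)) abort("Butterfly growth bound violated.") # unreachable by algebra
  list(a_prime = a_prime, b_prime = b_prime)
}

bit_reverse_perm <- function(n) {
  bits <- as.integer(log2(n))
  v <- 0:(n - 1)
  r <- integer(n)
  for (b in seq_len(bits)) {
    r <- r * 2L + v %% 2L
    v <- v %/% 2L
  }
  r + 1L
}

#' Overflow-controlled radix-2 FFT with per-stage scaling
#'
#' Decimation-in-frequency radix-2 FFT in which every stage's butterfly
#' outputs are divided by two before the next stage. Because a butterfly
#' can grow data by at most a factor of two, the halving guarantees a
#' fixed-point word never overflows while only accumulating an overall
#' known factor `1/N`; per-stage rounding noise is itself halved at each
#' subsequent stage, so far less precision is lost than by pre-scaling
#' the input by `1/N`. In float mode the result equals the standard DFT
#' divided by `N` exactly; with a [fixed_point_format()] every stage
#' output is additionally rounded to the fixed-point grid (saturating at
#' the rails, which cannot trigger when the input precondition holds).
#'
#' @param x Complex (or numeric) vector whose length is a power of two.
#' @param fmt Optional [fixed_point_format()] enabling fixed-point
#'   emulation. Real and imaginary input components must then not exceed
#'   half the representable maximum (twiddle rotation can grow a
#'   component by up to a factor `sqrt(2)` before the halving).
#' @param sample_rate Sampling rate in Hz (metadata for frequency axes).
#' @return An object of class `fft_result`: `bins` (the `DFT/N`-scaled
#'   spectrum in natural bin order), `scale_exponent` (`log2(N)` halving
#'   stages applied), `n`, `sample_rate`, and `fmt`.
#' @export
#' @examples
#' fft_scaled(rep(1, 8))$bins[1] # DC bin = 1 after 1/N scaling
fft_scaled <- function(x, fmt = NULL, sample_rate = NA_real_) {
  n <- length(x)
  if (n < 2 || !is_power_of_two(n)) {
    abort(sprintf("Length %d is not a power of two.", n))
  }
  X <- as.complex(x)
  if (!is.null(fmt)) {
    stopifnot(inherits(fmt, "fixed_point_format"))
    lim <- fp_max(fmt) / 2
    if (max(abs(Re(X)), abs(Im(X))) > lim) {
      abort(sprintf(
        "Overflow risk: input components must not exceed half the representable maximum (%g).",
        lim
      ))
    }
    X <- fp_quantize(X, fmt)
  }
  size <- n
  while (size >= 2) {
    half <- size %/% 2
    tw <- exp(-2i * pi * (0:(half - 1)) / size)
    m <- matrix(X, nrow = size)
    a <- m[seq_len(half), , drop = FALSE]
    b <- m[half + seq_len(half), , drop = FALSE]
    m[seq_len(half), ] <- (a + b) / 2
    m[half + seq_len(half), ] <- ((a - b) * tw) / 2
    X <- as.vector(m)
    if (!is.null(fmt)) X <- fp_quantize(X, fmt)
    size <- half
  }
  X <- X[bit_reverse_perm(n)]
  structure(
    list(bins = X, scale_exponent = as.integer(log2(n)), n = n,
         sample_rate = sample_rate, fmt = fmt),
    class = "fft_result"
  )
}

#' Frequency of each FFT bin in natural order
#'
#' @param n FFT length.
#' @param sample_rate Sampling rate in Hz.
#' @return Frequencies in Hz: nonnegative up to just below `sample_rate/2`,
#'   then the negative half.
#' @export
fft_bin_freqs <- function(n, sample_rate) {
  k <- 0:(n - 1)
  ifelse(k < n / 2, k, k - n) * sample_rate / n
}

#' @export
print.fft_result <- function(x, ...) {
  cat(sprintf(
    "<fft_result> N = %d, scale exponent %d (bins = DFT / 2^%d)%s\n",
    x$n, x$scale_exponent, x$scale_exponent,
    if (is.null(x$fmt)) "" else sprintf(", fixed point Q%d.%d",
                                        x$fmt$total_bits - x$fmt$frac_bits - 1,
                                        x$fmt$frac_bits)
  ))
  invisible(x)
}

#' @export
as_tibble.fft_result <- function(x, ...) {
  tibble(
    bin = seq_len(x$n),
    freq_hz = if (is.na(x$sample_rate)) NA_real_ else fft_bin_freqs(x$n, x$sample_rate),
    re = Re(x$bins),
    im = Im(x$bins),
    power = Mod(x$bins)^2
  )
}
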