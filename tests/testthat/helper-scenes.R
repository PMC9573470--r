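# Shared scene builders for the test suite.

quiet_scene <- function(seed = 1, duration = 60, rate = 20,
                        motion = chest_motion(), noise_power = 0,
                        clutter = 0 + 0i, leakage = 0 + 0i, n_channels = 1L) {
  synthesize_baseband(
    radar_params(slow_sample_rate = rate, duration = duration, seed = seed),
    motion,
    interference_params(noise_power = noise_power, clutter_amp = clutter,
                        leakage_amp = leakage),
    n_channels = n_channels
  )
}

# Circular complex Gaussian noise samples, independent of package RNG wrappers.
cgauss <- function(n, power) {
  complex(real = rnorm(n, sd = sqrt(power / 2)),
          imaginary = rnorm(n, sd = sqrt(power / 2)))
}

# Brute-force O(N^2) DFT oracle.
dft_direct <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  w <- exp(-2i * pi * outer(k, k) / n)
  as.vector(w %*% x)
}

# Direct-form recursion oracle for y(n) = b0 [x(n) - x(n-1)] + a1 y(n-1).
iir_direct <- function(x, b0, a1) {
  y <- numeric(length(x))
  xm1 <- 0
  ym1 <- 0
  for (k in seq_along(x)) {
    y[k] <- b0 * (x[k] - xm1) + a1 * ym1
    xm1 <- x[k]
    ym1 <- y[k]
  }
  y
}
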