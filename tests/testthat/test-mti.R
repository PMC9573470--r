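test_that("Butterworth order formula reproduces the design point", {
  res <- butterworth_order(highpass_spec())
  expect_equal(res$order_real, 0.9988, tolerance = 5e-4)
  expect_identical(res$order, 1L)
  # direct evaluation of the closed form at a deeper stopband
  res40 <- butterworth_order(highpass_spec(stopband_atten = -40))
  expect_equal(res40$order_real,
               log10((1e4 - 1) / (10^0.3 - 1)) / 2, tolerance = 1e-12)
  expect_equal(round(res40$order_real, 4), 2.0010)
  expect_identical(res40$order, 3L) # ceiling of 2.001
  # (near-)equal attenuations need no selectivity: order clamps to 1
  flat <- butterworth_order(highpass_spec(stopband_atten = -3 - 1e-9))
  expect_lt(flat$order_real, 1e-6)
  expect_identical(flat$order, 1L)
  expect_error(highpass_spec(stopband_cutoff = 0.02 * pi), "outside the allowed")
})

test_that("bilinear-transform design yields the published coefficient pair", {
  f <- design_highpass(0.02 * pi)
  expect_equal(f$b0, 1 / (1 + 0.01 * pi), tolerance = 1e-15)
  expect_equal(f$a1, (1 - 0.01 * pi) / (1 + 0.01 * pi), tolerance = 1e-15)
  # printed to 4 decimals as 0.9696 / 0.9391; exact values agree to one
  # unit in the last printed digit
  expect_equal(f$b0, 0.9696, tolerance = 1e-4)
  expect_equal(round(f$a1, 4), 0.9391)
  # independent point: wp = 0.1 pi
  f2 <- design_highpass(0.1 * pi)
  expect_equal(round(f2$b0, 5), 0.86424)
  expect_equal(round(f2$a1, 5), 0.72849)
  # wp -> 0 limit: pure differencer-accumulator
  f0 <- design_highpass(1e-12)
  expect_equal(f0$b0, 1, tolerance = 1e-9)
  expect_equal(f0$a1, 1, tolerance = 1e-9)
  expect_error(design_highpass(pi), "outside the allowed")
})

test_that("5-bit coefficient quantization lands on 31/32 and 30/32", {
  q <- quantize_coeffs(design_highpass(0.02 * pi), 5)
  expect_identical(q$b0, 31 / 32)
  expect_identical(q$a1, 30 / 32)
  expect_identical(q$quant_bits, 5L)
  # nearest-multiple oracle on a second design
  q2 <- quantize_coeffs(design_highpass(0.1 * pi), 5)
  expect_identical(q2$b0, 28 / 32)
  expect_identical(q2$a1, 23 / 32)
  # grid points are fixed points of the rounding
  expect_identical(quantize_coeffs(q, 5)$b0, q$b0)
  expect_identical(quantize_coeffs(q, 5)$a1, q$a1)
})

test_that("rounding to the coefficient grid takes ties away from zero", {
  expect_identical(vitalradar:::round_to_grid(0.5 / 32 + 30 / 32, 5), 31 / 32)
  expect_identical(vitalradar:::round_to_grid(-(0.5 / 32 + 30 / 32), 5), -31 / 32)
})

test_that("frequency response meets the passband and stopband points", {
  f <- design_highpass(0.02 * pi)
  expect_identical(magnitude_response(f, 0), -Inf)
  g_pass <- magnitude_response(f, 0.02 * pi)
  g_stop <- magnitude_response(f, 0.002 * pi)
  expect_equal(g_pass, -3.01, tolerance = 0.005)
  expect_lte(g_stop, -20)
  expect_equal(g_stop, -20.04, tolerance = 0.005)
  # high-pass: response increases toward Nyquist
  tbl <- frequency_response(f, 64)
  expect_true(all(diff(tbl$gain_db) > 0))
})

test_that("constant clutter decays along the closed-form envelope", {
  f <- design_highpass(0.02 * pi)
  amp <- 57.3
  sig <- quiet_scene(
    motion = chest_motion(resp_amp = 0, heart_amp = 0),
    duration = 20, clutter = amp - 1 + 0i # total constant = amp
  )
  y <- Re(bb_matrix(mti_apply(sig, f))[, 1])
  n <- seq_along(y) - 1
  expect_equal(y, amp * f$b0 * f$a1^n, tolerance = 1e-12)
  expect_lt(abs(y[201]), 0.01 * amp)
})

test_that("impulse response equals the brute-force recursion", {
  f <- design_highpass(0.02 * pi)
  x <- c(1, numeric(99))
  sig <- as_baseband_signal(x)
  y <- Re(bb_matrix(mti_apply(sig, f))[, 1])
  expect_equal(y, iir_direct(x, f$b0, f$a1), tolerance = 1e-12)
})

test_that("transposed form matches direct recursion and signal::filter", {
  f <- design_highpass(0.07 * pi)
  set.seed(11)
  x <- rnorm(500)
  y <- Re(bb_matrix(mti_apply(as_baseband_signal(x), f))[, 1])
  expect_equal(y, iir_direct(x, f$b0, f$a1), tolerance = 1e-12)
  oracle <- as.numeric(signal::filter(c(f$b0, -f$b0), c(1, -f$a1), x))
  expect_equal(y, oracle, tolerance = 1e-10)
})

test_that("MTI filtering is linear from reset state", {
  f <- design_highpass(0.02 * pi)
  set.seed(21)
  x <- cgauss(300, 1)
  y <- cgauss(300, 1)
  a <- 1.7
  b <- -0.4
  lhs <- bb_matrix(mti_apply(as_baseband_signal(a * x + b * y), f))[, 1]
  rhs <- a * bb_matrix(mti_apply(as_baseband_signal(x), f))[, 1] +
    b * bb_matrix(mti_apply(as_baseband_signal(y), f))[, 1]
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("steady-state phase increments pass through unchanged", {
  # justification for IIR MTI: the nonlinear phase only shifts the constant
  # offset, not the per-sample phase increment
  f <- design_highpass(0.02 * pi)
  omega <- 0.3
  z <- exp(1i * omega * (0:999))
  y <- bb_matrix(mti_apply(as_baseband_signal(z), f))[, 1]
  inc <- diff(phase_sequence(y[500:1000])) # past the transient
  expect_lt(max(abs(inc - omega)), 1e-6)
})

test_that("multi-channel filtering equals per-channel filtering", {
  f <- design_highpass(0.02 * pi)
  sig <- quiet_scene(seed = 8, duration = 10, noise_power = 0.2, n_channels = 3)
  z <- bb_matrix(sig)
  all_at_once <- bb_matrix(mti_apply(sig, f))
  for (ch in 1:3) {
    alone <- bb_matrix(mti_apply(as_baseband_signal(z[, ch]), f))[, 1]
    expect_equal(all_at_once[, ch], alone, tolerance = 1e-12)
  }
  expect_error(mti_apply(sig, f, state = mti_state(2)), "channel")
})

test_that("block-wise filtering with carried state equals one-shot", {
  f <- design_highpass(0.02 * pi)
  sig <- quiet_scene(seed = 9, duration = 120, noise_power = 0.1)
  whole <- mti_apply(sig, f)
  z <- bb_matrix(sig)
  n <- nrow(z)
  first <- mti_apply(as_baseband_signal(z[1:(n / 2), 1]), f)
  second <- mti_apply(as_baseband_signal(z[(n / 2 + 1):n, 1]), f,
                      state = mti_state_of(first))
  expect_equal(c(bb_matrix(first)[, 1], bb_matrix(second)[, 1]),
               bb_matrix(whole)[, 1], tolerance = 1e-12)
})

test_that("5-bit quantization moves the response by less than 0.5 dB", {
  f <- design_highpass(0.02 * pi)
  q <- quantize_coeffs(f, 5)
  omega <- seq(0.01 * pi, pi, length.out = 400)
  expect_lt(max(abs(magnitude_response(f, omega) - magnitude_response(q, omega))),
            0.5)
})
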