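test_that("chest displacement reduces to the standoff without motion", {
  still <- chest_motion(resp_amp = 0, heart_amp = 0, d0 = 0.5)
  expect_equal(chest_displacement(still, c(0, 0.37, 12)), rep(0.5, 3))
  # zero-phase sines start at their zero crossing
  expect_equal(chest_displacement(chest_motion(d0 = 0.5), 0), 0.5)
})

test_that("displacement excursion matches the closed form on a dense grid", {
  motion <- chest_motion(resp_freq = 0.267, resp_amp = 8,
                         heart_freq = 1.383, heart_amp = 0.4)
  t_dense <- seq(0, 60, by = 1e-4)
  d <- chest_displacement(motion, t_dense)
  oracle <- motion$d0 +
    8e-3 * sin(2 * pi * 0.267 * t_dense) + 0.4e-3 * sin(2 * pi * 1.383 * t_dense)
  expect_lt(max(abs(d - oracle)), 1e-15)
  expect_equal(max(d) - min(d), max(oracle) - min(oracle), tolerance = 1e-9)
})

test_that("doppler shift follows 2 v f / c with the sign of v", {
  expect_equal(doppler_shift(0, 2.4e10), 0)
  expect_equal(doppler_shift(0.5, 0), 0)
  expect_equal(doppler_shift(0.1, 24e9, c = 3e8), 16)
  expect_equal(doppler_shift(-0.1, 24e9, c = 3e8), -16)
})

test_that("echo phase is 4 pi x / lambda with period lambda/2", {
  lambda <- 12.5e-3
  expect_equal(echo_phase(lambda / 4, lambda), pi)
  expect_equal(echo_phase(0, lambda), 0)
  expect_equal(echo_phase(0.5e-3, lambda), 4 * pi * 0.5 / 12.5)
  # one displacement period of lambda/2 advances phase by a full turn
  expect_equal(echo_phase(lambda / 2, lambda), 2 * pi)
  expect_error(echo_phase(1e-3, -1), "radar configuration")
})

test_that("noiseless motionless scene is a constant unit phasor", {
  sig <- quiet_scene(motion = chest_motion(resp_amp = 0, heart_amp = 0),
                     duration = 5)
  z <- bb_matrix(sig)[, 1]
  expect_equal(length(z), 100)
  expect_true(all(Mod(z - 1) < 1e-12))
})

test_that("pure phase modulation keeps unit magnitude", {
  z <- bb_matrix(quiet_scene(duration = 30))[, 1]
  expect_lt(max(abs(Mod(z) - 1)), 1e-12)
})

test_that("generation is bitwise reproducible for a fixed seed", {
  a <- synthesize_baseband(radar_params(duration = 10, seed = 77),
                           chest_motion(), interference_params())
  b <- synthesize_baseband(radar_params(duration = 10, seed = 77),
                           chest_motion(), interference_params())
  expect_identical(a$i, b$i)
  expect_identical(a$q, b$q)
  d <- synthesize_baseband(radar_params(duration = 10, seed = 78),
                           chest_motion(), interference_params())
  expect_false(identical(a$i, d$i))
})

test_that("noise-only magnitude-squared samples are exponential with mean sigma2", {
  # cancel the unit target phasor with clutter_amp = -1: samples are pure noise
  sigma2 <- 0.37
  sig <- quiet_scene(seed = 5, duration = 5000, rate = 20,
                     motion = chest_motion(resp_amp = 0, heart_amp = 0),
                     noise_power = sigma2, clutter = -1 + 0i)
  p <- Mod(bb_matrix(sig)[, 1])^2
  n <- length(p)
  expect_equal(n, 1e5)
  se <- sigma2 / sqrt(n) # sd of exponential = mean
  expect_lt(abs(mean(p) - sigma2), 3 * se)
})

test_that("instantaneous frequency of the clean echo matches the Doppler law", {
  motion <- chest_motion()
  radar <- radar_params(slow_sample_rate = 100, duration = 30, seed = 1)
  z <- bb_matrix(synthesize_baseband(
    radar, motion, interference_params(noise_power = 0, clutter_amp = 0,
                                       leakage_amp = 0)))[, 1]
  phi <- phase_sequence(z)
  fs <- 100
  t <- (seq_along(z) - 1) / fs
  inst_freq <- (phi[3:length(phi)] - phi[1:(length(phi) - 2)]) * fs / (4 * pi)
  v <- 2 * pi * motion$resp_freq * motion$resp_amp * 1e-3 *
    cos(2 * pi * motion$resp_freq * t) +
    2 * pi * motion$heart_freq * motion$heart_amp * 1e-3 *
    cos(2 * pi * motion$heart_freq * t)
  expected <- doppler_shift(v, radar$carrier_freq, radar$c)[2:(length(z) - 1)]
  expect_lt(max(abs(inst_freq - expected)), 0.01 * max(abs(expected)))
})

test_that("clean-echo spectral lines sit on the respiration harmonic grid", {
  motion <- chest_motion(resp_freq = 0.25, resp_amp = 4,
                         heart_freq = 1.3, heart_amp = 0.4)
  z <- bb_matrix(quiet_scene(duration = 60, motion = motion))[, 1]
  n <- length(z)
  mag <- Mod(fft(z)) # independent oracle for the spectrum
  freq <- fft_bin_freqs(n, 20)
  mag[1] <- 0 # drop DC
  top <- order(mag, decreasing = TRUE)[1:6]
  # every strong line is a multiple of resp_freq, or a heart sideband
  # m * resp_freq +/- heart_freq, to within one bin
  grid <- c(outer(0:30, c(0), function(m, s) m * 0.25),
            c(outer(0:30, c(-1.3, 1.3), function(m, s) m * 0.25 + s)))
  for (b in top) {
    expect_lt(min(abs(abs(freq[b]) - abs(grid))), 1 / 60 + 1e-9)
  }
})

test_that("Nyquist-violating configurations are rejected", {
  expect_error(
    synthesize_baseband(radar_params(slow_sample_rate = 2),
                        chest_motion(heart_freq = 1.5), interference_params()),
    "twice the highest motion frequency"
  )
})

test_that("I/Q text records round-trip to full precision", {
  sig <- quiet_scene(seed = 3, duration = 5, noise_power = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_iq(sig, path)
  back <- read_iq(path)
  expect_equal(back$i, sig$i, tolerance = 1e-12)
  expect_equal(back$q, sig$q, tolerance = 1e-12)
  expect_equal(bb_sample_rate(back), 20, tolerance = 1e-9)
  expect_identical(attr(back, "provenance"), "loaded")
})
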