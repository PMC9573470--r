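test_that("square-law detection is the sum of squared quadratures", {
  expect_equal(square_law(3 + 4i)$power, 25)
  expect_equal(square_law(0 + 0i)$power, 0)
  set.seed(2)
  z <- cgauss(200, 1)
  alpha <- 2.7
  expect_equal(square_law(alpha * z)$power, alpha^2 * square_law(z)$power,
               tolerance = 1e-12)
  expect_error(square_law(c(1 + 0i, NaN + 0i)), "finite")
})

test_that("Rayleigh and exponential densities are correctly normalized", {
  s2 <- 1.7
  expect_equal(exponential_pdf(0, s2), 1 / s2)
  int_ray <- stats::integrate(rayleigh_pdf, 0, 20 * sqrt(s2), sigma2 = s2,
                              rel.tol = 1e-10)
  int_exp <- stats::integrate(exponential_pdf, 0, 20 * s2, sigma2 = s2,
                              rel.tol = 1e-10)
  expect_equal(int_ray$value, 1, tolerance = 1e-6)
  expect_equal(int_exp$value, 1, tolerance = 1e-6)
  expect_error(rayleigh_pdf(-1, s2), "nonnegative")
  expect_error(exponential_pdf(1, 0), "outside the allowed")
})

test_that("square-law noise power matches the exponential model by Monte Carlo", {
  set.seed(31)
  s2 <- 0.8
  p <- Mod(cgauss(1e5, s2))^2
  expect_lt(abs(mean(p) - s2), 3 * s2 / sqrt(1e5))
})

test_that("threshold is the log-scaled noise power with exact inverse", {
  expect_equal(cfar_threshold(3.2, 1), 0)
  expect_equal(cfar_threshold(1, exp(-4)), 4)
  expect_equal(cfar_threshold(2, 0.01), 9.2103, tolerance = 1e-4)
  s2 <- 1.37
  T <- cfar_threshold(s2, 0.0042)
  expect_equal(exp(-T / s2), 0.0042, tolerance = 1e-12)
  expect_error(cfar_threshold(1, 0), "infinite threshold")
  # monotonicity: decreasing in pfa, increasing in noise power
  pfas <- c(0.2, 0.1, 0.01, 0.001)
  expect_true(all(diff(sapply(pfas, cfar_threshold, noise_power = 1)) > 0))
  expect_true(all(diff(cfar_threshold(c(1, 2, 5), 0.01)) > 0))
})

test_that("training-cell mean reproduces hand-computable cases", {
  cfg <- cfar_config(num_train = 32, num_guard = 2)
  # constant training cells
  expect_equal(estimate_noise(rep(4.2, 100), bin = 60, cfg), 4.2)
  # cells 1..32 lead the test bin beyond two guards: mean 16.5
  spec <- c(1:32, 7, 7, 100, numeric(20))
  expect_equal(estimate_noise(spec, bin = 35, cfg), 16.5)
  # near the left edge the window reflects to the trailing side
  spec2 <- c(100, 7, 7, 1:32, numeric(20))
  expect_equal(estimate_noise(spec2, bin = 1, cfg), 16.5)
  expect_error(estimate_noise(numeric(10), bin = 1, cfg), "below num_train")
})

test_that("estimate variability shrinks as 1/sqrt(M) over exponential noise", {
  set.seed(5)
  cfg <- cfar_config(num_train = 32, num_guard = 2)
  p <- Mod(cgauss(50000, 1))^2
  est <- vitalradar:::cfar_noise_estimates(p, cfg)
  inner <- est[40:49000] # full leading windows only
  expect_equal(stats::sd(inner) / mean(inner), 1 / sqrt(32), tolerance = 0.1)
})

test_that("an all-zero spectrum yields no detections", {
  det <- cfar_detect(numeric(64), cfar_config())
  expect_identical(sum(det$detected), 0L)
})

test_that("known-noise false-alarm rate matches exp(-T/sigma2)", {
  set.seed(17)
  n <- 2e5
  p <- Mod(cgauss(n, 1))^2
  det <- cfar_detect(p, cfar_config(pfa = 0.01), noise_power = 1)
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(mean(det$detected) - 0.01), 3 * se)
})

test_that("plug-in threshold inflates the alarm rate by the finite-M factor", {
  # with an M-cell averaged exponential background the realized rate is
  # (1 + ln(1/pfa)/M)^-M, not pfa itself
  set.seed(23)
  n <- 2e5
  m <- 32
  p <- Mod(cgauss(n, 1))^2
  det <- cfar_detect(p, cfar_config(pfa = 0.01, num_train = m, num_guard = 2))
  expected <- (1 + log(100) / m)^(-m)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(det$detected) - expected), 3 * se)
})

test_that("detection set is invariant to spectrum rescaling", {
  set.seed(41)
  p <- Mod(cgauss(3000, 1))^2
  p[c(300, 1700)] <- p[c(300, 1700)] + 40
  cfg <- cfar_config(pfa = 1e-3)
  base <- cfar_detect(p, cfg)$detected
  for (alpha in c(1e-3, 0.5, 7, 1e4)) {
    expect_identical(cfar_detect(alpha * p, cfg)$detected, base)
  }
  expect_true(base[300] && base[1700])
})

test_that("two-sided averaging uses both flanks", {
  cfg <- cfar_config(num_train = 4, num_guard = 0, sidedness = "two-sided")
  spec <- c(1, 1, 1, 1, 99, 3, 3, 3, 3)
  expect_equal(estimate_noise(spec, bin = 5, cfg), 2)
})

test_that("narrowband noise has Rayleigh amplitude and uniform phase", {
  set.seed(67)
  z <- cgauss(1e5, 2)
  amp <- Mod(z)
  ph <- Arg(z)
  # chi-square goodness of fit on equal-probability bins at the 1% level
  edges <- sqrt(-2 * 1 * log(1 - (0:10) / 10)) # Rayleigh quantiles, sigma2=2
  edges[11] <- Inf
  counts <- table(cut(amp, edges))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  ph_counts <- table(cut(ph, seq(-pi, pi, length.out = 11)))
  expect_gt(stats::chisq.test(as.vector(ph_counts))$p.value, 0.01)
})
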