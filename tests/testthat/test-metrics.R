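test_that("Allan deviation of a constant trace is zero", {
  ac <- allan_deviation(rep(12.5, 600), sample_rate = 3, f0 = 50e6)
  expect_true(all(ac$adev == 0))
  expect_true(all(diff(ac$tau_s) > 0))
  expect_true(all(ac$n_terms >= 1))
})

test_that("an alternating trace matches the two-cycle closed form", {
  delta <- 3
  f0 <- 50e6
  v <- rep(c(delta, -delta), 500)
  ac <- allan_deviation(v, sample_rate = 1, f0 = f0, taus = 1)
  expect_equal(ac$adev, sqrt(2) * delta / f0, tolerance = 1e-12)
})

test_that("the estimator agrees with a brute-force loop", {
  set.seed(33)
  v <- cumsum(rnorm(1000)) + rnorm(1000, sd = 4)
  for (m in c(1, 4, 16, 64)) {
    ac <- allan_deviation(v, sample_rate = 2, f0 = 50e6, taus = m / 2)
    expect_equal(ac$adev, oracle_adev(v, 2, 50e6, m), tolerance = 1e-12)
  }
})

test_that("white frequency noise follows the tau^-1/2 law", {
  slopes <- vapply(1:100, function(seed) {
    set.seed(seed)
    v <- rnorm(8192, sd = 2)
    ac <- allan_deviation(v, sample_rate = 3, f0 = 50e6,
                          taus = c(1, 2, 4, 8, 16) / 3)
    stats::coef(stats::lm(log(adev) ~ log(tau_s), data = ac))[2]
  }, numeric(1))
  expect_equal(mean(slopes), -0.5, tolerance = 0.05)
})

test_that("too-large taus are omitted with a warning", {
  expect_warning(
    ac <- allan_deviation(rnorm(100), sample_rate = 1, f0 = 5e6,
                          taus = c(10, 80)),
    "omitted"
  )
  expect_identical(nrow(ac), 1L)
})

test_that("drift rate recovers an exact ramp and is zero for a constant", {
  t <- (0:(3600 * 3)) / 3
  v <- 200 / 3600 * t # exact 200 Hz rise over one hour at 3 S/s
  expect_equal(drift_rate(v, sample_rate = 3), 200, tolerance = 1e-9)
  expect_equal(drift_rate(rep(3, 100), sample_rate = 3), 0)
})

test_that("drift estimate under noise stays within OLS theory", {
  fails <- vapply(1:50, function(seed) {
    set.seed(seed)
    n <- 3600 * 3
    t <- (seq_len(n) - 1) / 3
    v <- 50 / 3600 * t + rnorm(n)
    se_slope <- 1 / sqrt(sum((t - mean(t))^2)) * 3600
    abs(drift_rate(v, sample_rate = 3) - 50) > 3 * se_slope
  }, logical(1))
  expect_lte(mean(fails), 0.05)
})

test_that("Sauerbrey sensitivity scales quadratically with f0", {
  s50 <- sauerbrey_sensitivity(sensor_spec(f0 = 50e6))
  s100 <- sauerbrey_sensitivity(sensor_spec(f0 = 100e6))
  expect_equal(s100 / s50, 4, tolerance = 1e-12)
  expect_equal(sauerbrey_sensitivity(sensor_spec(f0 = 5e6)), -0.0566,
               tolerance = 5e-3)
  expect_lt(s50, 0)
})

test_that("mass conversion is linear with the documented sign convention", {
  spec <- sensor_spec(f0 = 50e6)
  expect_equal(mass_from_frequency(0, spec), 0)
  expect_gt(mass_from_frequency(-1000, spec), 0)
  expect_equal(mass_from_frequency(-2000, spec),
               2 * mass_from_frequency(-1000, spec))
})

test_that("baseline noise measures fluctuations, not trend", {
  expect_equal(baseline_noise(rep(2, 1000), n_intervals = 10)$sigma, 0)
  ramp <- seq(0, 500, length.out = 10000)
  expect_lt(baseline_noise(ramp, n_intervals = 100)$sigma, 1e-9)
  set.seed(19)
  est <- vapply(1:20, function(i) {
    baseline_noise(rnorm(10000), n_intervals = 100)$sigma
  }, numeric(1))
  expect_equal(mean(est), 1, tolerance = 0.05)
  expect_error(baseline_noise(rnorm(50), n_intervals = 100), "too few")
})

test_that("the detection limit is linear in sigma and inverse in |S|", {
  spec <- sensor_spec(f0 = 50e6)
  expect_equal(idl(0, spec), 0)
  s <- abs(sauerbrey_sensitivity(spec))
  expect_equal(idl(s / 3, spec), 1, tolerance = 1e-12)
  expect_equal(idl(2, spec), 2 * idl(1, spec))
  expect_equal(idl(1, sensor_spec(f0 = 100e6)), idl(1, spec) / 4,
               tolerance = 1e-12)
  expect_equal(idl(1, spec), 3 / s, tolerance = 1e-12)
  expect_error(idl(-1, spec), "sigma")
})

test_that("metric functions accept data frames with tidy columns", {
  sim <- simulate_qcm(duration = 800, seed = 3)
  d1 <- drift_rate(sim, sensor, sample_rate = 3)
  d2 <- drift_rate(sim$sensor, sample_rate = 3)
  expect_identical(d1, d2)
  a1 <- allan_deviation(sim, sensor, sample_rate = 3)
  expect_s3_class(a1, "allan_curve")
})
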