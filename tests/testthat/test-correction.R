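test_that("derivative and integration are exact inverses", {
  expect_equal(derivative(c(1, 3, 6)), c(2, 3))
  expect_equal(derivative(rep(4, 10)), rep(0, 9))
  expect_error(derivative(1), "at least 2")
  expect_equal(integrate_series(c(2, 3), initial = 1), c(1, 3, 6))
  expect_equal(integrate_series(rep(0, 5), initial = 0), rep(0, 6))
  s <- c(3L, -1L, 10L, 4L, 4L, -7L)
  expect_identical(integrate_series(derivative(s), initial = s[1]),
                   as.numeric(s))
  set.seed(12)
  for (i in 1:20) {
    z <- rnorm(100)
    expect_equal(derivative(integrate_series(z, initial = rnorm(1))), z,
                 tolerance = 1e-12)
  }
})

test_that("windowed correlation recognises perfect and inverted copies", {
  set.seed(3)
  xd <- rnorm(300)
  tr <- windowed_correlation(xd, xd, window = 32)
  expect_true(all(tr$defined))
  expect_true(all(tr$r == 1))
  expect_true(all(tr$p < 1e-10))
  tr2 <- windowed_correlation(xd, -xd, window = 32)
  expect_true(all(tr2$r == -1))
  expect_true(all(tr2$n_window >= 8) && all(tr2$n_window <= 32))
})

test_that("zero-variance windows are flagged undefined, not numeric", {
  xd <- rnorm(100)
  tr <- windowed_correlation(xd, rep(2, 100), window = 16)
  expect_true(all(!tr$defined))
  expect_true(all(is.na(tr$r)))
  expect_error(windowed_correlation(rnorm(10), rnorm(9)), "equal length")
})

test_that("the correlation test is calibrated under the null", {
  set.seed(2024)
  n_windows <- 1000
  w <- 32
  xd <- rnorm(n_windows * w)
  yd <- rnorm(n_windows * w)
  tr <- windowed_correlation(xd, yd, window = w)
  # stride-w subsample: effectively independent windows
  idx <- seq(w, n_windows * w - w, by = w)
  fp <- mean(tr$p[idx] < 0.05)
  expect_gte(fp, 0.03)
  expect_lte(fp, 0.07)
})

test_that("projection annihilates an exact linear relation", {
  set.seed(8)
  yd <- rnorm(200)
  xd <- 2 + 3 * yd
  tr <- windowed_correlation(xd, yd, window = 32)
  zd <- project_and_cancel(xd, yd, tr, alpha = 0.05)
  proj <- attr(zd, "projection")
  expect_true(any(proj))
  expect_lt(max(abs(zd[proj])), 1e-9 * max(abs(xd)))
})

test_that("an all-zero reference falls back to plain subtraction", {
  set.seed(4)
  xd <- rnorm(64)
  yd <- rep(0, 64)
  tr <- windowed_correlation(xd, yd, window = 16)
  zd <- project_and_cancel(xd, yd, tr)
  expect_equal(as.numeric(zd), xd)
  expect_false(any(attr(zd, "projection")))
})

test_that("projection beats direct subtraction under a gain-mismatched
           random walk", {
  wins <- vapply(1:100, function(seed) {
    set.seed(seed)
    n <- 300
    cd <- rnorm(n)          # derivative of a common random walk
    sd_ <- rnorm(n, sd = 0.1) # derivative of the small independent signal
    xd <- sd_ + 1.3 * cd
    yd <- cd
    tr <- windowed_correlation(xd, yd, window = 32)
    zd <- project_and_cancel(xd, yd, tr, alpha = 0.05)
    mse_proj <- mean((zd - sd_)^2)
    mse_naive <- mean(((xd - yd) - sd_)^2)
    mse_proj < mse_naive
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("a zero reference leaves exactly the shrinkage-denoised sensor", {
  set.seed(77)
  x <- sin((1:2048) / 40) * 50 + rnorm(2048, sd = 2)
  p <- paired_record(x, numeric(2048), sample_rate = 3)
  z <- correct_pair(p)
  denoised <- idwt_reconstruct(hard_threshold(dwt_decompose(x)))
  expect_equal(z$values, denoised, tolerance = 1e-9)
})

test_that("an identical pair is corrected to a constant", {
  set.seed(2)
  x <- sin(2 * pi * (0:2047) / 900) + 0.3 * cos(2 * pi * (0:2047) / 270) +
    rnorm(2048, sd = 0.05)
  p <- paired_record(x, x, sample_rate = 3)
  z <- correct_pair(p)
  expect_lt(max(abs(z$values - z$values[1])), 1e-6)
})

test_that("output metadata mirrors the sensor input", {
  sim <- simulate_pair(sim_config(duration = 600, seed = 31,
                                  channel = "dissipation",
                                  binding_steps = list(
                                    list(start = 100, amplitude = -50,
                                         time_constant = 60,
                                         d_amplitude = 8))))
  z <- correct_pair(sim$pair, correction_params(levels = 3))
  expect_identical(length(z$values), length(sim$pair$sensor$values))
  expect_identical(z$sample_rate, sim$pair$sensor$sample_rate)
  expect_identical(z$channel, "dissipation")
  diag <- attr(z, "diagnostics")
  expect_identical(diag$series, c("A", "D1", "D2", "D3"))
})

test_that("a common smooth disturbance added to both channels barely moves
           the output", {
  # temperature-timescale wander: a 300 Hz slow oscillation, ten-minute period
  base <- simulate_pair(quiescent_config(seed = 21, drift_rate = 0,
                                         duration = 1200))
  t <- (seq_len(length(base$pair$sensor$values)) - 1) / 3
  disturb <- 300 * sin(2 * pi * t / 600)
  z0 <- correct_pair(base$pair)
  shifted <- paired_record(base$pair$sensor$values + disturb,
                           base$pair$reference$values + disturb,
                           sample_rate = 3)
  z1 <- correct_pair(shifted)
  change <- sqrt(mean((z1$values - z0$values)^2))
  expect_lt(change, 0.05 * sqrt(mean(disturb^2)))
})

test_that("binding amplitude is recovered across reference gains", {
  for (g in c(0.5, 1.2, 2)) {
    errs <- vapply(1:5, function(seed) {
      sim <- simulate_pair(harsh_config(seed = seed, gain = g))
      z <- correct_pair(sim$pair)
      abs(mean(utils::tail(z$values, 300)) - (-3681))
    }, numeric(1))
    expect_lt(stats::median(errs), 0.05 * 3681)
  }
})

test_that("the plateau survives a gain-mismatched common ramp", {
  cfg <- sim_config(duration = 7200, sample_rate = 3, drift_rate = 200,
                    temperature = NULL, sawtooth = NULL,
                    binding_steps = list(list(start = 600, amplitude = -3681,
                                              time_constant = 300)),
                    gain_mismatch = 1.2, seed = 23)
  sim <- simulate_pair(cfg)
  z <- correct_pair(sim$pair)
  plateau <- mean(utils::tail(z$values, 300))
  expect_lt(abs(plateau - (-3681)), 0.05 * 3681)
})
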