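test_that("round trip reconstructs the signal to floating-point accuracy", {
  set.seed(101)
  for (mode in c("symmetric", "periodic")) {
    for (wv in c("db2", "db3", "db4")) {
      for (n in c(48, 64, 100, 137, 1000)) {
        x <- cumsum(rnorm(n)) + 10 * sin(seq_len(n) / 17)
        lv <- min(4L, floor(log2(n / (wavelet_filter(wv)$length - 1))))
        co <- dwt_decompose(x, wavelet = wv, levels = lv,
                            extension_mode = mode)
        err <- max(abs(idwt_reconstruct(co) - x)) / max(abs(x))
        expect_lt(err, 1e-9)
      }
    }
  }
})

test_that("detail bands annihilate a constant trace", {
  co <- dwt_decompose(rep(7.5, 96), wavelet = "db3", levels = 3)
  for (d in co$details) expect_lt(max(abs(d)), 1e-10 * 7.5)
  expect_gt(max(abs(co$approximation)), 1)
})

test_that("signals too short for the requested depth are refused by name", {
  expect_error(dwt_decompose(rnorm(20), levels = 4, wavelet = "db3"),
               "at least 80 samples")
})

test_that("periodised db3 coefficients match a direct convolution-decimation
           oracle and conserve energy", {
  set.seed(64)
  x <- rnorm(64)
  co <- dwt_decompose(x, wavelet = "db3", levels = 3,
                      extension_mode = "periodic")
  or <- oracle_dwt(x, "db3", 3)
  expect_equal(co$approximation, or$approximation, tolerance = 1e-12)
  for (lev in 1:3) {
    expect_equal(co$details[[lev]], or$details[[lev]], tolerance = 1e-12)
  }
  energy <- sum(co$approximation^2) + sum(unlist(co$details)^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-6)
})

test_that("reconstruction is linear across bands", {
  set.seed(5)
  x <- cumsum(rnorm(128))
  co <- dwt_decompose(x, levels = 3)
  no_d1 <- co
  no_d1$details$D1 <- 0 * no_d1$details$D1
  only_d1 <- co
  only_d1$approximation <- 0 * only_d1$approximation
  only_d1$details$D2 <- 0 * only_d1$details$D2
  only_d1$details$D3 <- 0 * only_d1$details$D3
  expect_equal(idwt_reconstruct(no_d1) + idwt_reconstruct(only_d1), x,
               tolerance = 1e-10)
  zero <- co
  zero$approximation <- 0 * zero$approximation
  zero$details <- lapply(zero$details, function(d) 0 * d)
  expect_equal(idwt_reconstruct(zero), rep(0, 128))
})

test_that("inconsistent coefficient lengths are rejected", {
  co <- dwt_decompose(rnorm(128), levels = 3)
  co$details$D2 <- co$details$D2[-1]
  expect_error(idwt_reconstruct(co), "inconsistent")
})

test_that("hard thresholding implements the hard rule exactly", {
  co <- dwt_decompose(rnorm(96), levels = 1)
  co$details$D1 <- c(5, -0.1, 0.2, -6, rep(0, length(co$details$D1) - 4))
  th <- hard_threshold(co, lambda = 1)
  expect_equal(th$details$D1[1:4], c(5, 0, 0, -6))
  # lambda = 0 is the identity
  expect_equal(hard_threshold(co, lambda = 0)$details$D1, co$details$D1)
  # idempotent at fixed lambda; survivors keep sign and magnitude
  expect_equal(hard_threshold(th, lambda = 1), th, ignore_attr = TRUE)
  kept <- th$details$D1[th$details$D1 != 0]
  expect_true(all(kept %in% co$details$D1))
  # approximation passes through untouched
  expect_equal(th$approximation, co$approximation)
})

test_that("the universal rule silences almost all white-noise detail
           coefficients", {
  zeroed <- vapply(1:100, function(seed) {
    set.seed(seed)
    co <- dwt_decompose(rnorm(512), levels = 2)
    th <- hard_threshold(co, rule = "universal")
    mean(th$details$D1 == 0)
  }, numeric(1))
  expect_gte(mean(zeroed), 0.90)
})

test_that("the energy rule removes at most the requested energy fraction", {
  set.seed(9)
  co <- dwt_decompose(cumsum(rnorm(256)), levels = 2)
  th <- hard_threshold(co, rule = "energy", energy_fraction = 0.01)
  for (lev in 1:2) {
    removed <- sum(co$details[[lev]]^2) - sum(th$details[[lev]]^2)
    expect_lte(removed, 0.01 * sum(co$details[[lev]]^2) + 1e-12)
  }
})
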