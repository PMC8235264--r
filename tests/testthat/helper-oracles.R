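# Independent oracles and fixture builders used across the suite.

# Naive single-level periodised convolution-decimation: direct double loop,
# no shared code with the package's filter-bank implementation.
oracle_dwt_level <- function(x, dec_lo, dec_hi) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  m <- length(x)
  L <- length(dec_lo)
  half <- m %/% 2L
  cA <- numeric(half)
  cD <- numeric(half)
  for (i in seq_len(half)) {
    for (j in seq_len(L)) {
      src <- ((2L * (i - 1L) + L %/% 2L - (j - 1L)) %% m) + 1L
      cA[i] <- cA[i] + dec_lo[j] * x[src]
      cD[i] <- cD[i] + dec_hi[j] * x[src]
    }
  }
  list(cA = cA, cD = cD)
}

oracle_dwt <- function(x, wavelet, levels) {
  f <- wavelet_filter(wavelet)
  details <- vector("list", levels)
  cur <- x
  for (lev in seq_len(levels)) {
    st <- oracle_dwt_level(cur, f$dec_lo, f$dec_hi)
    details[[lev]] <- st$cD
    cur <- st$cA
  }
  list(approximation = cur, details = details)
}

# Brute-force non-overlapping Allan deviation: explicit loop over bins.
oracle_adev <- function(values, sample_rate, f0, m) {
  y <- values / f0
  nb <- length(y) %/% m
  ybar <- vapply(seq_len(nb), function(k) {
    mean(y[((k - 1L) * m + 1L):(k * m)])
  }, numeric(1))
  d <- ybar[-1] - ybar[-nb]
  sqrt(0.5 * mean(d^2))
}

# Quiescent one-hour baseline run: common linear drift with a gain-mismatched
# reference plus independent white noise (the drift-suppression benchmark
# conditions).
quiescent_config <- function(seed, duration = 3600, drift_rate = 200,
                             gain = 1.2, noise = 2) {
  sim_config(duration = duration, sample_rate = 3, drift_rate = drift_rate,
             noise_sd_sensor = noise, noise_sd_reference = noise,
             temperature = NULL, sawtooth = NULL, binding_steps = list(),
             gain_mismatch = gain, seed = seed)
}

# Harsh-environment adsorption run: one saturating binding step on the sensor
# plus a temperature excursion and sawtooth interference common to both
# channels with unequal gain.
harsh_config <- function(seed, amplitude = -3681, gain = 1.2) {
  sim_config(duration = 7200, sample_rate = 3,
             binding_steps = list(list(start = 600, amplitude = amplitude,
                                       time_constant = 300)),
             gain_mismatch = gain, seed = seed)
}
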