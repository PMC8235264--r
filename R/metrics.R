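# Stability and sensitivity metrics: Allan deviation, baseline drift rate,
# baseline noise, Sauerbrey sensitivity / mass conversion, and the
# instrument detection limit.

.metric_values <- function(data, value) {
  if (is.numeric(data)) return(as.numeric(data))
  if (inherits(data, "resonator_trace")) return(data$values)
  if (is.data.frame(data)) {
    col <- rlang::enquo(value)
    if (rlang::quo_is_missing(col)) {
      stop("supply the `value` column when passing a data frame.",
           call. = FALSE)
    }
    return(dplyr::pull(data, !!col))
  }
  stop("unsupported input type.", call. = FALSE)
}

.metric_rate <- function(data, sample_rate) {
  if (inherits(data, "resonator_trace")) return(data$sample_rate)
  if (is.null(sample_rate)) {
    stop("`sample_rate` is required.", call. = FALSE)
  }
  sample_rate
}

#' Allan deviation of a frequency-shift trace
#'
#' The two-sample (Allan) deviation of bin-averaged fractional frequency,
#' the standard stability metric for resonators and oscillators:
#' `sigma_y(tau) = sqrt(0.5 * mean((ybar[k + 1] - ybar[k])^2))`, where
#' `ybar[k]` are means of `y = values / f0` over adjacent non-overlapping
#' bins of length `tau`. Lower curves mean a more stable resonator; the
#' log-log slope identifies the dominant noise type (white frequency noise
#' falls as `tau^-0.5`, drift rises as `tau`).
#'
#' The non-overlapping estimator matching the adjacent-average definition is
#' the default; set `overlapping = TRUE` for the smoother overlapping
#' estimator.
#'
#' @param data A data frame (with `value` naming the frequency-shift column),
#'   a numeric vector of frequency shifts (Hz), or a `resonator_trace`.
#' @param value Column containing the frequency shift when `data` is a data
#'   frame (tidy evaluation).
#' @param sample_rate Samples per second (taken from the trace if `data` is a
#'   `resonator_trace`).
#' @param f0 Fundamental resonance frequency in Hz used to form fractional
#'   frequency, or a [sensor_spec()].
#' @param taus Integration times in seconds (each a multiple of the sample
#'   interval). Default: octave-spaced from one sample interval up while at
#'   least two bin pairs remain. Requested values too large for the trace are
#'   dropped with a warning.
#' @param overlapping Use the overlapping estimator instead.
#' @return A tibble of class `allan_curve` with columns `tau_s`, `adev`
#'   (dimensionless fractional frequency) and `n_terms` (number of averaged
#'   squared differences per point).
#' @examples
#' adev <- allan_deviation(rnorm(3000, sd = 2), sample_rate = 3, f0 = 50e6)
#' @export
allan_deviation <- function(data, value, sample_rate = NULL, f0 = 50e6,
                            taus = NULL, overlapping = FALSE) {
  v <- .metric_values(data, {{ value }})
  fs <- .metric_rate(data, sample_rate)
  if (inherits(f0, "sensor_spec")) f0 <- f0$f0
  n <- length(v)
  if (is.null(taus)) {
    ms <- 2L^(0:floor(log2(max(1, n / 4))))
    ms <- ms[2L * ms <= n]
  } else {
    m_real <- taus * fs
    ms <- as.integer(round(m_real))
    if (any(abs(m_real - ms) > 1e-6 * pmax(1, m_real))) {
      stop("every `tau` must be a multiple of the sample interval.",
           call. = FALSE)
    }
    drop <- 2L * ms > n
    if (any(drop)) {
      warning(sum(drop), " tau value(s) too large for the trace were ",
              "omitted.", call. = FALSE)
      ms <- ms[!drop]
    }
  }
  if (any(ms < 1L)) stop("`tau` must be at least one sample interval.",
                         call. = FALSE)
  # centring leaves the deviation unchanged but avoids accumulation error
  y <- v / f0
  y <- y - mean(y)
  cy <- c(0, cumsum(y))
  rows <- lapply(ms, function(m) {
    if (overlapping) {
      starts <- seq_len(n - 2L * m + 1L)
      ybar1 <- (cy[starts + m] - cy[starts]) / m
      ybar2 <- (cy[starts + 2L * m] - cy[starts + m]) / m
      d <- ybar2 - ybar1
    } else {
      nb <- n %/% m
      starts <- (seq_len(nb) - 1L) * m + 1L
      ybar <- (cy[starts + m] - cy[starts]) / m
      d <- diff(ybar)
    }
    c(tau_s = m / fs, adev = sqrt(0.5 * mean(d^2)), n_terms = length(d))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$n_terms <- as.integer(out$n_terms)
  class(out) <- c("allan_curve", class(out))
  out
}

#' Baseline drift rate in Hz per hour
#'
#' Slope of the ordinary least-squares line of signal value versus time,
#' scaled to one hour. OLS is used instead of an endpoint difference because
#' it is robust to noise and matches the usual Hz/h reporting convention.
#'
#' @inheritParams allan_deviation
#' @return The signed drift rate, Hz/h (or 1e-6/h for dissipation traces).
#' @examples
#' drift_rate(seq(0, 200, length.out = 10800), sample_rate = 3)
#' @export
drift_rate <- function(data, value, sample_rate = NULL) {
  v <- .metric_values(data, {{ value }})
  fs <- .metric_rate(data, sample_rate)
  if (length(v) < 2L) stop("need at least 2 samples.", call. = FALSE)
  t <- (seq_along(v) - 1) / fs
  tc <- t - mean(t)
  slope <- sum(tc * (v - mean(v))) / sum(tc^2)
  slope * 3600
}

#' Sauerbrey mass sensitivity of a quartz resonator
#'
#' `S = -2 * f0^2 / sqrt(rho_q * eta_q)`, expressed in Hz cm^2/ng. The
#' quadratic dependence on `f0` is why high-fundamental-frequency resonators
#' (tens of MHz) reach far lower detection limits than the classic 5 MHz
#' crystals. Negative by convention: adsorbed mass lowers the resonance
#' frequency.
#'
#' @param spec A [sensor_spec()].
#' @return Sensitivity in Hz cm^2/ng.
#' @examples
#' sauerbrey_sensitivity(sensor_spec(f0 = 50e6))
#' @export
sauerbrey_sensitivity <- function(spec = sensor_spec()) {
  stopifnot(inherits(spec, "sensor_spec"))
  # SI value is Hz m^2/kg; 1 Hz m^2/kg = 1e-8 Hz cm^2/ng
  -2 * spec$f0^2 / sqrt(spec$rho_q * spec$eta_q) * 1e-8
}

#' Convert a frequency shift to areal mass density
#'
#' Applies the Sauerbrey relation `delta_m = delta_f / S` (gravimetric
#' regime: the adsorbed film is assumed rigid, thin and uniformly coupled,
#' so the frequency shift is proportional to areal mass). A negative
#' frequency shift maps to a positive adsorbed mass.
#'
#' @param delta_f Frequency shift(s) in Hz.
#' @param spec A [sensor_spec()].
#' @return Areal mass density in ng/cm^2.
#' @examples
#' mass_from_frequency(-3681, sensor_spec(f0 = 50e6))
#' @export
mass_from_frequency <- function(delta_f, spec = sensor_spec()) {
  delta_f / sauerbrey_sensitivity(spec)
}

#' Baseline noise from interval-wise detrended standard deviations
#'
#' Splits the trace into `n_intervals` equal contiguous segments, removes a
#' least-squares line from each segment, and reports the mean of the
#' per-segment residual standard deviations together with their spread.
#' The per-interval detrending makes `sigma` measure noise rather than
#' drift; detection limits computed from it therefore quantify the
#' fluctuation floor, not baseline wander.
#'
#' @inheritParams allan_deviation
#' @param n_intervals Number of segments (default 100).
#' @return A one-row tibble with `sigma` (mean per-interval residual SD, in
#'   the trace's units), `sigma_spread` (SD across intervals, for error
#'   bars), `n_intervals` and `samples_per_interval`.
#' @examples
#' baseline_noise(rnorm(10000), n_intervals = 100)
#' @export
baseline_noise <- function(data, value, n_intervals = 100L) {
  v <- .metric_values(data, {{ value }})
  n_intervals <- as.integer(n_intervals)
  k <- length(v) %/% n_intervals
  if (k < 3L) {
    stop("too few samples: need at least 3 per interval (",
         3L * n_intervals, " total), got ", length(v), ".", call. = FALSE)
  }
  seg <- matrix(v[seq_len(k * n_intervals)], nrow = k)
  t <- seq_len(k)
  tc <- t - mean(t)
  stt <- sum(tc^2)
  means <- colMeans(seg)
  slopes <- as.numeric(crossprod(tc, seg)) / stt
  resid <- seg - rep(means, each = k) - outer(tc, slopes)
  sds <- sqrt(colSums(resid^2) / (k - 2L))
  tibble::tibble(sigma = mean(sds), sigma_spread = stats::sd(sds),
                 n_intervals = n_intervals, samples_per_interval = k)
}

#' Instrument detection limit
#'
#' `IDL = 3 * sigma / |S|`: the smallest areal mass density distinguishable
#' from the baseline fluctuations, given the system noise `sigma` (Hz) and
#' the Sauerbrey sensitivity `S` (Hz cm^2/ng). Linear in `sigma` and
#' inversely proportional to `|S|`.
#'
#' @param sigma Baseline noise in Hz (e.g. from [baseline_noise()]).
#' @param spec A [sensor_spec()].
#' @return Detection limit in ng/cm^2.
#' @examples
#' idl(1, sensor_spec(f0 = 50e6))
#' @export
idl <- function(sigma, spec = sensor_spec()) {
  if (any(sigma < 0)) stop("`sigma` must be >= 0.", call. = FALSE)
  3 * sigma / abs(sauerbrey_sensitivity(spec))
}
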