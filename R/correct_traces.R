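# Data-frame-first interface and broom-style methods for the correction.

#' Correct a sensor trace against its reference (data-frame interface)
#'
#' Pipe-friendly front end to the correction methods: takes a tibble of
#' paired traces (one row per sample), applies the selected method and
#' returns a fitted-object wrapper whose [tidy()] method gives the
#' per-sample result and whose [glance()] method summarises stability
#' metrics of the corrected trace.
#'
#' Methods: `"dwt"` is the dual-resonator wavelet correction
#' ([correct_pair()]); `"mecea"` is filtered direct subtraction
#' ([mecea_filtered()]); `"raw"` passes the sensor through unchanged
#' ([raw_passthrough()]), the no-correction benchmark arm.
#'
#' @param data A data frame with one row per sample.
#' @param sensor,reference Trace columns (tidy evaluation).
#' @param time Time column in seconds; used to infer the sample rate.
#' @param method `"dwt"`, `"mecea"` or `"raw"`.
#' @param params A [correction_params()] for `method = "dwt"`.
#' @param mecea_window Averaging window for `method = "mecea"`.
#' @param sample_rate,channel Optional overrides, see [as_paired_record()].
#' @return An object of class `qcm_correction`.
#' @examples
#' sim <- simulate_qcm(duration = 1200, seed = 1)
#' fit <- correct_traces(sim, sensor, reference,
#'                       params = correction_params(levels = 3))
#' glance(fit)
#' @export
correct_traces <- function(data, sensor, reference, time = time_s,
                           method = c("dwt", "mecea", "raw"),
                           params = correction_params(), mecea_window = 16L,
                           sample_rate = NULL, channel = NULL) {
  method <- match.arg(method)
  pr <- as_paired_record(data, {{ sensor }}, {{ reference }}, {{ time }},
                         sample_rate = sample_rate, channel = channel)
  corrected <- switch(method,
    dwt = correct_pair(pr, params),
    mecea = mecea_filtered(pr, window = mecea_window),
    raw = raw_passthrough(pr)
  )
  n <- length(pr$sensor$values)
  res <- tibble::tibble(
    time_s = (seq_len(n) - 1) / pr$sensor$sample_rate,
    sensor = pr$sensor$values,
    reference = pr$reference$values,
    corrected = corrected$values
  )
  structure(
    list(data = res, method = method,
         params = if (method == "dwt") params else NULL,
         mecea_window = if (method == "mecea") mecea_window else NULL,
         diagnostics = attr(corrected, "diagnostics"),
         sample_rate = pr$sensor$sample_rate, channel = pr$sensor$channel),
    class = "qcm_correction"
  )
}

#' @export
print.qcm_correction <- function(x, ...) {
  cat(sprintf("<qcm_correction: method '%s', %s channel, %d samples @ %g S/s>\n",
              x$method, x$channel, nrow(x$data), x$sample_rate))
  if (!is.null(x$diagnostics)) {
    pf <- stats::weighted.mean(x$diagnostics$projection_fraction,
                               x$diagnostics$n_coefficients, na.rm = TRUE)
    cat(sprintf("  projection branch used at %.1f%% of coefficient indices\n",
                100 * pf))
  }
  invisible(x)
}

#' Tidy a corrected pair
#'
#' @param x A `qcm_correction`.
#' @param ... Unused.
#' @return A tibble with one row per sample: `time_s`, `sensor`, `reference`,
#'   `corrected`.
#' @exportS3Method generics::tidy
tidy.qcm_correction <- function(x, ...) {
  x$data
}

#' One-row summary of a corrected pair
#'
#' Reports the standard stability quantities of the corrected trace: OLS
#' baseline drift (per hour), interval-detrended baseline noise, the
#' detection limit implied by that noise, and (for the wavelet method) the
#' overall fraction of projection-branch decisions.
#'
#' @param x A `qcm_correction`.
#' @param spec A [sensor_spec()] used for the detection limit.
#' @param n_intervals Intervals for [baseline_noise()]; reduced automatically
#'   for short traces.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.qcm_correction <- function(x, spec = sensor_spec(),
                                  n_intervals = 100L, ...) {
  v <- x$data$corrected
  n_intervals <- max(2L, min(n_intervals, length(v) %/% 3L))
  bn <- baseline_noise(v, n_intervals = n_intervals)
  pf <- if (is.null(x$diagnostics)) NA_real_ else
    stats::weighted.mean(x$diagnostics$projection_fraction,
                         x$diagnostics$n_coefficients, na.rm = TRUE)
  tibble::tibble(
    method = x$method,
    n = nrow(x$data),
    duration_s = nrow(x$data) / x$sample_rate,
    drift_per_h = drift_rate(v, sample_rate = x$sample_rate),
    sigma = bn$sigma,
    idl_ng_cm2 = if (x$channel == "frequency") idl(bn$sigma, spec) else
      NA_real_,
    projection_fraction = pf
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
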