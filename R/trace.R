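#' Construct a resonator trace
#'
#' A resonator trace is one uniformly sampled signal recorded at a single
#' resonator of a (M)QCM device: either a resonance-frequency shift in Hz or
#' a dissipation shift in units of 1e-6. It is the elementary container that
#' all correction and metric functions operate on.
#'
#' @param values Numeric vector of samples. Must be finite and non-empty.
#' @param sample_rate Sampling rate in samples per second (> 0). Typical
#'   multi-channel QCM-D instruments acquire around 3 samples/s per sensor.
#' @param channel `"frequency"` (Hz) or `"dissipation"` (units of 1e-6).
#' @param label Free-text label, e.g. the instrument channel name.
#'
#' @return An object of class `resonator_trace`: a list with elements
#'   `values`, `sample_rate`, `channel` and `label`.
#' @examples
#' tr <- resonator_trace(rnorm(100), sample_rate = 3)
#' length(tr$values)
#' @export
resonator_trace <- function(values, sample_rate,
                            channel = c("frequency", "dissipation"),
                            label = "") {
  channel <- match.arg(channel)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("`values` must contain at least one sample.", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop("`values` must be finite; first non-finite sample at index ", bad,
         ".", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(values = values, sample_rate = as.numeric(sample_rate),
         channel = channel, label = as.character(label)),
    class = "resonator_trace"
  )
}

#' @export
print.resonator_trace <- function(x, ...) {
  cat(sprintf("<resonator_trace: %s%s, %d samples @ %g S/s>\n",
              x$channel,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$values), x$sample_rate))
  invisible(x)
}

#' Pair a sensor trace with its reference trace
#'
#' The correction algorithm works on pairs of co-located resonators: the
#' *sensor* is exposed to the sample while the *reference* is kept isolated
#' from it, so that disturbances common to both (temperature, pressure, flow,
#' mechanical stress) can be identified and cancelled. Pairing in an array is
#' by explicit user mapping; no automatic nearest-neighbour inference is
#' performed.
#'
#' @param sensor,reference `resonator_trace` objects (or numeric vectors,
#'   which are promoted with `sample_rate`).
#' @param sample_rate Used only when `sensor`/`reference` are bare numeric
#'   vectors.
#' @param channel Used only when promoting bare numeric vectors.
#'
#' @return An object of class `paired_record` with elements `sensor` and
#'   `reference`. Construction fails if lengths, sample rates or channel
#'   kinds differ.
#' @examples
#' p <- paired_record(rnorm(64), rnorm(64), sample_rate = 3)
#' @export
paired_record <- function(sensor, reference, sample_rate = NULL,
                          channel = "frequency") {
  if (is.numeric(sensor)) {
    if (is.null(sample_rate)) {
      stop("`sample_rate` is required when passing bare numeric vectors.",
           call. = FALSE)
    }
    sensor <- resonator_trace(sensor, sample_rate, channel, "sensor")
  }
  if (is.numeric(reference)) {
    if (is.null(sample_rate)) {
      stop("`sample_rate` is required when passing bare numeric vectors.",
           call. = FALSE)
    }
    reference <- resonator_trace(reference, sample_rate, channel, "reference")
  }
  stopifnot(inherits(sensor, "resonator_trace"),
            inherits(reference, "resonator_trace"))
  if (length(sensor$values) != length(reference$values)) {
    stop("sensor and reference traces must have equal length (",
         length(sensor$values), " vs ", length(reference$values), ").",
         call. = FALSE)
  }
  if (sensor$sample_rate != reference$sample_rate) {
    stop("sensor and reference traces must share one sample rate.",
         call. = FALSE)
  }
  if (sensor$channel != reference$channel) {
    stop("sensor and reference traces must be the same channel kind.",
         call. = FALSE)
  }
  structure(list(sensor = sensor, reference = reference),
            class = "paired_record")
}

#' @export
print.paired_record <- function(x, ...) {
  cat(sprintf("<paired_record: %s, %d samples @ %g S/s>\n",
              x$sensor$channel, length(x$sensor$values),
              x$sensor$sample_rate))
  invisible(x)
}

#' Physical constants of an AT-cut quartz resonator
#'
#' Holds the parameters entering the Sauerbrey mass-sensitivity relation
#' `S = -2 f0^2 / sqrt(rho_q * eta_q)`. Defaults are the standard AT-cut
#' quartz constants; both are overridable for non-standard cuts.
#'
#' @param f0 Fundamental resonance frequency in Hz (default 50 MHz, a
#'   high-fundamental-frequency miniaturised resonator).
#' @param rho_q Quartz density in kg/m^3 (default 2648).
#' @param eta_q AT-cut quartz shear modulus in Pa (default 2.947e10).
#'
#' @return An object of class `sensor_spec`.
#' @examples
#' sauerbrey_sensitivity(sensor_spec(f0 = 50e6))
#' @export
sensor_spec <- function(f0 = 50e6, rho_q = 2648, eta_q = 2.947e10) {
  for (nm in c("f0", "rho_q", "eta_q")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number.", call. = FALSE)
    }
  }
  structure(list(f0 = f0, rho_q = rho_q, eta_q = eta_q),
            class = "sensor_spec")
}

#' Parameters of the dual-resonator wavelet correction
#'
#' @param wavelet Daubechies wavelet identifier, `"db1"` to `"db6"`. The
#'   default `"db3"` (three vanishing moments) annihilates locally quadratic
#'   baselines in the detail bands.
#' @param levels Number of decomposition levels `q` (default 4).
#' @param window Sliding-window length `w`, in coefficient-index samples,
#'   used for the Pearson correlation and the linear projection fit
#'   (default 32; must be at least 8 so that `w - 2` degrees of freedom are
#'   meaningful). The window lives in coefficient index space because the
#'   correlation and fit operate on the decimated coefficient series.
#' @param alpha Significance level for the correlation test (default 0.05):
#'   indices with `P(n) < alpha` use the projection branch.
#' @param threshold_rule `"universal"` (per-level MAD-based universal
#'   threshold, the default) or `"energy"` (zero the smallest detail
#'   coefficients carrying at most `energy_fraction` of the level's energy).
#' @param extension_mode Boundary extension of the filter bank:
#'   `"symmetric"` (half-point reflection, default; minimises edge artifacts
#'   on drifting baselines) or `"periodic"` (orthonormal periodised
#'   transform).
#' @param energy_fraction Energy fraction for the `"energy"` rule
#'   (default 0.01).
#' @param min_window Smallest edge-truncated window still used for the
#'   correlation test (default 8); shorter windows fall back to direct
#'   subtraction.
#' @param lambda Optional fixed hard threshold(s), one value or one per
#'   detail level (finest first), overriding `threshold_rule`. Freezing the
#'   threshold (e.g. from a calibration segment) makes block-wise streaming
#'   output numerically consistent with batch processing; the data-driven
#'   rules re-estimate it from whatever data they see.
#'
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(wavelet = "db3", levels = 4L, window = 32L,
                              alpha = 0.05,
                              threshold_rule = c("universal", "energy"),
                              extension_mode = c("symmetric", "periodic"),
                              energy_fraction = 0.01, min_window = 8L,
                              lambda = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  extension_mode <- match.arg(extension_mode)
  levels <- as.integer(levels)
  window <- as.integer(window)
  min_window <- as.integer(min_window)
  if (levels < 1L) stop("`levels` must be >= 1.", call. = FALSE)
  if (window < 8L) stop("`window` must be >= 8.", call. = FALSE)
  if (min_window < 3L) stop("`min_window` must be >= 3.", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (!is.numeric(energy_fraction) || energy_fraction < 0 ||
      energy_fraction >= 1) {
    stop("`energy_fraction` must lie in [0, 1).", call. = FALSE)
  }
  if (!is.null(lambda) && (!is.numeric(lambda) || any(lambda < 0))) {
    stop("`lambda` must be non-negative.", call. = FALSE)
  }
  wavelet_filter(wavelet) # validates the identifier
  structure(
    list(wavelet = wavelet, levels = levels, window = window, alpha = alpha,
         threshold_rule = threshold_rule, extension_mode = extension_mode,
         energy_fraction = energy_fraction, min_window = min_window,
         lambda = lambda),
    class = "correction_params"
  )
}
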