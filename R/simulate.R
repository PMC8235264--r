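# Synthetic paired-signal generator. Emulates a two-resonator QCM-D
# acquisition under a harsh environment: a common temperature excursion and
# flow-rate (sawtooth) interference felt by both resonators with unequal
# gain, independent white electronic noise on each channel, and a saturating
# protein-binding transient present only on the sensor.

#' Saturating adsorption transient
#'
#' Stylised first-order binding curve `A * (1 - exp(-(t - start) / tau))` for
#' `t >= start`, zero before: the canonical shape of a protein-adsorption
#' frequency shift approaching saturation. Sequential steps superpose
#' additively.
#'
#' @param t Time grid in seconds.
#' @param amplitude Plateau amplitude `A` (Hz; negative for mass uptake on a
#'   frequency channel).
#' @param time_constant Exponential time constant `tau` in seconds (> 0).
#' @param start Onset time in seconds.
#' @return Numeric vector over `t`.
#' @examples
#' binding_curve(0:10 * 60, amplitude = -3681, time_constant = 300)
#' @export
binding_curve <- function(t, amplitude, time_constant, start = 0) {
  if (time_constant <= 0) stop("`time_constant` must be > 0.", call. = FALSE)
  ifelse(t >= start, amplitude * (1 - exp(-(t - start) / time_constant)), 0)
}

#' Configuration of a simulated sensor/reference pair
#'
#' Defaults emulate a two-step protein-adsorption run in a deliberately harsh
#' environment: a piecewise-linear temperature excursion 23 -> 34 -> 23
#' degrees C across the acquisition, a sawtooth flow-rate interference late
#' in the run, independent 2 Hz white noise per channel, a reference whose
#' disturbance response is 1.2 times the sensor's, and two saturating binding
#' steps seen by the sensor only. Set the relevant pieces to `NULL`/`0` (or
#' pass an empty `binding_steps` list) for quiescent-baseline scenarios.
#'
#' @param duration Acquisition length in seconds.
#' @param sample_rate Samples per second per resonator (default 3, typical of
#'   multi-channel QCM-D electronics).
#' @param noise_sd_sensor,noise_sd_reference White-noise SD per channel
#'   (Hz, or 1e-6 for dissipation).
#' @param drift_rate Deterministic common-mode ramp in Hz/h (0 disables).
#' @param temperature `NULL`, or a list with `start` and `peak` (degrees C),
#'   optional `t_peak`/`t_end` (seconds; default mid-run and end-of-run):
#'   a piecewise-linear excursion start -> peak -> start.
#' @param temp_coef Sensor frequency response to temperature, Hz per degree C
#'   (default -50: an effective 1 ppm/K at 50 MHz, the magnitude implied by
#'   the few-hundred-Hz distortion a ~10 degree C excursion imprints on a
#'   liquid-loaded miniaturised AT-cut resonator).
#' @param gain_mismatch Multiplier applied to the reference's response to
#'   every common disturbance (default 1.2).
#' @param sawtooth `NULL`, or a list with `period`, `amplitude` (Hz),
#'   `start`, `stop` (seconds): a sawtooth interference emulating periodic
#'   flow-rate changes, added to both channels (with `gain_mismatch` on the
#'   reference).
#' @param binding_steps List of binding steps, each a list with `start`,
#'   `amplitude`, `time_constant` (and optional `d_amplitude`, used when
#'   `channel = "dissipation"`). Present on the sensor only.
#' @param random_walk_sd Per-sample SD of an optional common random-walk
#'   (integrated white) component modelling low-frequency wander beyond the
#'   deterministic ramp (default 0: off).
#' @param channel `"frequency"` or `"dissipation"`. For dissipation the same
#'   structure is generated with `d_amplitude` binding amplitudes (units of
#'   1e-6).
#' @param seed Integer seed making the pair reproducible; `NULL` uses the
#'   current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 7200, sample_rate = 3,
                       noise_sd_sensor = 2, noise_sd_reference = 2,
                       drift_rate = 0,
                       temperature = list(start = 23, peak = 34),
                       temp_coef = -50,
                       gain_mismatch = 1.2,
                       sawtooth = list(period = 60, amplitude = 30,
                                       start = 6000, stop = 6300),
                       binding_steps = list(
                         list(start = 600, amplitude = -3681,
                              time_constant = 300, d_amplitude = 40),
                         list(start = 3000, amplitude = -1400,
                              time_constant = 300, d_amplitude = 12)
                       ),
                       random_walk_sd = 0,
                       channel = c("frequency", "dissipation"),
                       seed = NULL) {
  channel <- match.arg(channel)
  if (duration <= 0 || sample_rate <= 0) {
    stop("`duration` and `sample_rate` must be positive.", call. = FALSE)
  }
  if (noise_sd_sensor < 0 || noise_sd_reference < 0 || random_walk_sd < 0) {
    stop("noise standard deviations must be >= 0.", call. = FALSE)
  }
  structure(
    list(duration = duration, sample_rate = sample_rate,
         noise_sd_sensor = noise_sd_sensor,
         noise_sd_reference = noise_sd_reference,
         drift_rate = drift_rate, temperature = temperature,
         temp_coef = temp_coef, gain_mismatch = gain_mismatch,
         sawtooth = sawtooth, binding_steps = binding_steps,
         random_walk_sd = random_walk_sd, channel = channel, seed = seed),
    class = "sim_config"
  )
}

.temperature_shift <- function(t, temperature, duration) {
  if (is.null(temperature)) return(numeric(length(t)))
  t_peak <- temperature$t_peak %||% (duration / 2)
  t_end <- temperature$t_end %||% duration
  rise <- temperature$peak - temperature$start
  up <- rise * pmin(1, pmax(0, t / t_peak))
  down <- rise * pmin(1, pmax(0, (t - t_peak) / max(t_end - t_peak, 1e-9)))
  up - down
}

.sawtooth_shift <- function(t, sawtooth) {
  if (is.null(sawtooth)) return(numeric(length(t)))
  s <- numeric(length(t))
  m <- t >= sawtooth$start & t < sawtooth$stop
  phase <- ((t[m] - sawtooth$start) %% sawtooth$period) / sawtooth$period
  s[m] <- sawtooth$amplitude * (phase - 0.5)
  s
}

#' Simulate one sensor/reference pair with ground truth
#'
#' Builds `sensor = binding + disturbance + noise` and
#' `reference = gain_mismatch * disturbance + noise` (no binding on the
#' reference), where the common disturbance is the sum of the deterministic
#' ramp, the temperature excursion mapped through `temp_coef`, and the
#' optional random walk; the sawtooth interference is tracked as its own
#' component. The returned truth components sum exactly to the emitted
#' trace values, which is what makes parameter-recovery tests possible.
#'
#' @param config A [sim_config()].
#' @return A list with elements `pair` (a [paired_record()]) and `truth`
#'   (list with `time_s` and per-channel component lists `sensor` /
#'   `reference`, each holding `binding`, `drift`, `sawtooth`, `noise`).
#' @seealso [simulate_qcm()] for the tibble interface.
#' @examples
#' sim <- simulate_pair(sim_config(duration = 600, seed = 42))
#' str(sim$truth$sensor, max.level = 1)
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    n <- round(config$duration * config$sample_rate)
    t <- (seq_len(n) - 1) / config$sample_rate
    dissip <- config$channel == "dissipation"
    amp_of <- function(step) {
      if (dissip) step$d_amplitude %||% 0 else step$amplitude
    }
    binding <- Reduce(`+`, lapply(config$binding_steps, function(st) {
      binding_curve(t, amp_of(st), st$time_constant, st$start)
    }), accumulate = FALSE, init = numeric(n))
    drift <- config$drift_rate / 3600 * t +
      config$temp_coef * .temperature_shift(t, config$temperature,
                                            config$duration)
    if (config$random_walk_sd > 0) {
      drift <- drift + cumsum(stats::rnorm(n, sd = config$random_walk_sd))
    }
    saw <- .sawtooth_shift(t, config$sawtooth)
    noise_s <- stats::rnorm(n, sd = config$noise_sd_sensor)
    noise_r <- stats::rnorm(n, sd = config$noise_sd_reference)
    g <- config$gain_mismatch
    sensor <- binding + drift + saw + noise_s
    reference <- g * drift + g * saw + noise_r
    pair <- paired_record(
      resonator_trace(sensor, config$sample_rate, config$channel, "sensor"),
      resonator_trace(reference, config$sample_rate, config$channel,
                      "reference")
    )
    truth <- list(
      time_s = t,
      sensor = list(binding = binding, drift = drift, sawtooth = saw,
                    noise = noise_s),
      reference = list(binding = numeric(n), drift = g * drift,
                       sawtooth = g * saw, noise = noise_r)
    )
    list(pair = pair, truth = truth)
  }
  if (!is.null(config$seed)) {
    withr::with_seed(as.integer(config$seed), run())
  } else {
    run()
  }
}

#' Simulate a paired QCM-D acquisition as a tibble
#'
#' Data-frame interface to [simulate_pair()]: returns one row per sample with
#' the emitted traces and, optionally, the ground-truth components (columns
#' prefixed `sensor_` / `reference_`), which sum exactly to the corresponding
#' trace column.
#'
#' @param config A [sim_config()], or leave `NULL` and pass [sim_config()]
#'   arguments through `...`.
#' @param truth Include ground-truth component columns (default `TRUE`).
#' @param ... Arguments forwarded to [sim_config()] when `config` is `NULL`.
#' @return A tibble with columns `time_s`, `sensor`, `reference` and (with
#'   `truth = TRUE`) the component columns. The sample rate and channel kind
#'   are attached as attributes `sample_rate` and `channel`.
#' @examples
#' sim <- simulate_qcm(duration = 600, seed = 1)
#' names(sim)
#' @export
simulate_qcm <- function(config = NULL, truth = TRUE, ...) {
  if (is.null(config)) config <- sim_config(...)
  res <- simulate_pair(config)
  out <- tibble::tibble(
    time_s = res$truth$time_s,
    sensor = res$pair$sensor$values,
    reference = res$pair$reference$values
  )
  if (truth) {
    for (ch in c("sensor", "reference")) {
      for (comp in names(res$truth[[ch]])) {
        out[[paste(ch, comp, sep = "_")]] <- res$truth[[ch]][[comp]]
      }
    }
  }
  attr(out, "sample_rate") <- config$sample_rate
  attr(out, "channel") <- config$channel
  out
}
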