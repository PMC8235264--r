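# Comparator methods used for benchmarking the wavelet correction.

#' Filtered direct-subtraction (Mecea) compensation
#'
#' The classical dual-resonator compensation: subtract the reference trace
#' from the sensor trace sample by sample, then smooth the difference with a
#' sliding averaging window (default 16 samples) to tame the doubled
#' high-frequency noise. The window is centred and truncated at the edges;
#' a trailing (causal) variant is available for real-time benchmarking.
#'
#' Unlike the wavelet projection, direct subtraction assumes the two
#' resonators respond identically to shared disturbances: any gain mismatch
#' `g` leaves a residual `(1 - g)` fraction of the disturbance in the output.
#'
#' @param pair A [paired_record()].
#' @param window Averaging window length in samples (>= 1; 1 disables the
#'   smoothing).
#' @param align `"center"` (default) or `"right"` (trailing/causal).
#' @return A `resonator_trace` of the compensated signal.
#' @examples
#' p <- paired_record(rnorm(64), rnorm(64), sample_rate = 3)
#' m <- mecea_filtered(p)
#' @export
mecea_filtered <- function(pair, window = 16L, align = c("center", "right")) {
  stopifnot(inherits(pair, "paired_record"))
  align <- match.arg(align)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1.", call. = FALSE)
  d <- pair$sensor$values - pair$reference$values
  n <- length(d)
  idx <- seq_len(n)
  if (align == "center") {
    lo <- pmax(1L, idx - window %/% 2L)
    hi <- pmin(n, idx + (window + 1L) %/% 2L - 1L)
  } else {
    lo <- pmax(1L, idx - window + 1L)
    hi <- idx
  }
  cs <- c(0, cumsum(d))
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  resonator_trace(out, pair$sensor$sample_rate, pair$sensor$channel,
                  label = "mecea_filtered")
}

#' Uncorrected sensor signal (benchmark arm)
#'
#' Returns the raw sensor trace unchanged; the no-correction baseline against
#' which both compensation methods are compared.
#'
#' @param pair A [paired_record()].
#' @return The sensor `resonator_trace`, verbatim.
#' @export
raw_passthrough <- function(pair) {
  stopifnot(inherits(pair, "paired_record"))
  pair$sensor
}
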