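# CSV trace dialect: comma-delimited, header `time_s,<channel>_<label>`,
# time in seconds (strictly increasing, uniform), frequency columns in Hz,
# dissipation columns in units of 1e-6. Missing values are rejected, never
# imputed.

.validate_time <- function(t, rel_tol = 1e-6) {
  if (length(t) < 2L) return(1)
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("time column is not strictly increasing at row ",
         which(dt <= 0)[1L] + 1L, ".", call. = FALSE)
  }
  dt0 <- stats::median(dt)
  bad <- abs(dt - dt0) > rel_tol * dt0
  if (any(bad)) {
    stop("non-uniform sampling: time step at row ", which(bad)[1L] + 1L,
         " deviates from the median interval by more than the 1e-6 ",
         "relative tolerance.", call. = FALSE)
  }
  1 / dt0
}

#' Read paired resonator traces from a CSV file
#'
#' Reads the package's trace dialect and validates it: the time column must
#' be strictly increasing and uniform within a 1e-6 relative tolerance
#' (violations are rejected naming the offending row), and missing values
#' are an error. The sample rate is inferred from the time column and
#' attached as attribute `sample_rate`.
#'
#' @param path CSV file path.
#' @param time Name of the time column (seconds), default `"time_s"`.
#' @return A validated tibble with attribute `sample_rate`.
#' @seealso [as_paired_record()] to pick two columns as a sensor/reference
#'   pair, [write_traces()].
#' @export
read_traces <- function(path, time = "time_s") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!time %in% names(data)) {
    stop("malformed header: expected a '", time, "' column; found: ",
         paste(names(data), collapse = ", "), ".", call. = FALSE)
  }
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("all trace columns must be numeric.", call. = FALSE)
  }
  na_cells <- which(is.na(as.matrix(data)), arr.ind = TRUE)
  if (nrow(na_cells) > 0L) {
    stop("missing value at row ", na_cells[1L, 1L], ", column '",
         names(data)[na_cells[1L, 2L]], "'; missing values are not ",
         "permitted.", call. = FALSE)
  }
  attr(data, "sample_rate") <- .validate_time(data[[time]])
  data
}

#' Write resonator traces to the CSV trace dialect
#'
#' @param data A data frame with a `time_s` column (e.g. from
#'   [simulate_qcm()] or [tidy()] of a correction). An empty data frame
#'   yields a header-only file.
#' @param path Output CSV path.
#' @param time Name of the time column.
#' @return `path`, invisibly.
#' @export
write_traces <- function(data, path, time = "time_s") {
  stopifnot(is.data.frame(data))
  if (!time %in% names(data)) {
    stop("`data` must contain a '", time, "' column.", call. = FALSE)
  }
  if (anyNA(data)) stop("`data` contains missing values.", call. = FALSE)
  if (nrow(data) > 1L) .validate_time(data[[time]])
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Build a paired record from data-frame columns
#'
#' @param data A data frame holding the traces (e.g. from [read_traces()] or
#'   [simulate_qcm()]).
#' @param sensor,reference Columns holding the sensor and reference traces
#'   (tidy evaluation).
#' @param time Column holding time in seconds; used to infer the sample rate
#'   unless `sample_rate` is given.
#' @param sample_rate Explicit sample rate (samples/s), overriding `time`.
#' @param channel `"frequency"` or `"dissipation"`. `NULL` (default) infers
#'   it from the sensor column name prefix (`diss*` means dissipation).
#' @return A [paired_record()].
#' @examples
#' sim <- simulate_qcm(duration = 600, seed = 1)
#' pr <- as_paired_record(sim, sensor, reference)
#' @export
as_paired_record <- function(data, sensor, reference, time = time_s,
                             sample_rate = NULL, channel = NULL) {
  stopifnot(is.data.frame(data))
  s_quo <- rlang::enquo(sensor)
  r_quo <- rlang::enquo(reference)
  s <- dplyr::pull(data, !!s_quo)
  r <- dplyr::pull(data, !!r_quo)
  if (is.null(sample_rate)) {
    t_quo <- rlang::enquo(time)
    tcol <- try(dplyr::pull(data, !!t_quo), silent = TRUE)
    if (inherits(tcol, "try-error")) {
      sample_rate <- attr(data, "sample_rate")
      if (is.null(sample_rate)) {
        stop("supply `time` or `sample_rate`.", call. = FALSE)
      }
    } else {
      sample_rate <- .validate_time(tcol)
    }
  }
  if (is.null(channel)) {
    s_name <- rlang::as_label(s_quo)
    channel <- if (grepl("^diss", s_name, ignore.case = TRUE)) {
      "dissipation"
    } else {
      "frequency"
    }
  }
  paired_record(
    resonator_trace(s, sample_rate, channel, "sensor"),
    resonator_trace(r, sample_rate, channel, "reference")
  )
}
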