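# Core dual-resonator correction: derivative, sliding-window Pearson
# correlation with significance, conditional linear-projection cancellation,
# re-integration, and the batch/streaming orchestrators.

#' First difference of a coefficient series
#'
#' `derivative(s)[n] = s[n + 1] - s[n]`. The forward first difference is used
#' (rather than a centred stencil) because it is exactly invertible by
#' [integrate_series()], which the re-integration step requires.
#'
#' @param series Numeric vector, length >= 2.
#' @return Numeric vector one sample shorter than the input.
#' @examples
#' derivative(c(1, 3, 6))
#' @export
derivative <- function(series) {
  if (length(series) < 2L) {
    stop("`series` must contain at least 2 samples to differentiate.",
         call. = FALSE)
  }
  diff(series)
}

#' Cumulative integration, the exact inverse of [derivative()]
#'
#' @param zd Numeric vector of increments (may be empty).
#' @param initial Value of the first output sample.
#' @return Numeric vector of length `length(zd) + 1`.
#' @examples
#' integrate_series(c(2, 3), initial = 1)
#' @export
integrate_series <- function(zd, initial = 0) {
  initial <- as.numeric(initial)
  c(initial, initial + cumsum(as.numeric(zd)))
}

# rolling window bounds: centred, truncated (never padded) at the edges
.window_bounds <- function(n, window) {
  idx <- seq_len(n)
  lo <- pmax(1L, idx - window %/% 2L)
  hi <- pmin(n, idx + (window + 1L) %/% 2L - 1L)
  list(lo = lo, hi = hi, m = hi - lo + 1L)
}

# rolling first and second moments over [lo, hi] via cumulative sums
.rolling_sums <- function(x, y, lo, hi) {
  cx <- c(0, cumsum(x));  cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cyy <- c(0, cumsum(y * y))
  cxy <- c(0, cumsum(x * y))
  list(sx = cx[hi + 1L] - cx[lo],  sy = cy[hi + 1L] - cy[lo],
       sxx = cxx[hi + 1L] - cxx[lo], syy = cyy[hi + 1L] - cyy[lo],
       sxy = cxy[hi + 1L] - cxy[lo])
}

#' Sliding-window Pearson correlation with significance
#'
#' For every index `n`, the Pearson correlation between `xd` and `yd` is
#' computed over a window of `window` samples centred on `n` (truncated, not
#' padded, at the series edges). The two-sided p-value comes from the
#' t statistic `t = R * sqrt((m - 2) / (1 - R^2))` with `m - 2` degrees of
#' freedom, `m` being the actual window size at that index. Windows in which
#' either signal has zero variance are flagged `defined = FALSE` rather than
#' given a numeric correlation; the same applies to edge windows shorter than
#' `min_window`.
#'
#' @param xd,yd Numeric vectors of equal length (typically coefficient
#'   derivatives of the sensor and the reference).
#' @param window Window length `w` in samples (in coefficient-index space).
#' @param min_window Smallest truncated window still evaluated.
#' @return A tibble of class `correlation_track` with columns `index`, `r`,
#'   `p`, `n_window`, `defined`, and attributes `window`/`min_window`.
#' @examples
#' xd <- rnorm(200)
#' tr <- windowed_correlation(xd, xd, window = 32)
#' all(tr$r[tr$defined] == 1)
#' @export
windowed_correlation <- function(xd, yd, window = 32L, min_window = 8L) {
  n <- length(xd)
  if (length(yd) != n) {
    stop("`xd` and `yd` must have equal length.", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 samples.", call. = FALSE)
  wb <- .window_bounds(n, as.integer(window))
  rs <- .rolling_sums(xd, yd, wb$lo, wb$hi)
  m <- wb$m
  vx <- rs$sxx - rs$sx^2 / m
  vy <- rs$syy - rs$sy^2 / m
  cov <- rs$sxy - rs$sx * rs$sy / m
  # zero-variance detection robust to catastrophic cancellation
  zero_x <- vx <= 1e-12 * rs$sxx / m
  zero_y <- vy <= 1e-12 * rs$syy / m
  defined <- !zero_x & !zero_y & m >= as.integer(min_window)
  r <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  ok <- defined
  r[ok] <- pmin(1, pmax(-1, cov[ok] / sqrt(vx[ok] * vy[ok])))
  df <- m[ok] - 2L
  r2 <- r[ok]^2
  tt <- ifelse(r2 >= 1, Inf, abs(r[ok]) * sqrt(df / (1 - r2)))
  p[ok] <- 2 * stats::pt(-tt, df)
  out <- tibble::tibble(index = seq_len(n), r = r, p = p, n_window = m,
                        defined = defined)
  attr(out, "window") <- as.integer(window)
  attr(out, "min_window") <- as.integer(min_window)
  class(out) <- c("correlation_track", class(out))
  out
}

#' Cancel the reference from the sensor derivative, window by window
#'
#' Implements the conditional cancellation at the heart of the method. At
#' each index `n`:
#' * if the windowed correlation is statistically significant
#'   (`P(n) < alpha`), the corrected derivative is the residual of a linear
#'   projection of the reference into the sensor space,
#'   `z'(n) = xd(n) - a - b * yd(n)`, with `(a, b)` the least-squares fit of
#'   `xd` on `yd` over the window centred on `n`;
#' * otherwise (including undefined windows), the reference derivative is
#'   subtracted directly, `z'(n) = xd(n) - yd(n)`.
#'
#' The projection makes the cancellation robust to unequal absolute responses
#' of the two resonators: a gain mismatch is absorbed by `b` and a rate
#' offset by `a`.
#'
#' @param xd,yd Equal-length numeric vectors (sensor and reference
#'   derivatives).
#' @param track A [windowed_correlation()] result computed from the same
#'   `xd`, `yd` and window.
#' @param alpha Significance level; the projection branch requires
#'   `P(n) < alpha` (strict).
#' @return Numeric vector `zd` of corrected derivatives, with a logical
#'   attribute `"projection"` marking the indices that used the projection
#'   branch.
#' @examples
#' yd <- rnorm(100); xd <- 2 + 3 * yd
#' tr <- windowed_correlation(xd, yd, window = 16)
#' zd <- project_and_cancel(xd, yd, tr, alpha = 0.05)
#' max(abs(zd[attr(zd, "projection")]))
#' @export
project_and_cancel <- function(xd, yd, track, alpha = 0.05) {
  n <- length(xd)
  if (length(yd) != n) {
    stop("`xd` and `yd` must have equal length.", call. = FALSE)
  }
  if (!inherits(track, "correlation_track") || nrow(track) != n) {
    stop("`track` must be a correlation track computed from `xd` and `yd`.",
         call. = FALSE)
  }
  window <- attr(track, "window")
  wb <- .window_bounds(n, window)
  rs <- .rolling_sums(xd, yd, wb$lo, wb$hi)
  m <- wb$m
  vy <- rs$syy - rs$sy^2 / m
  cov <- rs$sxy - rs$sx * rs$sy / m
  use_proj <- track$defined & !is.na(track$p) & track$p < alpha & vy > 0
  b <- ifelse(use_proj, cov / vy, 0)
  a <- ifelse(use_proj, (rs$sx - b * rs$sy) / m, 0)
  zd <- ifelse(use_proj, xd - a - b * yd, xd - yd)
  attr(zd, "projection") <- use_proj
  zd
}

# Steps 3-6 applied to one pair of (already thresholded) coefficient series.
.correct_series <- function(xs, ys, window, alpha, min_window) {
  if (length(xs) < 2L) {
    return(list(values = xs, projection_fraction = NA_real_))
  }
  xd <- derivative(xs)
  yd <- derivative(ys)
  track <- windowed_correlation(xd, yd, window = window,
                                min_window = min_window)
  zd <- project_and_cancel(xd, yd, track, alpha = alpha)
  list(values = integrate_series(zd, initial = xs[1L]),
       projection_fraction = mean(attr(zd, "projection")))
}

#' Correct a sensor trace against its reference (batch)
#'
#' Runs the full dual-resonator wavelet correction on one paired record:
#' both traces are decomposed (multi-level DWT), their detail coefficients
#' are hard-thresholded, every coefficient series (approximation and all
#' details) is differentiated, the sensor and reference derivatives are
#' compared by a sliding-window Pearson significance test and cancelled via
#' [project_and_cancel()], the corrected derivatives are re-integrated (each
#' series anchored at the sensor's thresholded coefficient value at index 1,
#' so the corrected trace stays on the sensor's scale), and the inverse DWT
#' returns the corrected time-domain trace.
#'
#' The algorithm is channel-agnostic: frequency-shift and dissipation traces
#' obey identical contracts.
#'
#' @param pair A [paired_record()].
#' @param params A [correction_params()] object.
#' @return A `resonator_trace` with the same length, sample rate and channel
#'   kind as the sensor input. Per-series branch statistics (fraction of
#'   projection-branch decisions) are attached as attribute `"diagnostics"`
#'   (a tibble with columns `series`, `n_coefficients`,
#'   `projection_fraction`).
#' @seealso [correct_traces()] for the data-frame interface,
#'   [correct_stream()] for block-wise operation.
#' @examples
#' sim <- simulate_pair(sim_config(duration = 400, seed = 1))
#' z <- correct_pair(sim$pair, correction_params(levels = 3))
#' @export
correct_pair <- function(pair, params = correction_params()) {
  stopifnot(inherits(pair, "paired_record"),
            inherits(params, "correction_params"))
  cx <- dwt_decompose(pair$sensor, params)
  cy <- dwt_decompose(pair$reference, params)
  cx <- hard_threshold(cx, rule = params$threshold_rule,
                       energy_fraction = params$energy_fraction,
                       lambda = params$lambda)
  cy <- hard_threshold(cy, rule = params$threshold_rule,
                       energy_fraction = params$energy_fraction,
                       lambda = params$lambda)
  series_x <- c(list(A = cx$approximation), cx$details)
  series_y <- c(list(A = cy$approximation), cy$details)
  corrected <- purrr::map2(series_x, series_y, .correct_series,
                           window = params$window, alpha = params$alpha,
                           min_window = params$min_window)
  cz <- cx
  cz$approximation <- corrected$A$values
  for (lev in seq_len(params$levels)) {
    cz$details[[lev]] <- corrected[[paste0("D", lev)]]$values
  }
  diagnostics <- tibble::tibble(
    series = names(series_x),
    n_coefficients = lengths(lapply(series_x, identity)),
    projection_fraction = vapply(corrected, `[[`, numeric(1),
                                 "projection_fraction")
  )
  out <- resonator_trace(idwt_reconstruct(cz), pair$sensor$sample_rate,
                         pair$sensor$channel, label = "corrected")
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Correct a pair block-by-block (streaming / real-time mode)
#'
#' Processes the paired signal in overlapping blocks and emits only each
#' block's central region (overlap-discard), so that samples become available
#' with bounded latency instead of after the full acquisition. Each block is
#' corrected independently with [correct_pair()]; consecutive emissions are
#' stitched by anchoring each block's first emitted increment to the
#' previously emitted sample, which keeps the integrated baseline continuous
#' across block seams. Interior samples agree with the batch output up to
#' block-edge effects; widening `overlap` tightens the agreement.
#'
#' @param block_source Either a function that returns a list with elements
#'   `sensor` and `reference` (numeric chunks of any length, `NULL` when the
#'   stream ends), or a [paired_record()] which is then chunked internally.
#' @param params A [correction_params()].
#' @param block_length Samples per processed block. Must allow
#'   `params$levels` decomposition levels and exceed `2 * overlap`.
#' @param overlap Edge margin discarded on each side of a block, in
#'   time-domain samples. Default `4 * window * 2^levels`; must be at least
#'   `window * 2^levels` so a full correlation window of the coarsest
#'   coefficient series fits inside the margin.
#' @param sample_rate Sample rate of the stream (required when
#'   `block_source` is a function).
#' @param channel Channel kind of the stream when `block_source` is a
#'   function.
#' @param sink Optional function called with each emitted chunk of corrected
#'   samples.
#' @return A `resonator_trace` holding all emitted samples (equal length to
#'   the consumed stream), invisibly if `sink` is given.
#' @examples
#' sim <- simulate_pair(sim_config(duration = 1200, seed = 1))
#' p <- correction_params(levels = 3, window = 16)
#' z <- correct_stream(sim$pair, p, block_length = 1500, overlap = 200)
#' @export
correct_stream <- function(block_source, params = correction_params(),
                           block_length,
                           overlap = 4L * params$window * 2L^params$levels,
                           sample_rate = NULL, channel = "frequency",
                           sink = NULL) {
  stopifnot(inherits(params, "correction_params"))
  block_length <- as.integer(block_length)
  overlap <- as.integer(overlap)
  minlen <- .dwt_min_length(params$wavelet, params$levels)
  if (block_length < minlen) {
    stop("`block_length` too short: need at least ", minlen,
         " samples for ", params$levels, " levels of ", params$wavelet, ".",
         call. = FALSE)
  }
  if (overlap < params$window * 2L^params$levels) {
    stop("`overlap` must be at least window * 2^levels = ",
         params$window * 2L^params$levels, " samples.", call. = FALSE)
  }
  if (block_length <= 2L * overlap) {
    stop("`block_length` must exceed 2 * overlap.", call. = FALSE)
  }

  if (inherits(block_source, "paired_record")) {
    pr <- block_source
    sample_rate <- pr$sensor$sample_rate
    channel <- pr$sensor$channel
    served <- FALSE
    block_source <- function() {
      if (served) return(NULL)
      served <<- TRUE
      list(sensor = pr$sensor$values, reference = pr$reference$values)
    }
  }
  if (is.null(sample_rate)) {
    stop("`sample_rate` is required when `block_source` is a function.",
         call. = FALSE)
  }

  engine <- function(xs, ys) {
    correct_pair(paired_record(xs, ys, sample_rate = sample_rate,
                               channel = channel), params)$values
  }

  xbuf <- numeric(0)
  ybuf <- numeric(0)
  buf_origin <- 1L   # global index of xbuf[1]
  emitted_n <- 0L    # global samples emitted so far
  anchor <- NA_real_ # last emitted value
  out <- list()
  ended <- FALSE

  emit <- function(vals) {
    out[[length(out) + 1L]] <<- vals
    emitted_n <<- emitted_n + length(vals)
    anchor <<- vals[length(vals)]
    if (!is.null(sink)) sink(vals)
  }

  process_block <- function(pos, end, last) {
    i0 <- pos - buf_origin + 1L
    i1 <- end - buf_origin + 1L
    zb <- engine(xbuf[i0:i1], ybuf[i0:i1])
    e0 <- emitted_n + 1L - pos + 1L            # block-relative start
    e1 <- if (last) end - pos + 1L else block_length - overlap
    if (e1 < e0) return(invisible())
    vals <- zb[e0:e1]
    if (emitted_n > 0L) vals <- vals - zb[e0 - 1L] + anchor
    emit(vals)
  }

  repeat {
    while (!ended) {
      chunk <- block_source()
      if (is.null(chunk)) { ended <- TRUE; break }
      if (length(chunk$sensor) != length(chunk$reference)) {
        stop("sensor and reference chunks must have equal length.",
             call. = FALSE)
      }
      xbuf <- c(xbuf, chunk$sensor)
      ybuf <- c(ybuf, chunk$reference)
      if (buf_origin + length(xbuf) - 1L >= emitted_n + block_length) break
    }
    avail_end <- buf_origin + length(xbuf) - 1L
    # next block starts so that its emission continues at emitted_n + 1
    pos <- max(1L, emitted_n + 1L - overlap)
    if (!ended && avail_end - pos + 1L >= block_length) {
      process_block(pos, pos + block_length - 1L, last = FALSE)
      # drop consumed prefix, keep the overlap context
      keep_from <- max(1L, emitted_n + 1L - overlap)
      drop_n <- keep_from - buf_origin
      if (drop_n > 0L) {
        xbuf <- xbuf[-seq_len(drop_n)]
        ybuf <- ybuf[-seq_len(drop_n)]
        buf_origin <- keep_from
      }
    } else if (ended) {
      if (avail_end > emitted_n) {
        # widen the final block's left context as far as the buffer allows
        pos <- max(buf_origin, min(pos, avail_end - block_length + 1L))
        if (avail_end - pos + 1L < minlen) {
          stop("stream remainder too short to correct; supply at least ",
               minlen, " samples.", call. = FALSE)
        }
        process_block(pos, avail_end, last = TRUE)
      }
      break
    }
  }
  res <- resonator_trace(unlist(out), sample_rate, channel,
                         label = "corrected (streamed)")
  if (is.null(sink)) res else invisible(res)
}
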