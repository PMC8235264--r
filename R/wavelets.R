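# Mallat filter-bank DWT for Daubechies wavelets.
#
# Two boundary policies are provided:
#   "symmetric": half-point symmetric extension by (L - 1) samples per side,
#     full convolution, decimation by 2. Redundant near the edges (the
#     per-level length is floor((n + L - 1) / 2)) but free of wrap-around
#     artifacts on drifting baselines.
#   "periodic": periodised orthonormal transform (per-level length
#     ceiling(n / 2)); exactly energy preserving.
# Both reconstruct the input to floating-point accuracy.

# Daubechies low-pass decomposition filters (orthonormal, sum = sqrt(2)).
.db_dec_lo <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999,
          -0.0062414902127982744, 0.077571493840045719,
          -0.032244869584638375, -0.24229488706638203, 0.13842814590132074,
          0.72430852843777294, 0.60382926979718965, 0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108,
          0.00055384220116149613, -0.03158203931748603,
          0.027522865530305727, 0.097501605587323043, -0.12976686756726194,
          -0.22626469396543983, 0.31525035170919763, 0.75113390802109536,
          0.49462389039845306, 0.11154074335010947)
)

#' Quadrature-mirror filter set of a Daubechies wavelet
#'
#' @param wavelet One of `"db1"` ... `"db6"`.
#' @return A list with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and the filter
#'   `length`.
#' @keywords internal
#' @export
wavelet_filter <- function(wavelet) {
  dec_lo <- .db_dec_lo[[wavelet]]
  if (is.null(dec_lo)) {
    stop("Unknown wavelet '", wavelet, "'. Available: ",
         paste(names(.db_dec_lo), collapse = ", "), ".", call. = FALSE)
  }
  L <- length(dec_lo)
  j <- seq_len(L) - 1L
  dec_hi <- (-1)^(j + 1) * rev(dec_lo)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), length = L)
}

# minimum signal length so that `levels` decompositions are meaningful
.dwt_min_length <- function(wavelet, levels) {
  L <- wavelet_filter(wavelet)$length
  (L - 1L) * 2L^levels
}

# full (open) convolution of x with filter f
.conv_full <- function(x, f) {
  n <- length(x)
  L <- length(f)
  # stats::convolve(type = "open") returns conv with f reversed relative to
  # the textbook definition; rev() restores sum_j f[j] x[k - j].
  stats::convolve(x, rev(f), type = "open")
}

# one analysis step: x -> list(cA, cD)
.dwt_step <- function(x, filt, mode) {
  L <- filt$length
  n <- length(x)
  if (mode == "symmetric") {
    p <- L - 1L
    left <- x[pmin(p:1, n)]
    right <- x[pmax(n - (1:p) + 1L, 1L)]
    ext <- c(left, x, right)
    olen <- (n + L - 1L) %/% 2L
    idx <- L + 2L * (seq_len(olen) - 1L) + 1L # 1-based index into full conv
    ya <- .conv_full(ext, filt$dec_lo)[idx]
    yd <- .conv_full(ext, filt$dec_hi)[idx]
  } else { # periodic
    xe <- if (n %% 2L == 1L) c(x, x[n]) else x
    m <- length(xe)
    olen <- m %/% 2L
    ya <- numeric(olen)
    yd <- numeric(olen)
    # circular correlation-style sum: c[i] = sum_j f[j] xe[(2i + L/2 - j) mod m]
    for (j in seq_len(L)) {
      src <- ((2L * (seq_len(olen) - 1L) + L %/% 2L - (j - 1L)) %% m) + 1L
      ya <- ya + filt$dec_lo[j] * xe[src]
      yd <- yd + filt$dec_hi[j] * xe[src]
    }
  }
  list(cA = ya, cD = yd)
}

# one synthesis step: (cA, cD) -> signal of length out_length
.idwt_step <- function(cA, cD, filt, mode, out_length) {
  L <- filt$length
  lc <- length(cA)
  if (length(cD) != lc) {
    stop("approximation and detail series lengths differ (", lc, " vs ",
         length(cD), "); coefficient set is inconsistent.", call. = FALSE)
  }
  if (mode == "symmetric") {
    u <- numeric(2L * lc)
    v <- numeric(2L * lc)
    u[seq(1L, 2L * lc, by = 2L)] <- cA
    v[seq(1L, 2L * lc, by = 2L)] <- cD
    z <- .conv_full(u, filt$rec_lo) + .conv_full(v, filt$rec_hi)
    avail <- 2L * lc - L + 2L
    if (out_length > avail) {
      stop("cannot reconstruct ", out_length, " samples from ", lc,
           " coefficients.", call. = FALSE)
    }
    z[(L - 1L):(L - 2L + out_length)]
  } else {
    m <- 2L * lc
    x <- numeric(m)
    base <- 2L * (seq_len(lc) - 1L) + (1L - L %/% 2L)
    for (j in seq_len(L)) {
      # destinations are distinct within one j (stride 2 modulo even m)
      dst <- ((base + (j - 1L)) %% m) + 1L
      x[dst] <- x[dst] + filt$rec_lo[j] * cA + filt$rec_hi[j] * cD
    }
    if (out_length > m) {
      stop("cannot reconstruct ", out_length, " samples from ", lc,
           " coefficients.", call. = FALSE)
    }
    x[seq_len(out_length)]
  }
}

#' Multi-level discrete wavelet decomposition
#'
#' Runs the Mallat analysis tree: at each level the current approximation is
#' split by the quadrature-mirror filter pair into a new (coarser)
#' approximation and a detail band, each decimated by 2. Four levels of a
#' db3 transform turn one trace into five coefficient series
#' (A, D4, D3, D2, D1).
#'
#' @param trace A `resonator_trace` or a bare numeric vector.
#' @param params A [correction_params()] object, or leave default and set
#'   `wavelet`/`levels`/`extension_mode` directly.
#' @param wavelet,levels,extension_mode Convenience overrides used when
#'   `params` is not supplied.
#'
#' @return An object of class `wavelet_coefs`: a list with `approximation`
#'   (numeric), `details` (list, finest `D1` first), `wavelet`, `levels`,
#'   `extension_mode`, `original_length` and `stage_lengths` (the input
#'   length at each analysis stage, needed for exact reconstruction).
#' @seealso [idwt_reconstruct()], [hard_threshold()]
#' @examples
#' co <- dwt_decompose(sin(seq(0, 10, length.out = 128)), levels = 3)
#' lengths(co$details)
#' @export
dwt_decompose <- function(trace, params = NULL, wavelet = "db3", levels = 4L,
                          extension_mode = "symmetric") {
  if (!is.null(params)) {
    stopifnot(inherits(params, "correction_params"))
    wavelet <- params$wavelet
    levels <- params$levels
    extension_mode <- params$extension_mode
  }
  x <- if (inherits(trace, "resonator_trace")) trace$values else
    as.numeric(trace)
  if (!all(is.finite(x))) stop("input contains non-finite values.",
                               call. = FALSE)
  levels <- as.integer(levels)
  filt <- wavelet_filter(wavelet)
  minlen <- .dwt_min_length(wavelet, levels)
  if (length(x) < minlen) {
    stop("signal too short for ", levels, " levels of ", wavelet,
         ": need at least ", minlen, " samples, got ", length(x), ".",
         call. = FALSE)
  }
  details <- vector("list", levels)
  stage_lengths <- integer(levels)
  cur <- x
  for (lev in seq_len(levels)) {
    stage_lengths[lev] <- length(cur)
    st <- .dwt_step(cur, filt, extension_mode)
    details[[lev]] <- st$cD
    cur <- st$cA
  }
  names(details) <- paste0("D", seq_len(levels))
  structure(
    list(approximation = cur, details = details, wavelet = wavelet,
         levels = levels, extension_mode = extension_mode,
         original_length = length(x), stage_lengths = stage_lengths),
    class = "wavelet_coefs"
  )
}

#' @export
print.wavelet_coefs <- function(x, ...) {
  cat(sprintf("<wavelet_coefs: %s, %d levels, %s extension, n = %d>\n",
              x$wavelet, x$levels, x$extension_mode, x$original_length))
  cat("  A:", length(x$approximation), "coefficients;  D1..Dq:",
      paste(lengths(x$details), collapse = ", "), "\n")
  invisible(x)
}

#' Inverse multi-level discrete wavelet transform
#'
#' Rebuilds the time-domain signal from a [dwt_decompose()] coefficient set
#' by running the synthesis filter bank level by level. The round trip
#' `idwt_reconstruct(dwt_decompose(x))` reproduces `x` to floating-point
#' accuracy for both extension modes.
#'
#' @param coeffs A `wavelet_coefs` object.
#' @return Numeric vector of length `coeffs$original_length`.
#' @examples
#' x <- cumsum(rnorm(100))
#' co <- dwt_decompose(x, levels = 2)
#' max(abs(idwt_reconstruct(co) - x))
#' @export
idwt_reconstruct <- function(coeffs) {
  stopifnot(inherits(coeffs, "wavelet_coefs"))
  if (length(coeffs$details) != coeffs$levels) {
    stop("coefficient set is inconsistent: ", length(coeffs$details),
         " detail series for ", coeffs$levels, " levels.", call. = FALSE)
  }
  filt <- wavelet_filter(coeffs$wavelet)
  cur <- coeffs$approximation
  for (lev in rev(seq_len(coeffs$levels))) {
    cD <- coeffs$details[[lev]]
    if (length(cur) != length(cD)) {
      stop("inconsistent coefficient lengths at level ", lev, " (A: ",
           length(cur), ", D: ", length(cD), ").", call. = FALSE)
    }
    cur <- .idwt_step(cur, cD, filt, coeffs$extension_mode,
                      coeffs$stage_lengths[lev])
  }
  cur
}

#' Hard-threshold the detail coefficients of a decomposition
#'
#' Wavelet shrinkage: detail coefficients whose magnitude falls below a
#' per-level threshold are set exactly to zero; surviving coefficients are
#' kept untouched (hard rule, never shrunk). Approximation coefficients pass
#' through unchanged.
#'
#' Two threshold policies are available. `"universal"` (default) uses the
#' classic per-level universal threshold `lambda = sigma * sqrt(2 log N)`
#' with the robust noise scale `sigma = median(|d|) / 0.6745`; for a pure
#' white-noise band this zeroes essentially every coefficient. `"energy"`
#' zeroes the smallest coefficients of each level whose cumulative squared
#' magnitude stays below `energy_fraction` of the level's total energy.
#'
#' @param coeffs A `wavelet_coefs` object.
#' @param rule `"universal"` or `"energy"`.
#' @param energy_fraction Cumulative energy fraction for the `"energy"` rule.
#' @param lambda Optional explicit threshold(s): a single value or one per
#'   detail level (finest first); overrides `rule`.
#' @return A `wavelet_coefs` object with thresholded details. The applied
#'   thresholds are attached as attribute `"lambda"`.
#' @examples
#' co <- dwt_decompose(rnorm(256), levels = 4)
#' th <- hard_threshold(co)
#' mean(th$details$D1 == 0)
#' @export
hard_threshold <- function(coeffs, rule = c("universal", "energy"),
                           energy_fraction = 0.01, lambda = NULL) {
  stopifnot(inherits(coeffs, "wavelet_coefs"))
  rule <- match.arg(rule)
  q <- coeffs$levels
  if (!is.null(lambda)) {
    lam <- rep_len(lambda, q)
  } else if (rule == "universal") {
    lam <- vapply(coeffs$details, function(d) {
      if (length(d) == 0L) return(0)
      sigma <- stats::median(abs(d)) / 0.6745
      sigma * sqrt(2 * log(length(d)))
    }, numeric(1))
  } else {
    lam <- vapply(coeffs$details, function(d) {
      if (length(d) == 0L) return(0)
      e <- sort(d^2)
      total <- sum(e)
      if (total == 0) return(0)
      k <- sum(cumsum(e) <= energy_fraction * total)
      if (k == 0L) 0 else sqrt(e[k]) * (1 + 1e-12)
    }, numeric(1))
  }
  out <- coeffs
  for (lev in seq_len(q)) {
    d <- out$details[[lev]]
    d[abs(d) < lam[lev]] <- 0
    out$details[[lev]] <- d
  }
  attr(out, "lambda") <- lam
  out
}
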