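# ECG preprocessing chain: bandpass -> resample -> normalize -> segment.

#' Construct a raw ECG trace
#'
#' @param samples Numeric amplitude vector (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `raw_ecg` with fields `samples`, `fs` and
#'   derived `duration_s = length(samples) / fs`.
#' @export
raw_ecg <- function(samples, fs) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort_invalid("`samples` must be a non-empty numeric vector")
  }
  check_scalar_number(fs, "fs")
  if (fs <= 0) abort_invalid("`fs` must be > 0")
  structure(list(samples = as.numeric(samples), fs = fs,
                 duration_s = length(samples) / fs),
            class = "raw_ecg")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`),
#' so the filter is phase-neutral and beat morphology is not skewed.
#' Default band 0.5-100 Hz removes baseline drift and high-frequency noise
#' while passing ECG content.
#'
#' @param x A [raw_ecg()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order (default 4).
#' @return A filtered `raw_ecg` of the same length and sampling rate.
#' @export
bandpass_filter <- function(x, low_hz = 0.5, high_hz = 100.0, order = 4L) {
  stopifnot(inherits(x, "raw_ecg"))
  check_scalar_number(low_hz, "low_hz")
  check_scalar_number(high_hz, "high_hz")
  nyq <- x$fs / 2
  if (low_hz <= 0 || low_hz >= high_hz) {
    abort_invalid("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyq) {
    abort_invalid(sprintf(
      "high_hz = %g must be below the Nyquist frequency %g Hz (fs/2)",
      high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x$samples)
  raw_ecg(y, x$fs)
}

#' Resample a trace to a new rate
#'
#' Polyphase resampling (`signal::resample`) with the output trimmed or
#' zero-padded to exactly `round(length(x) * fs_out / fs)` samples so the
#' duration bookkeeping is exact.
#'
#' @param x A [raw_ecg()].
#' @param fs_out Target sampling rate in Hz (> 0), default 125.
#' @return A `raw_ecg` at `fs_out`.
#' @export
resample_signal <- function(x, fs_out = 125.0) {
  stopifnot(inherits(x, "raw_ecg"))
  check_scalar_number(fs_out, "fs_out")
  if (fs_out <= 0) abort_invalid("`fs_out` must be > 0")
  n_out <- round(length(x$samples) * fs_out / x$fs)
  if (fs_out == x$fs) return(raw_ecg(x$samples, fs_out))
  # rational approximation of the rate ratio for the polyphase filter
  frac <- .rat_approx(fs_out / x$fs)
  y <- signal::resample(x$samples, frac[1], frac[2])
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  raw_ecg(y, fs_out)
}

# best rational p/q approximation with q bounded, for resample ratios
.rat_approx <- function(r, max_den = 1024L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) {
      err <- e; best <- c(as.integer(p), q)
      if (e < 1e-12) break
    }
  }
  best
}

#' Z-normalize a beat
#'
#' Subtracts the mean and divides by the population (divide-by-N) standard
#' deviation. A constant input (sd < 1e-12) cannot be scaled; it maps to
#' all zeros with a warning.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector with mean 0 and population sd 1 (or all zeros for
#'   constant input).
#' @export
normalize_beat <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort_invalid("`x` must be numeric with length >= 2")
  }
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop < 1e-12) {
    warning("constant input to normalize_beat(); returning zeros")
    return(numeric(length(x)))
  }
  (x - mu) / sd_pop
}

#' Segment a raw trace into fixed-length beats
#'
#' Detects candidate R-peaks as local maxima above an adaptive threshold
#' (midway between the trace mean and maximum) with a minimum separation of
#' `min_rr_s` seconds, extracts a window of `length` samples centered on
#' each peak (zero-padded where the window overruns the trace), and
#' z-normalizes each window via [normalize_beat()].
#'
#' This is a deliberately simple detector for phantom/clean signals, not a
#' clinically validated QRS algorithm.
#'
#' @param x A [raw_ecg()].
#' @param length Window length in samples (default 186).
#' @param min_rr_s Minimum peak separation in seconds (default 0.3).
#' @return List of `beat_segment` objects (possibly empty, with a warning,
#'   when the trace is too short or contains no peaks).
#' @export
segment_beats <- function(x, length = 186L, min_rr_s = 0.3) {
  stopifnot(inherits(x, "raw_ecg"))
  check_count(length, "length", lower = 32L)
  n <- base::length(x$samples)
  if (n < length) {
    warning("trace shorter than one beat window; returning no segments")
    return(list())
  }
  s <- x$samples
  thr <- mean(s) + 0.5 * (max(s) - mean(s))
  if (max(s) - mean(s) < 1e-12) return(list())  # flat trace: no peaks
  pk <- pracma::findpeaks(s, minpeakheight = thr,
                          minpeakdistance = max(1L, round(min_rr_s * x$fs)))
  if (is.null(pk)) return(list())
  locs <- sort(pk[, 2])
  half <- length %/% 2L
  lapply(locs, function(p) {
    idx <- (p - half):(p - half + length - 1L)
    w <- numeric(base::length(idx))
    ok <- idx >= 1L & idx <= n
    w[ok] <- s[idx[ok]]
    structure(list(samples = suppressWarnings(normalize_beat(w)),
                   fs = x$fs, label = NA_integer_,
                   record_id = sprintf("peak_%d", p)),
              class = "beat_segment")
  })
}
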