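#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order (by default) Butterworth band-pass applied forward and
#' backward (zero phase, squared magnitude response). The trace is
#' odd-reflection padded before filtering so that edge transients and any DC
#' offset decay outside the retained samples; the pad length scales with the
#' low-cutoff period.
#'
#' @param trace A [signal_trace()].
#' @param low,high Pass-band corner frequencies in Hz (default 10 and 450,
#'   the conventional surface-EMG band).
#' @param order Filter order of each pass (default 4).
#' @return A filtered [signal_trace()] of the same length.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' tr <- signal_trace(sin(2 * pi * 50 * t) + 2, fs = 1000)
#' filt <- bandpass_filter(tr)
#' @export
bandpass_filter <- function(trace, low = 10, high = 450, order = 4) {
  stopifnot(inherits(trace, "signal_trace"))
  fs <- trace$fs
  if (!(low > 0 && low < high)) {
    abort("need 0 < low < high.", class = "emghht_invalid_argument")
  }
  if (high >= fs / 2) {
    abort("`high` must be below the Nyquist frequency fs/2.",
          class = "emghht_invalid_argument")
  }
  x <- trace$samples
  n <- length(x)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  pad <- min(n - 1L, as.integer(ceiling(6 * fs / low)))
  xl <- 2 * x[1] - x[(pad + 1):2]
  xr <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(xl, x, xr))
  signal_trace(y[(pad + 1):(pad + n)], fs, trace$t0)
}

#' Moving RMS envelope
#'
#' Full-wave rectifies the trace and smooths it with a centered moving
#' root-mean-square window (default 50 ms). Windows shrink symmetrically at
#' the edges so the output has the input's length.
#'
#' @param trace A [signal_trace()].
#' @param window Window length in seconds (default 0.050).
#' @return A [signal_trace()] holding the RMS envelope.
#' @export
moving_rms <- function(trace, window = 0.050) {
  stopifnot(inherits(trace, "signal_trace"))
  n <- length(trace$samples)
  w <- as.integer(round(window * trace$fs))
  if (w < 2) abort("RMS window must span at least 2 samples.",
                   class = "emghht_invalid_argument")
  if (w > n) abort("RMS window longer than the trace.",
                   class = "emghht_invalid_argument")
  x2 <- abs(trace$samples)^2  # rectification absorbed by squaring
  half <- w %/% 2
  cs <- cumsum(c(0, x2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  env <- sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
  signal_trace(env, trace$fs, trace$t0)
}

#' Detect the stance phase from a vertical GRF trace
#'
#' Onset is the first sample at or above `threshold` within the longest
#' contiguous above-threshold run; offset is that run's last sample. A
#' pre-contact window of 100 ms worth of samples is attached for the
#' pre-activation analyses.
#'
#' @param grf A [signal_trace()] of vertical ground reaction force in newtons
#'   (non-negative).
#' @param threshold Contact threshold in newtons (default 20, the common
#'   gait-analysis convention).
#' @param pre_window Pre-contact window length in seconds (default 0.100).
#' @return A `stance_segment`: list with `onset_index`, `offset_index`,
#'   `pre_window_samples`, `fs` and logical `pre_window_truncated`.
#' @export
detect_stance <- function(grf, threshold = 20, pre_window = 0.100) {
  stopifnot(inherits(grf, "signal_trace"))
  above <- grf$samples >= threshold
  if (!any(above)) {
    abort("no sample reaches the contact threshold; no stance found.",
          class = "emghht_no_stance")
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  k <- runs[which.max(r$lengths[runs])]  # longest above-threshold run
  onset <- starts[k]
  offset <- ends[k]
  pre_n <- as.integer(round(pre_window * grf$fs))
  truncated <- onset - pre_n < 1L
  if (truncated) {
    warn("pre-contact window extends before the trace start; truncated.",
         class = "emghht_truncated_pre_window")
  }
  structure(list(onset_index = onset, offset_index = offset,
                 pre_window_samples = pre_n, fs = grf$fs,
                 pre_window_truncated = truncated),
            class = "stance_segment")
}

#' @export
print.stance_segment <- function(x, ...) {
  cat(sprintf("<stance_segment> onset %d, offset %d (%.0f ms), pre-window %d samples\n",
              x$onset_index, x$offset_index,
              (x$offset_index - x$onset_index + 1) / x$fs * 1000,
              x$pre_window_samples))
  invisible(x)
}

#' Analysis windows of a stance segment
#'
#' Half-open sample-index windows used throughout: the 100 ms before foot
#' contact, the first 20% of stance, and 20--40% of stance.
#'
#' @param seg A `stance_segment` from [detect_stance()].
#' @return Named list of integer vectors `c(start, end)` (half-open
#'   `[start, end)`), named `pre`, `early`, `mid`.
#' @export
stance_windows <- function(seg) {
  stopifnot(inherits(seg, "stance_segment"))
  on <- seg$onset_index
  span <- seg$offset_index - seg$onset_index
  s20 <- on + as.integer(round(0.20 * span))
  s40 <- on + as.integer(round(0.40 * span))
  list(pre = c(max(1L, on - seg$pre_window_samples), on),
       early = c(on, s20),
       mid = c(s20, s40))
}

#' Amplitude-normalize an envelope by a reference value
#'
#' Divides the envelope by the subject-and-muscle reference (the mean of the
#' stance-phase peak RMS values over that subject's rearfoot-strike trials),
#' expressing activation as a fraction of the rearfoot-strike peak.
#'
#' @param env A [signal_trace()] RMS envelope.
#' @param reference Positive scalar reference amplitude.
#' @return A normalized [signal_trace()] (1.0 = reference peak).
#' @seealso [rfs_reference()] for computing the reference from a cohort.
#' @export
normalize_rms <- function(env, reference) {
  stopifnot(inherits(env, "signal_trace"))
  if (!is.numeric(reference) || length(reference) != 1 || !is.finite(reference) ||
      reference <= 0) {
    abort("`reference` must be a positive scalar.", class = "emghht_invalid_argument")
  }
  signal_trace(env$samples / reference, env$fs, env$t0)
}

#' Time-normalize a stance-phase envelope
#'
#' Linearly interpolates the stance-phase portion of the envelope onto
#' `n_points` equally spaced points over 0--100% of stance.
#'
#' @param env A [signal_trace()].
#' @param seg A `stance_segment`.
#' @param n_points Grid size (default 101, a 1% grid).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(env, seg, n_points = 101) {
  stopifnot(inherits(env, "signal_trace"), inherits(seg, "stance_segment"))
  if (seg$offset_index <= seg$onset_index) {
    abort("degenerate stance segment (offset <= onset).",
          class = "emghht_invalid_argument")
  }
  idx <- seg$onset_index:seg$offset_index
  y <- env$samples[idx]
  approx(x = seq(0, 100, length.out = length(idx)), y = y,
         xout = seq(0, 100, length.out = n_points))$y
}
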