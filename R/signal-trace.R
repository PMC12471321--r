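#' Uniformly sampled signal trace
#'
#' The basic carrier of all time-domain signals in the package: a numeric
#' sample vector, a sampling rate, and the time of the first sample relative
#' to foot contact (negative before contact).
#'
#' @param samples Numeric vector of finite samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0 Time of the first sample in seconds, relative to foot contact.
#' @return An object of class `signal_trace`: a list with elements `samples`,
#'   `fs`, `t0`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 10 * seq(0, 1, by = 1 / 1000)), fs = 1000)
#' tr
#' @export
signal_trace <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar.", class = "emghht_invalid_argument")
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    abort("`samples` must be finite and non-missing.", class = "emghht_invalid_argument")
  }
  structure(list(samples = samples, fs = fs, t0 = t0), class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz, t0 = %g s (%.3f s)\n",
              length(x$samples), x$fs, x$t0, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Time axis of a signal trace
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times in seconds (relative to contact).
#' @export
trace_time <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

#' @method as_tibble signal_trace
#' @export
as_tibble.signal_trace <- function(x, ...) {
  tibble::tibble(time_s = trace_time(x), value = x$samples)
}

as_trace <- function(x, fs, t0 = 0) {
  if (inherits(x, "signal_trace")) x else signal_trace(x, fs, t0)
}
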