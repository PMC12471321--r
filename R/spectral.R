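#' Analytic signal via the discrete Hilbert transform
#'
#' Builds the analytic signal z = x + i*H(x) by the standard frequency-domain
#' construction (doubling positive frequencies, zeroing negative ones), and
#' derives the instantaneous amplitude, unwrapped phase and instantaneous
#' frequency. Frequency uses a centered finite difference of the unwrapped
#' phase (one-sided at the edges) and is set to 0 where the amplitude is
#' negligible (below 1e-10 of its maximum), where phase is undefined.
#'
#' @param imf Numeric vector (typically one IMF), length >= 8.
#' @param fs Sampling rate in Hz.
#' @return List of class `analytic_signal` with numeric vectors `amplitude`,
#'   `phase` (radians, unwrapped) and `inst_freq` (Hz).
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' a <- analytic_signal(cos(2 * pi * 50 * t), fs = 1000)
#' range(a$inst_freq[100:900])
#' @export
analytic_signal <- function(imf, fs) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 8) abort("need at least 8 samples.", class = "emghht_invalid_argument")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  a <- Mod(z)
  theta <- signal::unwrap(Arg(z))
  f <- numeric(n)
  f[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) / 2
  f[1] <- theta[2] - theta[1]
  f[n] <- theta[n] - theta[n - 1]
  f <- f * fs / (2 * pi)
  eps <- 1e-10 * max(a)
  if (max(a) == 0) f[] <- 0 else f[a < eps] <- 0
  structure(list(amplitude = a, phase = theta, inst_freq = f),
            class = "analytic_signal")
}

#' Hilbert spectrum of an IMF set
#'
#' Deposits each IMF's instantaneous energy a_i^2(t) into the frequency bin
#' containing its instantaneous frequency, over all time samples, producing
#' the energy distribution H(f, t) on the frequency-time plane. Samples whose
#' instantaneous frequency falls outside (0, fmax] are excluded (negative or
#' out-of-band instantaneous frequencies are edge/low-amplitude artifacts of
#' the Hilbert transform); the residual is never included.
#'
#' @param imfset An `imf_set` from [emd_decompose()] or [eemd_decompose()].
#' @param fs Sampling rate; defaults to the one stored in `imfset`.
#' @param freq_bin_width Bin width in Hz (default 1).
#' @param fmax Upper frequency limit in Hz (default 500).
#' @return Object of class `hilbert_spectrum`: list with `energy` (matrix,
#'   frequency bins x time samples), `freq_edges`, `freq_centers`, `fs`,
#'   `t0`, and `in_range_energy` (the bookkeeping total of deposited energy).
#' @export
hilbert_spectrum <- function(imfset, fs = NULL, freq_bin_width = 1, fmax = 500) {
  stopifnot(inherits(imfset, "imf_set"))
  fs <- fs %||% imfset$fs
  if (is.null(fs)) abort("sampling rate unknown; supply `fs`.",
                         class = "emghht_invalid_argument")
  n <- imfset$source_length
  nb <- as.integer(ceiling(fmax / freq_bin_width))
  energy <- matrix(0, nrow = nb, ncol = n)
  total <- 0
  n_imfs <- ncol(imfset$imfs)
  if (n_imfs > 0) {
    for (k in seq_len(n_imfs)) {
      as_k <- analytic_signal(imfset$imfs[, k], fs)
      f <- as_k$inst_freq
      e <- as_k$amplitude^2
      keep <- f > 0 & f <= fmax
      if (any(keep)) {
        bins <- as.integer(ceiling(f[keep] / freq_bin_width))
        idx <- cbind(bins, which(keep))  # each time sample once per IMF
        energy[idx] <- energy[idx] + e[keep]
        total <- total + sum(e[keep])
      }
    }
  }
  structure(list(energy = energy,
                 freq_edges = seq(0, nb * freq_bin_width, by = freq_bin_width),
                 freq_centers = (seq_len(nb) - 0.5) * freq_bin_width,
                 freq_bin_width = freq_bin_width, fmax = fmax,
                 fs = fs, t0 = imfset$t0, in_range_energy = total),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d bins x %d samples, %g Hz bins up to %g Hz\n",
              nrow(x$energy), ncol(x$energy), x$freq_bin_width, x$fmax))
  invisible(x)
}

#' Marginal Hilbert spectrum
#'
#' Sums the Hilbert spectrum over time, giving the total energy contributed
#' by each frequency bin over the whole interval.
#'
#' @param hs A `hilbert_spectrum`.
#' @return A tibble with columns `freq_hz` (bin centers) and `energy`.
#' @export
marginal_spectrum <- function(hs) {
  stopifnot(inherits(hs, "hilbert_spectrum"))
  tibble::tibble(freq_hz = hs$freq_centers, energy = rowSums(hs$energy))
}

#' Locate the maximum-energy point of a Hilbert spectrum within stance
#'
#' Smooths the spectrum with a small 2-D moving-average kernel (default
#' 5 Hz x 10 ms) so a single noisy sample cannot dominate, then takes the
#' global argmax over the stance-phase columns. Ties break toward the
#' earliest time, then the lowest frequency.
#'
#' @param hs A `hilbert_spectrum`.
#' @param seg A `stance_segment` (sample indices into the spectrum's columns).
#' @param smooth_hz,smooth_s Smoothing kernel extent in Hz and seconds.
#' @return A list with `s_max_pct` (% of stance, 0--100) and `f_max_hz`
#'   (bin-center frequency).
#' @export
locate_max_energy <- function(hs, seg, smooth_hz = 5, smooth_s = 0.010) {
  stopifnot(inherits(hs, "hilbert_spectrum"), inherits(seg, "stance_segment"))
  on <- seg$onset_index
  off <- seg$offset_index
  if (off > ncol(hs$energy)) {
    abort("spectrum does not cover the stance segment.",
          class = "emghht_invalid_argument")
  }
  kf <- max(1L, as.integer(round(smooth_hz / hs$freq_bin_width)))
  kt <- max(1L, as.integer(round(smooth_s * hs$fs)))
  sm <- .box_smooth2d_cpp(hs$energy, kf, kt)
  stance <- sm[, on:off, drop = FALSE]
  if (all(stance == 0)) {
    abort("stance-phase spectrum is identically zero; features undefined.",
          class = "emghht_undefined_features")
  }
  # column-major scan: lowest frequency within the earliest time wins ties,
  # so scan time-major by transposing the comparison
  best <- which(stance == max(stance), arr.ind = TRUE)
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  list(s_max_pct = 100 * (best[[2]] - 1) / (off - on),
       f_max_hz = hs$freq_centers[best[[1]]])
}

#' Band power of a Hilbert spectrum over a time window
#'
#' Sums spectrum energy over the frequency bins lying inside `(band[1],
#' band[2]]` and the half-open sample window `[window[1], window[2])`. With
#' 1 Hz bins the conventional bands are `c(0, 60)` (low) and `c(60, 200)`
#' (high).
#'
#' @param hs A `hilbert_spectrum`.
#' @param band Numeric `c(low, high)` in Hz; bins fully inside the half-open
#'   interval are included.
#' @param window Integer `c(start, end)` sample window, half-open.
#' @return Scalar power (amplitude^2 summed over bins and samples).
#' @export
band_power <- function(hs, band, window) {
  stopifnot(inherits(hs, "hilbert_spectrum"))
  i1 <- window[1]
  i2 <- window[2]
  if (i2 <= i1 || i1 < 1 || i2 > ncol(hs$energy) + 1) {
    abort("empty or out-of-range window.", class = "emghht_invalid_argument")
  }
  w <- hs$freq_bin_width
  nb <- nrow(hs$energy)
  b <- seq_len(nb)
  keep <- ((b - 1) * w >= band[1]) & (b * w <= band[2])
  if (!any(keep)) return(0)
  sum(hs$energy[keep, i1:(i2 - 1), drop = FALSE])
}

#' Normalize band powers across conditions
#'
#' Expresses each raw band power as a percentage of the maximum observed in
#' its normalization group: the same subject, muscle, window and band across
#' the three foot-strike conditions (and trials).
#'
#' @param powers A data frame with columns `subject`, `muscle`, `window`,
#'   `band`, `condition` and `power`.
#' @return The input tibble with an added `power_pct` column (100 = group
#'   maximum). All-zero groups get zeros with a warning.
#' @export
normalize_band_power <- function(powers) {
  stopifnot(all(c("subject", "muscle", "window", "band", "condition", "power")
                %in% names(powers)))
  out <- powers |>
    dplyr::group_by(.data$subject, .data$muscle, .data$window, .data$band) |>
    dplyr::mutate(power_pct = if (max(.data$power) > 0)
      100 * .data$power / max(.data$power) else 0 * .data$power) |>
    dplyr::ungroup()
  if (any(out$power_pct == 0 & out$power == 0)) {
    grp_zero <- powers |>
      dplyr::group_by(.data$subject, .data$muscle, .data$window, .data$band) |>
      dplyr::summarise(allzero = all(.data$power == 0), .groups = "drop")
    if (any(grp_zero$allzero)) {
      warn("some normalization groups have all-zero power; left as zeros.",
           class = "emghht_zero_power_group")
    }
  }
  tibble::as_tibble(out)
}
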