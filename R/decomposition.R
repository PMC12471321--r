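#' Locate strict local extrema
#'
#' Finds local maxima and minima by sign changes of the first difference.
#' A flat plateau (a run of equal samples flanked by opposite slopes)
#' contributes a single extremum at its midpoint, rounded down.
#'
#' @param x Numeric vector, length >= 3.
#' @return A list with integer index vectors `maxima` and `minima` (1-based).
#' @examples
#' find_extrema(sin(2 * pi * 3 * seq(0, 1, length.out = 301)))
#' @export
find_extrema <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) abort("`x` must have at least 3 samples.",
                           class = "emghht_invalid_argument")
  .find_extrema_cpp(x)
}

#' Cubic-spline envelopes of a signal
#'
#' Fits natural cubic splines through the local maxima (upper envelope) and
#' minima (lower envelope). The two extrema nearest each end are
#' mirror-extended about the first/last sample before fitting, the standard
#' mitigation of spline end-swings in empirical mode decomposition.
#'
#' @param x Numeric vector.
#' @param maxima,minima Integer indices of local extrema, as returned by
#'   [find_extrema()].
#' @return List with numeric vectors `upper`, `lower` and their pointwise
#'   `mean`, each the length of `x`.
#' @export
spline_envelopes <- function(x, maxima = NULL, minima = NULL) {
  x <- as.numeric(x)
  if (is.null(maxima) || is.null(minima)) {
    ex <- find_extrema(x)
    maxima <- ex$maxima
    minima <- ex$minima
  }
  if (!sift_possible(maxima, minima)) {
    abort("too few extrema to build envelopes; signal is a residual.",
          class = "emghht_cannot_sift")
  }
  .spline_envelopes_cpp(x, as.integer(maxima), as.integer(minima))
}

sift_possible <- function(maxima, minima) {
  length(maxima) >= 1 && length(minima) >= 1 &&
    (length(maxima) + length(minima)) >= 2
}

#' Extract one intrinsic mode function by fixed-count sifting
#'
#' Repeatedly subtracts the mean of the upper and lower spline envelopes from
#' the working signal, a fixed number of times (no convergence criterion).
#' If the working signal loses its extrema mid-iteration, the current state
#' is returned as the IMF with `completed = FALSE`.
#'
#' @param x Numeric vector (must have at least one maximum and one minimum).
#' @param sift_iterations Number of sifting passes; default 10.
#' @return List with `imf`, `residual_after` (`x - imf`) and logical
#'   `completed`.
#' @export
sift_imf <- function(x, sift_iterations = 10) {
  x <- as.numeric(x)
  ex <- find_extrema(x)
  if (!sift_possible(ex$maxima, ex$minima)) {
    abort("signal has too few extrema to sift.", class = "emghht_cannot_sift")
  }
  stopifnot(sift_iterations >= 1)
  .sift_imf_cpp(x, as.integer(sift_iterations))
}

new_imf_set <- function(imfs, residual, fs = NULL, t0 = 0) {
  structure(list(imfs = imfs, residual = as.numeric(residual),
                 fs = fs, t0 = t0, source_length = length(residual)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual, %d samples%s\n",
              ncol(x$imfs), x$source_length,
              if (!is.null(x$fs)) sprintf(" @ %g Hz", x$fs) else ""))
  invisible(x)
}

#' @method as_tibble imf_set
#' @export
as_tibble.imf_set <- function(x, ...) {
  n <- x$source_length
  imfs <- x$imfs
  colnames(imfs) <- paste0("imf_", seq_len(ncol(imfs)))
  out <- tibble::as_tibble(as.data.frame(imfs))
  out$residual <- x$residual
  t <- if (is.null(x$fs)) seq_len(n) else x$t0 + (seq_len(n) - 1) / x$fs
  dplyr::bind_cols(tibble::tibble(time_s = t), out)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs), fastest
#' oscillation first, plus a residual, by iterated fixed-count sifting.
#' Extraction stops when the residual is monotone or has at most one
#' extremum, or when `max_imfs` is reached. The decomposition is complete:
#' the IMFs and residual sum back to the input exactly (floating round-off
#' aside).
#'
#' @param signal A [signal_trace()] or numeric vector.
#' @param sift_iterations Fixed number of sifting passes per IMF (default 10).
#' @param max_imfs Maximum number of IMFs; default `floor(log2(n)) - 1`, the
#'   usual dyadic bound.
#' @param fs Sampling rate, required only when `signal` is a bare vector and
#'   downstream spectral analysis is intended.
#' @return An `imf_set`: matrix `imfs` (samples x IMFs), vector `residual`,
#'   plus `fs`, `t0`, `source_length`.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' x <- sin(2 * pi * 25 * t) + sin(2 * pi * 150 * t)
#' dec <- emd_decompose(signal_trace(x, 1000))
#' dec
#' @export
emd_decompose <- function(signal, sift_iterations = 10, max_imfs = NULL, fs = NULL) {
  tr <- if (inherits(signal, "signal_trace")) signal else signal_trace(signal, fs %||% 1)
  x <- tr$samples
  n <- length(x)
  if (n < 10) abort("signal too short to decompose (need >= 10 samples).",
                    class = "emghht_invalid_argument")
  if (is.null(max_imfs)) max_imfs <- max(1L, floor(log2(n)) - 1L)
  res <- .emd_cpp(x, as.integer(sift_iterations), as.integer(max_imfs))
  new_imf_set(res$imfs, res$residual, fs = tr$fs, t0 = tr$t0)
}

#' EEMD configuration
#'
#' Bundles the ensemble-EMD parameters. Defaults follow the standard
#' noise-assisted settings for surface EMG: added white noise with standard
#' deviation 0.2 x sd(signal) (`nstd`), 100 ensemble members (`ne`), and 10
#' sifting iterations per IMF.
#'
#' @param nstd Noise amplitude as a multiple of the signal's standard
#'   deviation (>= 0; 0 collapses to plain EMD).
#' @param ne Ensemble size (>= 1).
#' @param sift_iterations Sifting passes per IMF.
#' @param max_imfs Maximum IMFs, or `NULL` for the dyadic default.
#' @param seed Integer seed for the ensemble noise streams.
#' @return A list of class `eemd_config`.
#' @export
eemd_config <- function(nstd = 0.2, ne = 100, sift_iterations = 10,
                        max_imfs = NULL, seed = 1L) {
  stopifnot(nstd >= 0, ne >= 1, sift_iterations >= 1)
  structure(list(nstd = nstd, ne = as.integer(ne),
                 sift_iterations = as.integer(sift_iterations),
                 max_imfs = max_imfs, seed = as.integer(seed)),
            class = "eemd_config")
}

# Deterministic per-member stream: the first members are unchanged when the
# ensemble grows.
member_seed <- function(seed, j) {
  as.integer(((as.double(seed) %% 65011 + 1) * 104729 + j) %% 2147483646 + 1)
}

#' Ensemble empirical mode decomposition
#'
#' Noise-assisted EMD: the signal plus an independent white-noise draw (sd =
#' `nstd` x sd(signal)) is decomposed `ne` times and the IMFs are averaged
#' index-wise. Members yielding fewer IMFs than others are zero-padded at the
#' slow end before averaging so that fast-IMF indexing is preserved. The
#' returned residual is defined as `signal - sum(averaged IMFs)`, which makes
#' the returned set complete by construction.
#'
#' @param signal A [signal_trace()] or numeric vector.
#' @param config An [eemd_config()].
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return An `imf_set` (see [emd_decompose()]).
#' @examples
#' t <- seq(0, 0.5, by = 1 / 1000)
#' x <- sin(2 * pi * 25 * t) + sin(2 * pi * 150 * t)
#' dec <- eemd_decompose(signal_trace(x, 1000), eemd_config(ne = 10, seed = 7))
#' @export
eemd_decompose <- function(signal, config = eemd_config(), fs = NULL) {
  tr <- if (inherits(signal, "signal_trace")) signal else signal_trace(signal, fs %||% 1)
  x <- tr$samples
  n <- length(x)
  if (n < 10) abort("signal too short to decompose (need >= 10 samples).",
                    class = "emghht_invalid_argument")
  max_imfs <- config$max_imfs %||% max(1L, floor(log2(n)) - 1L)
  noise_sd <- config$nstd * stats::sd(x)
  if (config$nstd == 0 || noise_sd == 0) {
    if (config$ne == 1 || noise_sd == 0) {
      return(emd_decompose(tr, config$sift_iterations, max_imfs))
    }
  }
  noise <- matrix(0, n, config$ne)
  for (j in seq_len(config$ne)) {
    old <- .Random.seed_save()
    set.seed(member_seed(config$seed, j))
    noise[, j] <- rnorm(n, 0, noise_sd)
    .Random.seed_restore(old)
  }
  res <- .eemd_cpp(x, noise, config$sift_iterations, as.integer(max_imfs))
  imfs <- res$imfs
  residual <- x - rowSums(imfs)
  new_imf_set(imfs, residual, fs = tr$fs, t0 = tr$t0)
}

# Keep the caller's RNG state untouched by internal seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
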