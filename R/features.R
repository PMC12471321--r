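#' Reconstruct a signal from its IMFs, residual removed
#'
#' Sums all IMFs, excluding the residual trend. This is the detrended
#' reconstruction on which the RMS amplitude features are computed.
#'
#' @param imfset An `imf_set`.
#' @return A [signal_trace()] (or bare numeric vector when the set carries no
#'   sampling rate).
#' @export
reconstruct_without_residual <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  if (ncol(imfset$imfs) == 0) {
    warn("IMF set is empty; reconstruction is a zero trace.",
         class = "emghht_empty_imfset")
    x <- numeric(imfset$source_length)
  } else {
    x <- rowSums(imfset$imfs)
  }
  if (is.null(imfset$fs)) return(x)
  signal_trace(x, imfset$fs, imfset$t0)
}

#' Co-activation index of the ankle dorsiflexor/plantarflexor pair
#'
#' CI = 2 * EMG_TA / (EMG_GM + EMG_TA) * 100, from window-averaged normalized
#' RMS of tibialis anterior (TA) and medial gastrocnemius (GM). Values above
#' 100% indicate dominant antagonist (TA) activation; below 100%, dominant
#' agonist (GM) activation; the index is bounded in [0, 200].
#'
#' @param emg_ta,emg_gm Non-negative window-mean normalized RMS amplitudes.
#' @return CI in percent.
#' @examples
#' coactivation_index(3, 1)  # 150
#' @export
coactivation_index <- function(emg_ta, emg_gm) {
  if (any(emg_ta < 0) || any(emg_gm < 0)) {
    abort("RMS amplitudes must be non-negative.", class = "emghht_invalid_argument")
  }
  if (any(emg_ta + emg_gm == 0)) {
    abort("both muscles silent; co-activation undefined.",
          class = "emghht_undefined_ci")
  }
  2 * emg_ta / (emg_gm + emg_ta) * 100
}

#' Subject-wise rearfoot-strike amplitude references
#'
#' For each subject and muscle, the mean over that subject's rearfoot-strike
#' trials of the stance-phase peak of the RMS envelope. Used by
#' [normalize_rms()].
#'
#' @param env_table Tibble with columns `subject`, `condition`, `muscle` and
#'   `peak` (stance-phase peak RMS per trial).
#' @return Tibble with `subject`, `muscle`, `reference`.
#' @export
rfs_reference <- function(env_table) {
  env_table |>
    dplyr::filter(.data$condition == "RFS") |>
    dplyr::group_by(.data$subject, .data$muscle) |>
    dplyr::summarise(reference = mean(.data$peak), .groups = "drop")
}

window_mean <- function(x, w) {
  mean(x[w[1]:(w[2] - 1L)])
}

#' Build the per-trial feature table for a cohort
#'
#' Runs the full analysis chain for every trial and muscle: band-pass
#' filtering, EEMD, residual-removed RMS enveloping with rearfoot-strike
#' amplitude normalization, Hilbert spectrum, maximum-energy timing
#' (`s_max_pct`) and frequency (`f_max_hz`), and low/high band powers in the
#' three analysis windows (100 ms pre-contact, 0--20% and 20--40% of
#' stance). Emits one tidy row per (subject, condition, trial, muscle,
#' window), plus one `"TA/GM"` row per (subject, condition, trial, window)
#' holding the co-activation index.
#'
#' @param cohort An `emg_cohort` (or list of `trial_record`s).
#' @param config Analysis configuration; see [default_config()]. `config$seed`
#'   makes the EEMD noise deterministic; `config$muscles` may restrict the
#'   analysis to a subset of channels.
#' @return A tibble with columns `subject`, `condition`, `trial`, `muscle`,
#'   `window`, `rms_pct`, `s_max_pct`, `f_max_hz`, `p_low_raw`, `p_high_raw`,
#'   `p_low`, `p_high`, `ci_pct`. Band powers `p_low`/`p_high` are
#'   percentages of the per-(subject, muscle, window, band) maximum across
#'   conditions. Failed trials are recorded in the `errors` attribute, never
#'   silently dropped.
#' @export
build_feature_table <- function(cohort, config = default_config()) {
  config <- merge_config(config)
  muscles <- config$muscles
  errors <- list()
  per_trial <- list()

  for (ti in seq_along(cohort)) {
    trial <- cohort[[ti]]
    rec <- tryCatch({
      seg <- detect_stance(trial$grf, threshold = config$stance$threshold_n,
                           pre_window = config$stance$pre_window_s)
      wins <- stance_windows(seg)
      ms <- list()
      for (mi in seq_along(muscles)) {
        m <- muscles[mi]
        filt <- bandpass_filter(trial$emg[[m]], low = config$filter$low_hz,
                                high = config$filter$high_hz,
                                order = config$filter$order)
        dec <- eemd_decompose(filt, eemd_config(
          nstd = config$eemd$nstd, ne = config$eemd$ne,
          sift_iterations = config$eemd$sift_iterations,
          seed = seed_chain(config$seed, ti, mi)))
        env <- moving_rms(reconstruct_without_residual(dec),
                          window = config$rms$window_s)
        hs <- hilbert_spectrum(dec, freq_bin_width = config$spectral$freq_bin_width_hz,
                               fmax = config$spectral$fmax_hz)
        mx <- locate_max_energy(hs, seg, smooth_hz = config$spectral$smooth_hz,
                                smooth_s = config$spectral$smooth_s)
        bp <- lapply(wins, function(w) {
          c(low = band_power(hs, c(0, 60), w),
            high = band_power(hs, c(60, 200), w))
        })
        ms[[m]] <- list(env = env$samples,
                        peak = max(env$samples[seg$onset_index:seg$offset_index]),
                        s_max = mx$s_max_pct, f_max = mx$f_max_hz, bands = bp)
      }
      list(seg = seg, wins = wins, muscles = ms)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1]] <- list(trial = ti,
                                           subject = trial$subject_id,
                                           condition = trial$condition,
                                           message = conditionMessage(rec))
    } else {
      per_trial[[as.character(ti)]] <- rec
    }
  }

  ok <- as.integer(names(per_trial))
  peaks <- purrr::map_dfr(ok, function(ti) {
    trial <- cohort[[ti]]
    tibble::tibble(subject = trial$subject_id, condition = trial$condition,
                   muscle = muscles,
                   peak = purrr::map_dbl(per_trial[[as.character(ti)]]$muscles,
                                         "peak"))
  })
  refs <- rfs_reference(peaks)

  rows <- purrr::map_dfr(ok, function(ti) {
    trial <- cohort[[ti]]
    rec <- per_trial[[as.character(ti)]]
    ref_s <- refs[refs$subject == trial$subject_id, ]
    win_rows <- purrr::map_dfr(names(rec$wins), function(wn) {
      w <- rec$wins[[wn]]
      mt <- purrr::map_dfr(muscles, function(m) {
        info <- rec$muscles[[m]]
        ref <- ref_s$reference[ref_s$muscle == m]
        rms_pct <- if (length(ref) == 1 && is.finite(ref) && ref > 0) {
          window_mean(info$env, w) / ref * 100
        } else NA_real_
        tibble::tibble(muscle = m, window = wn, rms_pct = rms_pct,
                       s_max_pct = info$s_max, f_max_hz = info$f_max,
                       p_low_raw = info$bands[[wn]][["low"]],
                       p_high_raw = info$bands[[wn]][["high"]],
                       ci_pct = NA_real_)
      })
      if (all(c("TA", "GM") %in% muscles)) {
        ref_ta <- ref_s$reference[ref_s$muscle == "TA"]
        ref_gm <- ref_s$reference[ref_s$muscle == "GM"]
        ta <- window_mean(rec$muscles[["TA"]]$env, w) / ref_ta
        gm <- window_mean(rec$muscles[["GM"]]$env, w) / ref_gm
        mt <- dplyr::bind_rows(mt, tibble::tibble(
          muscle = "TA/GM", window = wn, rms_pct = NA_real_,
          s_max_pct = NA_real_, f_max_hz = NA_real_,
          p_low_raw = NA_real_, p_high_raw = NA_real_,
          ci_pct = coactivation_index(ta, gm)))
      }
      mt
    })
    dplyr::bind_cols(tibble::tibble(subject = trial$subject_id,
                                    condition = trial$condition,
                                    trial = trial$trial_index)[rep(1, nrow(win_rows)), ],
                     win_rows)
  })

  # band powers as % of the per-(subject, muscle, window, band) maximum
  if (nrow(rows) > 0) {
    long <- rows |>
      dplyr::filter(.data$muscle != "TA/GM") |>
      dplyr::select("subject", "condition", "trial", "muscle", "window",
                    "p_low_raw", "p_high_raw") |>
      tidyr::pivot_longer(c("p_low_raw", "p_high_raw"), names_to = "band",
                          values_to = "power") |>
      normalize_band_power() |>
      dplyr::mutate(band = sub("_raw$", "", .data$band)) |>
      dplyr::select(-"power") |>
      tidyr::pivot_wider(names_from = "band", values_from = "power_pct")
    rows <- dplyr::left_join(
      rows, long,
      by = c("subject", "condition", "trial", "muscle", "window"))
  }
  attr(rows, "errors") <- errors
  attr(rows, "config") <- config
  rows
}
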