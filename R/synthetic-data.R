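MUSCLES <- c("VM", "VL", "RF", "TA", "GM", "GL")
CONDITIONS <- c("FFS", "MFS", "RFS")

# deterministic seed chain for nested (subject, condition, trial, channel) draws
seed_chain <- function(seed, ...) {
  v <- as.double(seed)
  for (k in c(...)) v <- (v * 7919 + as.double(k) + 1) %% 2147483629
  as.integer(v + 1)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Default per-muscle, per-condition burst design
#'
#' Burst parameters that emulate the qualitative activation differences
#' reported for forefoot (FFS), midfoot (MFS) and rearfoot (RFS) strike
#' running: quadriceps and gastrocnemius maximum-energy bursts arrive earlier
#' under RFS (medial gastrocnemius at 30% vs 45% of stance), tibialis
#' anterior pre-activation is strongest under RFS, gastrocnemius
#' pre-activation is strongest under FFS, and the medial gastrocnemius
#' carries relatively more low-band (<= 60 Hz) energy under MFS/RFS versus
#' more high-band (61--200 Hz) energy under FFS.
#'
#' @return A tibble with one row per muscle x condition: `burst_center` and
#'   `burst_width` (fractions of stance), `low_band_gain`, `high_band_gain`,
#'   `pre_activation_gain` (dimensionless amplitudes).
#' @export
default_burst_design <- function() {
  base <- tibble::tibble(
    muscle = rep(MUSCLES, each = 3),
    condition = rep(CONDITIONS, times = length(MUSCLES)),
    burst_center = 0.5, burst_width = 0.15,
    low_band_gain = 1, high_band_gain = 1, pre_activation_gain = 0.2
  )
  set_par <- function(d, m, cond, col, val) {
    d[d$muscle %in% m & d$condition %in% cond, col] <- val
    d
  }
  base |>
    set_par("GM", c("FFS", "MFS"), "burst_center", 0.45) |>
    set_par("GM", "RFS", "burst_center", 0.30) |>
    set_par("GL", c("FFS", "MFS"), "burst_center", 0.45) |>
    set_par("GL", "RFS", "burst_center", 0.32) |>
    set_par(c("VM", "VL"), c("FFS", "MFS"), "burst_center", 0.50) |>
    set_par(c("VM", "VL"), "RFS", "burst_center", 0.35) |>
    set_par("TA", CONDITIONS, "burst_center", 0.15) |>
    set_par("GM", "FFS", "low_band_gain", 0.6) |>
    set_par("GM", "FFS", "high_band_gain", 1.2) |>
    set_par("GM", c("MFS", "RFS"), "low_band_gain", 1.2) |>
    set_par("GM", c("MFS", "RFS"), "high_band_gain", 0.6) |>
    set_par("TA", "RFS", "pre_activation_gain", 0.8) |>
    set_par("TA", "MFS", "pre_activation_gain", 0.4) |>
    set_par("TA", "FFS", "pre_activation_gain", 0.25) |>
    set_par(c("GM", "GL"), "FFS", "pre_activation_gain", 0.5)
}

#' Synthetic cohort design
#'
#' Collects every knob of the synthetic gait generator. Defaults reproduce
#' the study's structure: 16 subjects, 3 conditions, 3 trials each, 1000 Hz
#' sampling, a 250 ms stance, and a 100 ms pre-contact analysis window.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param n_trials_per_condition Trials per condition (default 3).
#' @param fs Sampling rate in Hz (default 1000; must exceed 900 Hz so the
#'   10--450 Hz EMG band is representable).
#' @param stance_duration Stance length in seconds (default 0.25).
#' @param pre_window Pre-contact window in seconds (default 0.100).
#' @param lead_in Zero-force lead-in before contact in seconds (default 0.15).
#' @param tail Zero-force tail in seconds (default 0.05).
#' @param burst_params Per-muscle/condition burst tibble; see
#'   [default_burst_design()].
#' @param noise_sd White measurement-noise standard deviation (default 0.02).
#' @param subject_sd sdlog of the per-subject log-normal gain multipliers
#'   (default 0.2).
#' @param subject_timing_sd Per-subject shift of burst centers, as a fraction
#'   of stance (default 0.02).
#' @param trial_timing_sd Per-trial burst-center jitter, fraction of stance
#'   (default 0.01).
#' @param seed Integer master seed.
#' @return A list of class `effect_design`.
#' @export
effect_design <- function(n_subjects = 16, n_trials_per_condition = 3,
                          fs = 1000, stance_duration = 0.25,
                          pre_window = 0.100, lead_in = 0.15, tail = 0.05,
                          burst_params = default_burst_design(),
                          noise_sd = 0.02, subject_sd = 0.2,
                          subject_timing_sd = 0.02, trial_timing_sd = 0.01,
                          seed = 1L) {
  if (fs <= 2 * 450) abort("`fs` must exceed 900 Hz (2 x 450 Hz).",
                           class = "emghht_invalid_argument")
  stopifnot(n_subjects >= 1, n_trials_per_condition >= 1,
            stance_duration > 0, pre_window > 0, lead_in >= pre_window,
            noise_sd >= 0)
  bp <- tibble::as_tibble(burst_params)
  stopifnot(all(bp$burst_center > 0 & bp$burst_center < 1),
            all(bp$burst_width > 0 & bp$burst_width < 1),
            all(bp$low_band_gain >= 0), all(bp$high_band_gain >= 0),
            all(bp$pre_activation_gain >= 0))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 fs = fs, stance_duration = stance_duration,
                 pre_window = pre_window, lead_in = lead_in, tail = tail,
                 burst_params = bp, noise_sd = noise_sd,
                 subject_sd = subject_sd,
                 subject_timing_sd = subject_timing_sd,
                 trial_timing_sd = trial_timing_sd,
                 seed = as.integer(seed)),
            class = "effect_design")
}

#' Generate a synthetic vertical ground-reaction-force trace
#'
#' One running stance: a zero-force lead-in, a smooth force bump (a
#' half-sine active peak plus a condition-dependent early impact transient --
#' largest for rearfoot strike, absent for forefoot strike), and a zero
#' tail. The true contact onset (first sample at or above 20 N) is stored in
#' the `truth` attribute for recovery tests.
#'
#' @param stance_duration Stance length in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param condition One of `"FFS"`, `"MFS"`, `"RFS"`.
#' @param seed Integer seed (amplitude jitter).
#' @param lead_in,tail Zero-force margins in seconds.
#' @param amplitude Active-peak force scale in newtons (default 1500).
#' @return A [signal_trace()] in newtons with `t0 = -lead_in` and an attached
#'   `truth` attribute (`onset_index`, `offset_index`).
#' @export
generate_grf <- function(stance_duration, fs, condition = "RFS", seed = 1L,
                         lead_in = 0.15, tail = 0.05, amplitude = 1500) {
  if (stance_duration <= 0 || fs <= 0) {
    abort("`stance_duration` and `fs` must be positive.",
          class = "emghht_invalid_argument")
  }
  condition <- match.arg(condition, CONDITIONS)
  n_pre <- as.integer(round(lead_in * fs))
  L <- as.integer(round(stance_duration * fs))
  n_tail <- as.integer(round(tail * fs))
  s <- (seq_len(L) - 0.5) / L
  impact_amp <- c(FFS = 0, MFS = 250, RFS = 500)[[condition]]
  amp <- with_seed(seed, amplitude * exp(rnorm(1, 0, 0.05)))
  force <- amp * sin(pi * s) + impact_amp * exp(-0.5 * ((s - 0.13) / 0.04)^2)
  force <- pmax(force, 0)
  samples <- c(numeric(n_pre), force, numeric(n_tail))
  onset <- n_pre + which(force >= 20)[1]
  offset <- n_pre + max(which(force >= 20))
  out <- signal_trace(samples, fs, t0 = -lead_in)
  attr(out, "truth") <- list(onset_index = onset, offset_index = offset)
  out
}

unit_band_noise <- function(n, fs, low, high) {
  w <- rnorm(n)
  y <- bandpass_filter(signal_trace(w, fs), low = low, high = high)$samples
  y / stats::sd(y)
}

#' Generate one synthetic EMG channel
#'
#' A Gaussian burst envelope (in stance time) modulating a mixture of
#' band-limited noise carriers -- 15--60 Hz for the low band and 80--200 Hz
#' for the high band -- plus a pre-activation burst in the 100 ms before
#' contact (its own 15--200 Hz carrier) and white measurement noise. The
#' true burst-center sample is stored in the `truth` attribute.
#'
#' @param params A one-row data frame (or list) with `burst_center`,
#'   `burst_width` (fractions of stance), `low_band_gain`, `high_band_gain`,
#'   `pre_activation_gain`.
#' @param total_duration Trace duration in seconds.
#' @param onset Contact onset sample index (1-based, within the trace).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param stance_duration Stance length in seconds.
#' @param noise_sd White-noise standard deviation (default 0.02).
#' @param t0 Time of first sample (default 0).
#' @return A [signal_trace()] with a `truth` attribute (`burst_center_index`,
#'   `burst_center_frac`).
#' @export
generate_emg_channel <- function(params, total_duration, onset, fs, seed = 1L,
                                 stance_duration = 0.25, noise_sd = 0.02,
                                 t0 = 0) {
  n <- as.integer(round(total_duration * fs))
  if (onset < 1 || onset > n) {
    abort("`onset` must lie within the trace.", class = "emghht_invalid_argument")
  }
  p <- as.list(params)
  stopifnot(p$low_band_gain >= 0, p$high_band_gain >= 0,
            p$pre_activation_gain >= 0)
  L <- stance_duration * fs
  center <- onset + p$burst_center * L
  sd_samp <- p$burst_width * L
  i <- seq_len(n)
  env <- exp(-0.5 * ((i - center) / sd_samp)^2)
  pre_env <- exp(-0.5 * ((i - (onset - 0.05 * fs)) / (0.025 * fs))^2)
  x <- with_seed(seed, {
    carrier <- 0
    if (p$low_band_gain > 0) {
      carrier <- carrier + p$low_band_gain * unit_band_noise(n, fs, 15, 60)
    } else {
      rnorm(n)  # keep the stream aligned across gain settings
    }
    if (p$high_band_gain > 0) {
      carrier <- carrier + p$high_band_gain * unit_band_noise(n, fs, 80, 200)
    } else {
      rnorm(n)
    }
    pre <- if (p$pre_activation_gain > 0) {
      p$pre_activation_gain * pre_env * unit_band_noise(n, fs, 15, 200)
    } else {
      rnorm(n)
      0
    }
    env * carrier + pre + rnorm(n, 0, noise_sd)
  })
  out <- signal_trace(x, fs, t0 = t0)
  attr(out, "truth") <- list(burst_center_index = center,
                             burst_center_frac = p$burst_center)
  out
}

#' Generate a synthetic cohort of running trials
#'
#' Produces `n_subjects x 3 conditions x n_trials_per_condition` trial
#' records, each with six EMG channels (VM, VL, RF, TA, GM, GL) and a
#' synchronized vertical GRF channel. Per-subject log-normal gain
#' multipliers and small subject/trial burst-timing shifts create realistic
#' repeated-measures structure. Everything is deterministic in
#' `design$seed`.
#'
#' @param design An [effect_design()].
#' @return A list of class `emg_cohort`; each element is a `trial_record`
#'   (list with `emg` -- named list of [signal_trace()] -- `grf`,
#'   `subject_id`, `condition`, `trial_index`, `fs`, `truth`).
#' @examples
#' coh <- generate_cohort(effect_design(n_subjects = 2, n_trials_per_condition = 1,
#'                                      seed = 42))
#' length(coh)  # 2 subjects x 3 conditions x 1 trial
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "effect_design"))
  total_duration <- design$lead_in + design$stance_duration + design$tail
  trials <- list()
  for (s in seq_len(design$n_subjects)) {
    subj_mult <- with_seed(seed_chain(design$seed, s, 0, 0, 0),
                           setNames(rlnorm(length(MUSCLES), 0, design$subject_sd),
                                    MUSCLES))
    subj_shift <- with_seed(seed_chain(design$seed, s, 0, 0, 1),
                            rnorm(1, 0, design$subject_timing_sd))
    for (ci in seq_along(CONDITIONS)) {
      cond <- CONDITIONS[ci]
      for (tr in seq_len(design$n_trials_per_condition)) {
        grf <- generate_grf(design$stance_duration, design$fs, cond,
                            seed = seed_chain(design$seed, s, ci, tr, 2),
                            lead_in = design$lead_in, tail = design$tail)
        onset <- attr(grf, "truth")$onset_index
        emg <- list()
        truth_centers <- numeric(0)
        for (mi in seq_along(MUSCLES)) {
          m <- MUSCLES[mi]
          p <- design$burst_params[design$burst_params$muscle == m &
                                     design$burst_params$condition == cond, ]
          jit <- with_seed(seed_chain(design$seed, s, ci, tr, 100 + mi),
                           rnorm(1, 0, design$trial_timing_sd))
          p$burst_center <- min(0.95, max(0.05, p$burst_center + subj_shift + jit))
          p$low_band_gain <- p$low_band_gain * subj_mult[[m]]
          p$high_band_gain <- p$high_band_gain * subj_mult[[m]]
          p$pre_activation_gain <- p$pre_activation_gain * subj_mult[[m]]
          emg[[m]] <- generate_emg_channel(
            p, total_duration, onset, design$fs,
            seed = seed_chain(design$seed, s, ci, tr, 200 + mi),
            stance_duration = design$stance_duration,
            noise_sd = design$noise_sd, t0 = -design$lead_in)
          truth_centers[m] <- p$burst_center
        }
        trials[[length(trials) + 1]] <- structure(
          list(emg = emg, grf = grf, subject_id = s, condition = cond,
               trial_index = tr, fs = design$fs,
               truth = list(onset_index = onset,
                            burst_center = truth_centers)),
          class = "trial_record")
      }
    }
  }
  structure(trials, class = "emg_cohort", design = design)
}

#' @export
print.emg_cohort <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<emg_cohort> %d trials (%d subjects x 3 conditions x %d trials)\n",
              length(x), d$n_subjects, d$n_trials_per_condition))
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s, %s, trial %d: %d EMG channels + GRF @ %g Hz\n",
              x$subject_id, x$condition, x$trial_index, length(x$emg), x$fs))
  invisible(x)
}

#' @method as_tibble trial_record
#' @export
as_tibble.trial_record <- function(x, ...) {
  out <- tibble::tibble(time_s = trace_time(x$grf))
  for (m in names(x$emg)) out[[m]] <- x$emg[[m]]$samples
  out$GRF_N <- x$grf$samples
  out
}
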