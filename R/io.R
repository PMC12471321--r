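#' Write one trial to CSV
#'
#' Columns: `time_s`, the six muscles (`VM`, `VL`, `RF`, `TA`, `GM`, `GL`),
#' and `GRF_N`.
#'
#' @param trial A `trial_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  readr::write_csv(as_tibble(trial), path)
  invisible(path)
}

#' Read one trial from CSV
#'
#' Expects the dialect written by [write_trial_csv()]. The sampling rate is
#' recovered from the `time_s` column.
#'
#' @param path CSV file path.
#' @param subject_id,condition,trial_index Trial metadata (usually from the
#'   cohort manifest).
#' @return A `trial_record`.
#' @export
read_trial_csv <- function(path, subject_id = NA, condition = NA,
                           trial_index = NA) {
  if (!file.exists(path)) {
    abort(paste0("trial file not found: ", path), class = "emghht_io_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", MUSCLES, "GRF_N")
  if (!all(need %in% names(d))) {
    abort(paste0("trial CSV must have columns: ", paste(need, collapse = ", ")),
          class = "emghht_io_error")
  }
  fs <- 1 / stats::median(diff(d$time_s))
  t0 <- d$time_s[1]
  emg <- lapply(setNames(MUSCLES, MUSCLES),
                function(m) signal_trace(d[[m]], fs, t0))
  structure(list(emg = emg, grf = signal_trace(d$GRF_N, fs, t0),
                 subject_id = subject_id, condition = condition,
                 trial_index = trial_index, fs = fs, truth = NULL),
            class = "trial_record")
}

#' Write a cohort to a directory
#'
#' One CSV per trial plus `manifest.csv` (file, subject, condition, trial
#' index) and a `ground_truth.json` sidecar with the generator's stored
#' onsets and burst centers.
#'
#' @param cohort An `emg_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_along(cohort), function(i) {
    trial <- cohort[[i]]
    file <- sprintf("trial_s%02d_%s_t%d.csv", trial$subject_id,
                    trial$condition, trial$trial_index)
    write_trial_csv(trial, file.path(dir, file))
    tibble::tibble(file = file, subject = trial$subject_id,
                   condition = trial$condition, trial = trial$trial_index)
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  truth <- lapply(cohort, function(trial) {
    list(subject = trial$subject_id, condition = trial$condition,
         trial = trial$trial_index, onset_index = trial$truth$onset_index,
         burst_center = as.list(trial$truth$burst_center))
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_cohort()].
#' @return An `emg_cohort`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(paste0("manifest not found: ", manifest_path), class = "emghht_io_error")
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  trials <- purrr::map(seq_len(nrow(man)), function(i) {
    read_trial_csv(file.path(base, man$file[i]), subject_id = man$subject[i],
                   condition = man$condition[i], trial_index = man$trial[i])
  })
  structure(trials, class = "emg_cohort")
}

#' Export a Hilbert spectrum to CSV with a JSON header
#'
#' Writes the energy matrix (rows = frequency bins, columns = time samples)
#' as CSV and a JSON sidecar (`<path>.json`) holding the frequency edges,
#' time axis and units.
#'
#' @param hs A `hilbert_spectrum`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(hs, path) {
  stopifnot(inherits(hs, "hilbert_spectrum"))
  readr::write_csv(tibble::as_tibble(as.data.frame(hs$energy),
                                     .name_repair = "minimal"), path,
                   col_names = FALSE)
  jsonlite::write_json(
    list(freq_edges_hz = hs$freq_edges,
         time_s = hs$t0 + (seq_len(ncol(hs$energy)) - 1) / hs$fs,
         units = "amplitude^2", fs_hz = hs$fs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export an IMF set to CSV
#'
#' Columns `time_s`, `imf_1` ... `imf_N`, `residual`.
#'
#' @param imfset An `imf_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imfset_csv <- function(imfset, path) {
  readr::write_csv(as_tibble(imfset), path)
  invisible(path)
}
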