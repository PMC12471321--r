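#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their conventional values:
#' 10--450 Hz fourth-order zero-phase band-pass, 50 ms moving-RMS window,
#' 20 N contact threshold with a 100 ms pre-contact window, EEMD with noise
#' at 0.2 x signal sd, 100 ensemble members and 10 sifting iterations, 1 Hz
#' Hilbert-spectrum bins up to 500 Hz with a 5 Hz x 10 ms argmax smoothing
#' kernel.
#'
#' @param ... Named overrides, merged recursively (e.g.
#'   `eemd = list(ne = 25)`).
#' @return A nested list of class `emghht_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    filter = list(low_hz = 10, high_hz = 450, order = 4),
    rms = list(window_s = 0.050),
    stance = list(threshold_n = 20, pre_window_s = 0.100),
    eemd = list(nstd = 0.2, ne = 100, sift_iterations = 10),
    spectral = list(freq_bin_width_hz = 1, fmax_hz = 500,
                    smooth_hz = 5, smooth_s = 0.010),
    normalize = list(reference = "rfs_peak_mean"),
    muscles = MUSCLES,
    simulate = list(n_subjects = 16, n_trials_per_condition = 3),
    seed = 1L)
  over <- list(...)
  structure(modify_deep(cfg, over), class = "emghht_config")
}

modify_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- modify_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

merge_config <- function(config) {
  if (inherits(config, "emghht_config")) return(config)
  if (is.null(config)) return(default_config())
  structure(modify_deep(unclass(default_config()), config),
            class = "emghht_config")
}

#' Load a configuration from YAML
#'
#' Reads a YAML file of overrides (keys as in [default_config()], e.g.
#' `filter: {low_hz: 10}`) and merges it onto the defaults.
#'
#' @param path YAML file path.
#' @return An `emghht_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "emghht_io_error")
  }
  over <- yaml::read_yaml(path)
  bad <- setdiff(names(over), names(default_config()))
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
          class = "emghht_config_error")
  }
  structure(modify_deep(unclass(default_config()), over),
            class = "emghht_config")
}

#' Repeated-measures statistics over a feature table
#'
#' For every metric x muscle x window cell of the feature table, averages
#' trials within subject x condition, fits the one-way repeated-measures
#' ANOVA across the three foot-strike conditions, and (always) computes the
#' LSD pairwise comparisons. Cells with incomplete designs are skipped with
#' a note in the `errors` attribute.
#'
#' @param features A feature table from [build_feature_table()].
#' @param metrics Feature columns to analyse (default: RMS, S_max, F_max,
#'   normalized band powers, CI).
#' @return A tibble with one row per metric x muscle x window: `statistic`
#'   (F), `df`, `df.residual`, `p.value`, `eta.p.squared`, condition means,
#'   and unadjusted pairwise p-values `p_FFS_MFS`, `p_FFS_RFS`, `p_MFS_RFS`.
#' @export
analyze_features <- function(features,
                             metrics = c("rms_pct", "s_max_pct", "f_max_hz",
                                         "p_low", "p_high", "ci_pct")) {
  metrics <- intersect(metrics, names(features))
  combos <- features |>
    dplyr::distinct(.data$muscle, .data$window)
  errors <- list()
  out <- purrr::map_dfr(metrics, function(metric) {
    purrr::map_dfr(seq_len(nrow(combos)), function(i) {
      mu <- combos$muscle[i]
      wn <- combos$window[i]
      d <- features |>
        dplyr::filter(.data$muscle == mu, .data$window == wn) |>
        dplyr::transmute(subject = .data$subject, condition = .data$condition,
                         value = .data[[metric]])
      if (all(is.na(d$value))) return(NULL)
      fit <- tryCatch(rm_anova(d), error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[length(errors) + 1]] <<- list(metric = metric, muscle = mu,
                                              window = wn,
                                              message = conditionMessage(fit))
        return(NULL)
      }
      pw <- lsd_pairwise(fit)
      pw_cols <- setNames(pw$p.value,
                          paste0("p_", gsub(" - ", "_", pw$pair)))
      dplyr::bind_cols(
        tibble::tibble(metric = metric, muscle = mu, window = wn),
        glance(fit)[c("statistic", "df", "df.residual", "p.value",
                      "eta.p.squared", "degenerate")],
        tibble::as_tibble(as.list(fit$condition_means)),
        tibble::as_tibble(as.list(pw_cols)))
    })
  })
  attr(out, "errors") <- errors
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> EEMD -> features ->
#' statistics, and writes `features.csv`, `stats.csv`, `qc.csv` and
#' `run_meta.json` into `out_dir`. Reruns with an identical configuration
#' and seed are bit-identical.
#'
#' @param config An `emghht_config`, a list of overrides, or a YAML path.
#' @param out_dir Output directory.
#' @param cohort Optional pre-built `emg_cohort` (skips simulate/load).
#' @param manifest Optional path to a cohort manifest CSV to analyse instead
#'   of simulating.
#' @return Invisibly, a list with the output paths, the feature/stats
#'   tibbles, and `n_failed_trials`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, cohort = NULL,
                         manifest = NULL) {
  if (is.character(config)) config <- load_config(config)
  config <- merge_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- if (!is.null(manifest)) {
      read_cohort(manifest)
    } else {
      sim <- config$simulate
      generate_cohort(effect_design(
        n_subjects = sim$n_subjects %||% 16,
        n_trials_per_condition = sim$n_trials_per_condition %||% 3,
        seed = sim$seed %||% config$seed))
    }
  }
  features <- build_feature_table(cohort, config)
  stats_tbl <- analyze_features(features)
  qc <- purrr::map_dfr(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    seg <- tryCatch(detect_stance(rec$grf,
                                  threshold = config$stance$threshold_n,
                                  pre_window = config$stance$pre_window_s),
                    error = function(e) NULL)
    tibble::tibble(trial = i, subject = rec$subject_id,
                   condition = rec$condition,
                   trial_index = rec$trial_index,
                   stance_detected = !is.null(seg),
                   onset_index = if (is.null(seg)) NA_integer_ else seg$onset_index,
                   stance_ms = if (is.null(seg)) NA_real_ else
                     (seg$offset_index - seg$onset_index + 1) / rec$fs * 1000)
  })
  errs <- attr(features, "errors")
  paths <- list(features = file.path(out_dir, "features.csv"),
                stats = file.path(out_dir, "stats.csv"),
                qc = file.path(out_dir, "qc.csv"),
                meta = file.path(out_dir, "run_meta.json"))
  readr::write_csv(features, paths$features)
  readr::write_csv(stats_tbl, paths$stats)
  readr::write_csv(qc, paths$qc)
  jsonlite::write_json(
    list(config_hash = rlang::hash(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("emghht")),
         n_trials = length(cohort), n_failed_trials = length(errs),
         failures = errs),
    paths$meta, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(paths = paths, features = features, stats = stats_tbl,
                 qc = qc, n_failed_trials = length(errs)))
}
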