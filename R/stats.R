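#' One-way repeated-measures ANOVA across conditions
#'
#' Classical within-subject decomposition for a complete subjects x
#' conditions design, fitted with `stats::aov` using an `Error(subject)`
#' stratum: SS_total splits into SS_subject, SS_condition and SS_error, and
#' F = MS_condition / MS_error with (k - 1, (k - 1)(n - 1)) degrees of
#' freedom. Sphericity is assumed (no correction applied). Multiple trials
#' per cell are averaged within subject x condition before fitting.
#'
#' @param x Either an n_subjects x k_conditions numeric matrix, or a data
#'   frame with columns `subject`, `condition` and `value`.
#' @return An object of class `rm_anova` with elements `F`, `df_condition`,
#'   `df_error`, `p`, `grand_mean`, `condition_means`, `MS_error`,
#'   `SS_condition`, `SS_subject`, `SS_error`, `eta_p` (partial eta squared),
#'   `n_subjects`, `k`, `degenerate`, and the cell-mean matrix `cells`.
#'   When the condition effect is zero, F = 0 and p = 1; when MS_error is
#'   zero with a nonzero effect, the fit is flagged degenerate and p = 0.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5, 4, 5, 6), nrow = 4, byrow = TRUE)
#' colnames(m) <- c("FFS", "MFS", "RFS")
#' rm_anova(m)
#' @export
rm_anova <- function(x) {
  cells <- as_cell_matrix(x)
  n <- nrow(cells)
  k <- ncol(cells)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 conditions.",
                            class = "emghht_invalid_argument")
  d <- data.frame(
    subject = factor(rep(rownames(cells), times = k)),
    condition = factor(rep(colnames(cells), each = n)),
    value = as.vector(cells))
  fit <- stats::aov(value ~ condition + Error(subject), data = d)
  sm <- summary(fit)
  within <- sm[["Error: Within"]][[1]]
  between <- sm[["Error: subject"]][[1]]
  ss_c <- within["condition", "Sum Sq"]
  ss_e <- within["Residuals", "Sum Sq"]
  ss_s <- between["Residuals", "Sum Sq"]
  df_c <- within["condition", "Df"]
  df_e <- within["Residuals", "Df"]
  ms_c <- ss_c / df_c
  ms_e <- ss_e / df_e
  tol <- 1e-12 * max(ss_c + ss_e + ss_s, 1e-300)
  degenerate <- FALSE
  eta_p <- ss_c / (ss_c + ss_e)
  if (ss_c <= tol) {
    Fv <- 0
    p <- 1
    eta_p <- 0
  } else if (ss_e <= tol) {
    Fv <- Inf
    p <- 0
    degenerate <- TRUE
  } else {
    Fv <- ms_c / ms_e
    p <- stats::pf(Fv, df_c, df_e, lower.tail = FALSE)
  }
  structure(list(F = Fv, df_condition = df_c, df_error = df_e, p = p,
                 grand_mean = mean(cells),
                 condition_means = colMeans(cells),
                 MS_error = ms_e, SS_condition = ss_c, SS_subject = ss_s,
                 SS_error = ss_e, eta_p = eta_p,
                 n_subjects = n, k = k, degenerate = degenerate,
                 cells = cells),
            class = "rm_anova")
}

as_cell_matrix <- function(x) {
  if (is.matrix(x)) {
    cells <- x
    if (is.null(colnames(cells))) colnames(cells) <- paste0("C", seq_len(ncol(cells)))
    if (is.null(rownames(cells))) rownames(cells) <- paste0("S", seq_len(nrow(cells)))
  } else {
    stopifnot(is.data.frame(x), all(c("subject", "condition", "value") %in% names(x)))
    agg <- x |>
      dplyr::group_by(.data$subject, .data$condition) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    wide <- tidyr::pivot_wider(agg, names_from = "condition", values_from = "value")
    cells <- as.matrix(wide[, -1, drop = FALSE])
    rownames(cells) <- as.character(wide$subject)
  }
  if (anyNA(cells)) abort("incomplete design: every subject needs every condition.",
                          class = "emghht_incomplete_design")
  cells
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_condition, x$df_error, x$F, x$p,
              if (x$degenerate) " [degenerate: MS_error = 0]" else ""))
  cat("condition means:", paste(sprintf("%s = %.4g", names(x$condition_means),
                                        x$condition_means), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = c("condition", "error"),
    df = c(x$df_condition, x$df_error),
    sumsq = c(x$SS_condition, x$SS_error),
    meansq = c(x$SS_condition / x$df_condition, x$MS_error),
    statistic = c(x$F, NA_real_),
    p.value = c(x$p, NA_real_))
}

#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df = x$df_condition, df.residual = x$df_error,
                 p.value = x$p, eta.p.squared = x$eta_p,
                 n.subjects = x$n_subjects, degenerate = x$degenerate)
}

#' LSD post hoc pairwise comparisons
#'
#' Fisher's least-significant-difference tests for all condition pairs after
#' a repeated-measures ANOVA: t = (mean_a - mean_b) / sqrt(2 * MS_error / n)
#' on the ANOVA's error degrees of freedom, two-sided, with no multiplicity
#' adjustment (the LSD convention).
#'
#' @param anova An [rm_anova()] fit.
#' @return A tibble with columns `pair`, `level_a`, `level_b`, `mean_diff`,
#'   `statistic` (t), `df`, `p.value`, `degenerate`.
#' @export
lsd_pairwise <- function(anova) {
  stopifnot(inherits(anova, "rm_anova"))
  means <- anova$condition_means
  n <- anova$n_subjects
  se <- sqrt(2 * anova$MS_error / n)
  pairs <- utils::combn(names(means), 2)
  tol <- 1e-12 * max(anova$SS_condition + anova$SS_error + anova$SS_subject, 1e-300)
  degenerate <- anova$degenerate || anova$SS_error <= tol || !is.finite(se) || se == 0
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    diff <- means[[a]] - means[[b]]
    if (degenerate) {
      t <- if (diff == 0) 0 else sign(diff) * Inf
      p <- if (diff == 0) 1 else 0
    } else {
      t <- diff / se
      p <- 2 * stats::pt(-abs(t), anova$df_error)
    }
    tibble::tibble(pair = paste(a, "-", b), level_a = a, level_b = b,
                   mean_diff = diff, statistic = t, df = anova$df_error,
                   p.value = p, degenerate = degenerate)
  })
}
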