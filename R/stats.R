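#' RMS accuracy error of measurements against a reference
#'
#' Root mean square of the individual relative differences between measured
#' volumes and their reference (direct) volumes, in percent:
#' `sqrt(mean(((m - r) / r)^2)) * 100`. Scale-invariant: rescaling all
#' volumes by a common positive factor leaves it unchanged.
#'
#' @param measured,reference Equal-length numeric vectors (ml);
#'   `reference` must be strictly positive.
#' @return RMS relative error in percent.
#' @export
#' @examples
#' rms_relative_error(c(110, 90), c(100, 100))   # 10
rms_relative_error <- function(measured, reference) {
  if (length(measured) != length(reference) || length(measured) < 1L) {
    stop_adiposim("`measured` and `reference` must have equal length >= 1.",
                  "adiposim_stats_error")
  }
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop_adiposim("`reference` volumes must be positive.",
                  "adiposim_stats_error")
  }
  sqrt(mean(((measured - reference) / reference)^2)) * 100
}

#' Accuracy report for one method/condition cell
#'
#' Bundles the accuracy statistics computed for one segmentation method
#' under one acquisition condition: the RMS relative error, the squared
#' Pearson correlation against the reference volumes, the mean signed
#' relative difference (over/under-estimation direction), and the per-item
#' relative differences.
#'
#' @inheritParams rms_relative_error
#' @return An `accuracy_report`; see [tidy()] / [glance()] methods.
#' @export
accuracy_report <- function(measured, reference) {
  rel <- (measured - reference) / reference
  structure(
    list(
      rms_relative_error = rms_relative_error(measured, reference),
      pearson_r2 = if (length(measured) >= 3L &&
                       stats::sd(measured) > 0 && stats::sd(reference) > 0) {
        pearson_r2(measured, reference)
      } else {
        NA_real_
      },
      mean_signed_error = mean(rel) * 100,
      relative_differences = rel * 100,
      n = length(measured)
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n = %d, RMS %.2f%%, mean signed %.2f%%, r2 %.3f\n",
              x$n, x$rms_relative_error, x$mean_signed_error, x$pearson_r2))
  invisible(x)
}

#' Reproducibility report: RMS of per-subject coefficients of variation
#'
#' For repeated measurements of each subject, computes the per-subject
#' coefficient of variation (sample standard deviation of the repeats
#' divided by their mean) and aggregates them as a root mean square across
#' subjects, in percent. The degrees of freedom follow the repeat design:
#' `df = sum over subjects of (n_scans - 1)`.
#'
#' Subjects with fewer than 2 repeats are excluded with a warning and do not
#' contribute to the df.
#'
#' @param table A data frame with at least `subject_id` and `volume_ml`
#'   columns (one row per scan repeat). All volumes must be positive.
#' @return A `repro_report` with `rms_cv` (%), `df`, per-subject CVs
#'   (a tibble), `n_subjects` and `n_scans`; see [tidy()] / [glance()].
#' @export
#' @examples
#' tb <- tibble::tibble(subject_id = rep(1:7, each = 3),
#'                      volume_ml = rnorm(21, 2000, 50))
#' reproducibility_rms_cv(tb)$df   # 7 * (3 - 1) = 14
reproducibility_rms_cv <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "volume_ml") %in% names(table)))
  if (any(!is.finite(table$volume_ml)) || any(table$volume_ml <= 0)) {
    stop_adiposim("All volumes must be positive.", "adiposim_stats_error")
  }
  per <- table |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_scans = dplyr::n(),
      mean_ml = mean(.data$volume_ml),
      sd_ml = stats::sd(.data$volume_ml),
      cv = .data$sd_ml / .data$mean_ml,
      .groups = "drop"
    )
  dropped <- per |> dplyr::filter(.data$n_scans < 2L)
  if (nrow(dropped) > 0L) {
    warning(sprintf("%d subject(s) with < 2 repeats excluded from the CV.",
                    nrow(dropped)), call. = FALSE)
    per <- per |> dplyr::filter(.data$n_scans >= 2L)
  }
  if (nrow(per) == 0L) {
    stop_adiposim("No subject has >= 2 repeats.", "adiposim_stats_error")
  }
  structure(
    list(
      rms_cv = sqrt(mean(per$cv^2)) * 100,
      df = sum(per$n_scans - 1L),
      per_subject = per,
      n_subjects = nrow(per),
      n_scans = sum(per$n_scans)
    ),
    class = "repro_report"
  )
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("<repro_report> %d subjects, %d scans (df = %d): RMS-CV %.2f%%\n",
              x$n_subjects, x$n_scans, x$df, x$rms_cv))
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, non-zero variance.
#' @return r^2.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_adiposim("Need equal-length vectors with n >= 3.",
                  "adiposim_stats_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_adiposim("Zero variance: correlation undefined.",
                  "adiposim_stats_error")
  }
  stats::cor(x, y)^2
}

#' Compare two correlation coefficients (Fisher z transformation)
#'
#' Two-sided p-value for the difference of two independent Pearson
#' correlations: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (each >= 4).
#' @return Two-sided p-value.
#' @export
#' @examples
#' compare_correlations_fisher_z(0.9, 50, 0.3, 50)   # < 0.001
compare_correlations_fisher_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop_adiposim("Correlations must satisfy |r| < 1.",
                  "adiposim_stats_error")
  }
  if (n1 < 4L || n2 < 4L) {
    stop_adiposim("Need n >= 4 in both groups.", "adiposim_stats_error")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

#' Paired two-sided t test for related samples
#'
#' Thin wrapper around the standard paired t test that flags the degenerate
#' zero-variance case (identical pairwise differences, including `a == b`)
#' instead of returning an undefined statistic.
#'
#' @param a,b Paired numeric vectors of equal length (>= 2).
#' @return One-row tibble with `estimate` (mean difference), `statistic`,
#'   `df`, `p_value` and `zero_variance`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop_adiposim("Need paired vectors of equal length >= 2.",
                  "adiposim_stats_error")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(estimate = mean(d), statistic = NA_real_,
                          df = length(d) - 1L, p_value = NA_real_,
                          zero_variance = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 zero_variance = FALSE)
}

#' Kolmogorov-Smirnov check against a fitted normal distribution
#'
#' One-sample KS statistic of `x` against a normal distribution with the
#' sample mean and standard deviation. Because the parameters are estimated
#' from the sample, the p-value is conservative for rejecting normality; it
#' is used as the study used it, as a screen before applying t tests.
#'
#' @param x Numeric vector, `n >= 5`.
#' @return One-row tibble with `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5L) {
    stop_adiposim("Need n >= 5 for the KS check.", "adiposim_stats_error")
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n = length(x))
}
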