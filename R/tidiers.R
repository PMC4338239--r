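#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy method for accuracy reports
#'
#' @param x An [accuracy_report()].
#' @param ... Unused.
#' @return One row per measured item with its signed relative difference (%).
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  tibble::tibble(item = seq_len(x$n),
                 relative_difference_pct = x$relative_differences)
}

#' @rdname tidy.accuracy_report
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(rms_relative_error_pct = x$rms_relative_error,
                 pearson_r2 = x$pearson_r2,
                 mean_signed_error_pct = x$mean_signed_error,
                 n = x$n)
}

#' Tidy method for reproducibility reports
#'
#' @param x A [reproducibility_rms_cv()] report.
#' @param ... Unused.
#' @return `tidy()`: one row per subject with its coefficient of variation;
#'   `glance()`: one row with the RMS-CV, df and design sizes.
#' @method tidy repro_report
#' @export
tidy.repro_report <- function(x, ...) {
  x$per_subject
}

#' @rdname tidy.repro_report
#' @method glance repro_report
#' @export
glance.repro_report <- function(x, ...) {
  tibble::tibble(rms_cv_pct = x$rms_cv, df = x$df,
                 n_subjects = x$n_subjects, n_scans = x$n_scans)
}

#' @method tidy phantom_accuracy_study
#' @export
tidy.phantom_accuracy_study <- function(x, ...) x$accuracy

#' @method glance phantom_accuracy_study
#' @export
glance.phantom_accuracy_study <- function(x, ...) {
  tibble::tibble(
    n_phantoms = x$config$n_phantoms,
    n_measurements = nrow(x$measurements),
    best_rms_error_pct = min(x$accuracy$rms_error_pct),
    best_cell = paste(x$accuracy[which.min(x$accuracy$rms_error_pct),
                                 c("method", "sequence", "motion")],
                      collapse = "/")
  )
}

#' @method tidy infant_repro_study
#' @export
tidy.infant_repro_study <- function(x, ...) x$reproducibility

#' @method glance infant_repro_study
#' @export
glance.infant_repro_study <- function(x, ...) {
  total <- x$reproducibility |>
    dplyr::filter(.data$compartment == "total")
  tibble::tibble(
    n_measurements = nrow(x$measurements),
    worst_total_rms_cv_pct = max(total$rms_cv_pct),
    best_total_rms_cv_pct = min(total$rms_cv_pct)
  )
}
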