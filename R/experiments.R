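#' Configuration of an in-silico accuracy / reproducibility study
#'
#' The defaults reproduce the validation study's design sizes: ten phantoms
#' with fat volumes spanning 54-300 ml for the accuracy arm, and a repeat
#' design of 3 scans in each of 7 subjects (cartesian sequence; df = 14)
#' plus 4 + 3 + 3 + 3 scans in 4 subjects (PROPELLER sequence; df = 9) for
#' the reproducibility arm, one subject participating in both arms.
#'
#' @param study `"phantom_accuracy"` or `"infant_reproducibility"`.
#' @param n_phantoms Number of phantoms (default 10).
#' @param volume_range Range of target phantom fat volumes in ml
#'   (default 54-300).
#' @param sequences Character subset of `c("cartesian", "propeller")`.
#' @param motion_modes Character subset of `c("motionless", "breathing")`
#'   (phantom study only; infant scans always breathe).
#' @param methods Segmentation methods for the phantom study: `"kmeans"`
#'   and/or `"thrNNN"` strings (default kmeans + thresholds 150/250/350).
#' @param infant_methods Segmentation methods for the infant study
#'   (default kmeans + thr150 + thr250, as only these remained in vivo).
#' @param cartesian_repeats,propeller_repeats Integer vectors of repeats per
#'   subject in each arm.
#' @param breathing_amplitude Breathing displacement amplitude in mm
#'   (default 2.5).
#' @param jitter_sd Per-repeat rigid repositioning jitter sd in mm
#'   (default 0.4).
#' @param intensity_model An [intensity_model()].
#' @param supersample Rendering supersampling factor (default 5).
#' @param seed Master seed; every spec, render, artifact and jitter seed is
#'   derived from it deterministically.
#' @param out_dir Optional directory for CSV/JSON reports.
#' @param verbose Emit per-stage progress messages (default `TRUE`).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(study = c("phantom_accuracy",
                                        "infant_reproducibility"),
                              n_phantoms = 10L,
                              volume_range = c(54, 300),
                              sequences = c("cartesian", "propeller"),
                              motion_modes = c("motionless", "breathing"),
                              methods = c("kmeans", "thr150", "thr250",
                                          "thr350"),
                              infant_methods = c("kmeans", "thr150",
                                                 "thr250"),
                              cartesian_repeats = rep(3L, 7L),
                              propeller_repeats = c(4L, 3L, 3L, 3L),
                              breathing_amplitude = 2.5,
                              jitter_sd = 0.4,
                              intensity_model = adiposim::intensity_model(),
                              supersample = 5L,
                              seed = 1L,
                              out_dir = NULL,
                              verbose = TRUE) {
  study <- match.arg(study)
  sequences <- match.arg(sequences, several.ok = TRUE)
  motion_modes <- match.arg(motion_modes, several.ok = TRUE)
  if (n_phantoms < 1L || volume_range[1] < 20 || volume_range[2] > 500 ||
      volume_range[1] >= volume_range[2]) {
    stop_adiposim("Invalid phantom design.", "adiposim_config_error")
  }
  ok_method <- function(m) m == "kmeans" | grepl("^thr[0-9]+$", m)
  if (!all(ok_method(methods)) || !all(ok_method(infant_methods))) {
    stop_adiposim("Methods must be 'kmeans' or 'thrNNN'.",
                  "adiposim_config_error")
  }
  structure(
    list(study = study, n_phantoms = as.integer(n_phantoms),
         volume_range = as.numeric(volume_range), sequences = sequences,
         motion_modes = motion_modes, methods = methods,
         infant_methods = infant_methods,
         cartesian_repeats = as.integer(cartesian_repeats),
         propeller_repeats = as.integer(propeller_repeats),
         breathing_amplitude = breathing_amplitude,
         jitter_sd = jitter_sd,
         intensity_model = intensity_model,
         supersample = as.integer(supersample),
         seed = as.integer(seed), out_dir = out_dir,
         verbose = isTRUE(verbose)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [experiment_config()]; unspecified keys keep their defaults. The
#' `intensity_model` key, if present, is a mapping passed to
#' [intensity_model()].
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$intensity_model)) {
    raw$intensity_model <- do.call(intensity_model, raw$intensity_model)
  }
  do.call(experiment_config, raw)
}

segment_with_method <- function(image, method) {
  if (method == "kmeans") {
    kmeans_segment(image)
  } else {
    thr <- as.numeric(sub("^thr", "", method))
    threshold_segment(image, threshold_config(threshold = thr))
  }
}

log_stage <- function(config, ...) {
  if (config$verbose) message("[adiposim] ", sprintf(...))
}

artifact_for_sequence <- function(sequence) {
  if (sequence == "cartesian") "cartesian_ghost" else "propeller_blur"
}

#' Run the in-silico phantom accuracy study
#'
#' Generates the configured phantoms, renders them motionless with both
#' sequence geometries, applies the breathing-artifact surrogate for the
#' breathing condition, segments every image with every configured method,
#' and computes per-cell accuracy statistics (RMS relative error against the
#' analytic true volumes, Pearson r^2, mean signed error) for the
#' method x sequence x motion grid. Fully seeded and deterministic.
#'
#' @param config An [experiment_config()].
#' @return A `phantom_accuracy_study`: list with `measurements` (long
#'   tibble), `accuracy` (one row per grid cell), `specs` and `config`.
#'   When `config$out_dir` is set, CSV and JSON reports are written there.
#' @export
run_phantom_accuracy <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_phantoms
  targets <- seq(config$volume_range[1], config$volume_range[2],
                 length.out = n)
  seeds <- derive_seeds(config$seed, n * (1L + 2L * length(config$sequences)))
  spec_seeds <- seeds[seq_len(n)]
  log_stage(config, "building %d phantom specs (%.0f-%.0f ml)", n,
            min(targets), max(targets))
  specs <- purrr::map2(targets, spec_seeds, build_phantom_spec)
  truth <- purrr::map_dbl(specs, analytic_fat_volume)

  rows <- list()
  seed_i <- n
  for (seq_name in config$sequences) {
    geometry <- phantom_geometry(seq_name)
    for (p in seq_len(n)) {
      render_seed <- seeds[seed_i <- seed_i + 1L]
      artifact_seed <- seeds[seed_i <- seed_i + 1L]
      log_stage(config, "rendering phantom %d/%d (%s)", p, n, seq_name)
      base <- render(specs[[p]], geometry, config$intensity_model,
                     rng_seed = render_seed,
                     supersample = config$supersample)
      images <- list()
      if ("motionless" %in% config$motion_modes) {
        images$motionless <- base
      }
      if ("breathing" %in% config$motion_modes) {
        images$breathing <- apply_breathing_artifact(
          base, artifact_for_sequence(seq_name),
          config$breathing_amplitude, rng_seed = artifact_seed
        )
      }
      for (motion in names(images)) {
        for (method in config$methods) {
          mask <- segment_with_method(images[[motion]], method)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            phantom_id = p, sequence = seq_name, motion = motion,
            method = method, volume_ml = mask_volume(mask),
            true_ml = truth[p], spec_seed = spec_seeds[p],
            render_seed = render_seed
          )
        }
      }
    }
  }
  measurements <- dplyr::bind_rows(rows)
  accuracy <- measurements |>
    dplyr::group_by(.data$sequence, .data$motion, .data$method) |>
    dplyr::summarise(
      rms_error_pct = rms_relative_error(.data$volume_ml, .data$true_ml),
      pearson_r2 = if (dplyr::n() >= 3L && stats::sd(.data$volume_ml) > 0 &&
                       stats::sd(.data$true_ml) > 0) {
        pearson_r2(.data$volume_ml, .data$true_ml)
      } else {
        NA_real_
      },
      mean_signed_pct = mean((.data$volume_ml - .data$true_ml) /
                               .data$true_ml) * 100,
      n = dplyr::n(),
      .groups = "drop"
    )
  out <- structure(
    list(measurements = measurements, accuracy = accuracy, specs = specs,
         config = config),
    class = "phantom_accuracy_study"
  )
  if (!is.null(config$out_dir)) {
    write_phantom_reports(out, config$out_dir)
  }
  out
}

#' @export
print.phantom_accuracy_study <- function(x, ...) {
  cat("<phantom_accuracy_study>", nrow(x$measurements), "measurements\n")
  print(x$accuracy, n = Inf)
  invisible(x)
}

write_phantom_reports <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$measurements,
                   file.path(dir, "phantom_measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(study$accuracy, file.path(dir, "phantom_accuracy.csv"),
                   row.names = FALSE)
  wide <- study$accuracy |>
    dplyr::mutate(cell = paste(.data$sequence, .data$motion, sep = "_")) |>
    dplyr::select("method", "cell", "rms_error_pct") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "rms_error_pct")
  utils::write.csv(wide, file.path(dir, "phantom_accuracy_wide.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$accuracy, file.path(dir, "phantom_accuracy.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Run the in-silico infant reproducibility study
#'
#' Generates synthetic infant specs, renders the configured repeat series
#' for each arm (independent noise, breathing-artifact realization and
#' repositioning jitter per repeat), segments every repeat with the
#' configured methods, separates fat compartments for the k-means pipeline
#' (the only method for which the separation is performed), and computes the
#' RMS-CV reproducibility error per sequence x method x compartment with the
#' repeat-design degrees of freedom.
#'
#' @param config An [experiment_config()].
#' @return An `infant_repro_study`: list with `measurements` (long tibble),
#'   `reproducibility` (one row per cell with `rms_cv_pct`, `df`, sizes),
#'   `specs` and `config`.
#' @export
run_infant_reproducibility <- function(config = experiment_config(
  study = "infant_reproducibility")) {
  stopifnot(inherits(config, "experiment_config"))
  arms <- list()
  if ("cartesian" %in% config$sequences &&
      length(config$cartesian_repeats) > 0L) {
    arms$cartesian <- config$cartesian_repeats
  }
  if ("propeller" %in% config$sequences &&
      length(config$propeller_repeats) > 0L) {
    arms$propeller <- config$propeller_repeats
  }
  n_subj <- sum(lengths(arms))
  seeds <- derive_seeds(config$seed + 1L, 2L * n_subj)
  rows <- list()
  si <- 0L
  for (arm in names(arms)) {
    geometry <- infant_geometry(arm)
    repeats <- arms[[arm]]
    for (s in seq_along(repeats)) {
      si <- si + 1L
      # the first propeller subject is the first cartesian subject re-scanned
      # (one infant took part in both arms of the repeat design)
      spec_seed <- if (arm == "propeller" && s == 1L &&
                       !is.null(arms$cartesian)) {
        seeds[1L]
      } else {
        seeds[2L * si - 1L]
      }
      series_seed <- seeds[2L * si]
      spec <- build_infant_spec(rng_seed = spec_seed)
      log_stage(config, "rendering %d repeats of infant %s-%d (%.0f ml fat)",
                repeats[s], arm, s, spec$true_fat_volume)
      images <- render_repeat_series(
        spec, geometry, config$intensity_model, n_repeats = repeats[s],
        rng_seed = series_seed, artifact_mode = artifact_for_sequence(arm),
        artifact_amplitude = config$breathing_amplitude,
        jitter_sd = config$jitter_sd, supersample = config$supersample
      )
      for (r in seq_along(images)) {
        for (method in config$infant_methods) {
          mask <- segment_with_method(images[[r]], method)
          if (method == "kmeans") {
            mask <- split_compartments(mask, images[[r]])
          }
          rows[[length(rows) + 1L]] <- measure_mask(
            mask, subject_id = paste0(arm, "-", s), repeat_idx = r,
            method = method, sequence_mode = arm
          ) |>
            dplyr::mutate(true_total_ml = spec$true_fat_volume,
                          spec_seed = spec_seed)
        }
      }
    }
  }
  measurements <- dplyr::bind_rows(rows)
  reproducibility <- measurements |>
    dplyr::group_by(.data$sequence_mode, .data$method, .data$compartment) |>
    dplyr::group_modify(function(d, key) {
      rep_report <- reproducibility_rms_cv(d)
      tibble::tibble(rms_cv_pct = rep_report$rms_cv, df = rep_report$df,
                     n_subjects = rep_report$n_subjects,
                     n_scans = rep_report$n_scans)
    }) |>
    dplyr::ungroup()
  out <- structure(
    list(measurements = measurements, reproducibility = reproducibility,
         config = config),
    class = "infant_repro_study"
  )
  if (!is.null(config$out_dir)) {
    write_infant_reports(out, config$out_dir)
  }
  out
}

#' @export
print.infant_repro_study <- function(x, ...) {
  cat("<infant_repro_study>", nrow(x$measurements), "measurements\n")
  print(x$reproducibility, n = Inf)
  invisible(x)
}

write_infant_reports <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$measurements,
                   file.path(dir, "infant_measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(study$reproducibility,
                   file.path(dir, "infant_reproducibility.csv"),
                   row.names = FALSE)
  wide <- study$reproducibility |>
    dplyr::mutate(cell = paste(.data$compartment, .data$sequence_mode,
                               sep = "_")) |>
    dplyr::select("method", "cell", "rms_cv_pct") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "rms_cv_pct")
  utils::write.csv(wide, file.path(dir, "infant_reproducibility_wide.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$reproducibility,
                       file.path(dir, "infant_reproducibility.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
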