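# End-to-end orchestration: simulate -> reconstruct -> extract -> screen ->
# equivalence, with optional on-disk outputs and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the simulate/reconstruct/extract/stats chain in
#' one serializable list. Defaults are the study constants: 2.24 Hz, 25/32 mm,
#' four wavelengths, 30 s segments, a 20 s baseline window, SNR cutoff 1 dB,
#' the 2-SD outlier rule, alpha 0.05 and the published threshold table.
#'
#' @param n_subjects,trials_per_subject Cohort design.
#' @param correlation Between-location parameter correlation.
#' @param snr_threshold Trial-selection SNR cutoff, dB.
#' @param smooth_window,prominence_frac Extremum-detection settings.
#' @param detrend Remove per-channel linear drift before unmixing.
#' @param alpha,m Equivalence level and Bonferroni multiplicity.
#' @param thresholds Named equivalence thresholds.
#' @param seed RNG seed.
#' @return List of class `nirs_config`.
#' @export
pipeline_config <- function(n_subjects = 20, trials_per_subject = 3,
                            correlation = 0.5, snr_threshold = 1,
                            smooth_window = 3, prominence_frac = 0.2,
                            detrend = FALSE, alpha = 0.05, m = 4,
                            thresholds = default_equivalence_thresholds(),
                            seed = 1) {
  cfg <- list(
    n_subjects = n_subjects, trials_per_subject = trials_per_subject,
    correlation = correlation, snr_threshold = snr_threshold,
    smooth_window = smooth_window, prominence_frac = prominence_frac,
    detrend = detrend, alpha = alpha, m = m, thresholds = thresholds,
    seed = seed
  )
  required <- c("n_subjects", "trials_per_subject", "seed")
  missing <- required[vapply(cfg[required], is.null, logical(1))]
  if (length(missing)) {
    stop("config missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "nirs_config")
}

#' Run the full pipeline on one seed
#'
#' Simulates a cohort, reconstructs every trial, extracts and screens the
#' six parameters of interest, and runs the equivalence battery. When
#' `out_dir` is given, writes the stage tables (CSV), the equivalence results
#' (CSV + JSON), a plain-text summary in `MoD [95% CI]; p` format, and a
#' manifest (seed, package version, stage row counts and content hashes).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param noise A [noise_model()].
#' @return List of class `nirs_pipeline` with `cohort`, `reconstruction`,
#'   `features`, `screened`, `results`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         noise = noise_model()) {
  cohort <- generate_cohort(
    n_subjects = config$n_subjects,
    trials_per_subject = config$trials_per_subject,
    correlation = config$correlation,
    noise = noise,
    seed = config$seed
  )
  recon <- reconstruct_cohort(cohort, detrend = config$detrend)
  features <- extract_features(
    recon,
    snr_threshold = config$snr_threshold,
    smooth_window = config$smooth_window,
    prominence_frac = config$prominence_frac
  )
  screened <- screen_outliers(features)
  results <- equivalence_battery(
    screened, thresholds = config$thresholds,
    alpha = config$alpha, m = config$m, profiles = cohort$profiles
  )
  out <- structure(
    list(cohort = cohort, reconstruction = recon, features = features,
         screened = screened, results = results, config = config),
    class = "nirs_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    path
  }
  paths <- c(
    w(pipeline$cohort$profiles, "profiles.csv"),
    w(pipeline$cohort$recordings, "recordings.csv"),
    w(pipeline$cohort$truth, "truth.csv"),
    w(pipeline$reconstruction$traces, "traces.csv"),
    w(pipeline$features, "features.csv"),
    w(pipeline$screened, "features_screened.csv"),
    w(pipeline$results$equivalence, "equivalence.csv")
  )
  jsonlite::write_json(
    list(
      equivalence = pipeline$results$equivalence,
      correlations = pipeline$results$correlations,
      group_effects = pipeline$results$group_effects,
      skipped = pipeline$results$skipped
    ),
    file.path(out_dir, "results.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    package = "carotidnirs",
    version = as.character(utils::packageVersion("carotidnirs")),
    seed = pipeline$config$seed,
    n_subjects = pipeline$config$n_subjects,
    trials_per_subject = pipeline$config$trials_per_subject,
    stages = lapply(
      list(recordings = pipeline$cohort$recordings,
           traces = pipeline$reconstruction$traces,
           features = pipeline$features,
           equivalence = pipeline$results$equivalence),
      function(df) list(rows = nrow(df), hash = rlang::hash(df))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(pipeline_summary(pipeline), file.path(out_dir, "summary.txt"))
  invisible(paths)
}

#' Plain-text summary of pipeline results
#'
#' One line per comparison in the reporting format `MoD [95% CI]; p`.
#'
#' @param pipeline A [run_pipeline()] result.
#' @return Character vector of lines.
#' @export
pipeline_summary <- function(pipeline) {
  eq <- pipeline$results$equivalence
  n_series <- nrow(dplyr::distinct(pipeline$cohort$recordings,
                                   .data$subject_id, .data$location))
  header <- c(
    sprintf("cohort: %d subjects x %d locations = %d artery-level series",
            pipeline$config$n_subjects,
            length(unique(pipeline$cohort$recordings$location)), n_series),
    sprintf("excluded locations: %d", sum(pipeline$features$excluded)),
    ""
  )
  lines <- vapply(seq_len(nrow(eq)), function(i) {
    r <- eq[i, ]
    sprintf("%s | %s: MoD %.3g [%.3g, %.3g]; p = %.3g%s",
            r$parameter, r$pair, r$mod, r$ci_low, r$ci_high, r$p_adjusted,
            if (r$equivalent) " (equivalent)" else "")
  }, character(1))
  c(header, lines)
}

#' @export
print.nirs_pipeline <- function(x, ...) {
  cat(pipeline_summary(x), sep = "\n")
  invisible(x)
}

#' Validate a recordings table
#'
#' Structural checks on a long-format recordings table (or CSV path):
#' required columns, positive intensities, key uniqueness over subject x
#' location x trial x channel x time, and monotone time within each trial.
#' Violations are returned, never silently coerced.
#'
#' @param recordings Data frame or path to a CSV file.
#' @return Tibble of violations (`check`, `detail`); zero rows when valid.
#' @export
validate_recordings <- function(recordings) {
  if (is.character(recordings)) {
    if (!file.exists(recordings)) stop("file not found: ", recordings, call. = FALSE)
    recordings <- readr::read_csv(recordings, show_col_types = FALSE)
  }
  v <- list()
  need <- c("subject_id", "location", "trial", "time_s", "wavelength_nm",
            "distance_mm", "intensity")
  miss <- setdiff(need, names(recordings))
  if (length(miss)) {
    v[[length(v) + 1]] <- tibble(
      check = "columns", detail = paste("missing:", paste(miss, collapse = ", "))
    )
    return(dplyr::bind_rows(v))
  }
  if (any(!is.finite(recordings$intensity) | recordings$intensity <= 0)) {
    v[[length(v) + 1]] <- tibble(
      check = "domain",
      detail = sprintf("%d non-positive or non-finite intensities",
                       sum(!is.finite(recordings$intensity) |
                             recordings$intensity <= 0))
    )
  }
  dup <- recordings |>
    dplyr::count(.data$subject_id, .data$location, .data$trial,
                 .data$wavelength_nm, .data$distance_mm, .data$time_s) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    v[[length(v) + 1]] <- tibble(
      check = "duplicate key",
      detail = sprintf("%d duplicated (subject, location, trial, channel, time) keys",
                       nrow(dup))
    )
  }
  nonmono <- recordings |>
    dplyr::group_by(.data$subject_id, .data$location, .data$trial,
                    .data$wavelength_nm, .data$distance_mm) |>
    dplyr::summarise(mono = !is.unsorted(.data$time_s), .groups = "drop") |>
    dplyr::filter(!.data$mono)
  if (nrow(nonmono) > 0) {
    v[[length(v) + 1]] <- tibble(
      check = "time order",
      detail = sprintf("%d channels with non-monotone time", nrow(nonmono))
    )
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble(check = character(0), detail = character(0))
}
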