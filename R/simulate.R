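# Synthetic cohort generation: latent hemodynamic truth following the
# breathing protocol, forward-modelled into noisy raw patch intensities.

with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# moving-average low-pass of white noise, rescaled to a target sd
lowpass_noise <- function(n, sd_target, window = 11) {
  if (sd_target <= 0) return(rep(0, n))
  x <- as.numeric(stats::filter(rnorm(n + 2 * window), rep(1 / window, window),
                                sides = 2))
  x <- x[(window + 1):(window + n)]
  x * sd_target / stats::sd(x)
}

#' Measurement and physiology noise model
#'
#' Groups every stochastic nuisance the generator can inject: slow
#' physiological fluctuation on the latent traces, per-cycle amplitude jitter
#' of the deep-breathing oscillation, and instrument effects on the raw
#' intensities (multiplicative photon noise, slow gain drift, and
#' motion-artifact bumps shared across a patch's channels).
#'
#' @param physio_hbt_sd_uM,physio_sto2_sd_pct SD of low-pass physiological
#'   fluctuation added to the latent HbT (uM) and StO2 (% points) traces.
#' @param amplitude_cv Coefficient of variation of per-half-cycle amplitude
#'   jitter of the deep-breathing oscillations.
#' @param multiplicative_sd SD of per-sample multiplicative intensity noise.
#' @param additive_sd Additive intensity noise SD, as a fraction of the
#'   channel's median intensity.
#' @param drift_frac Peak-to-peak fractional gain drift over one trial.
#' @param artifact_rate_hz Poisson rate of motion-artifact events.
#' @param artifact_amp Fractional amplitude of an artifact bump.
#' @param artifact_duration_s Artifact full width, s.
#' @param intensity_floor Clip floor for non-positive intensities.
#' @return Object of class `nirs_noise_model`.
#' @export
noise_model <- function(physio_hbt_sd_uM = 0.1, physio_sto2_sd_pct = 0.03,
                        amplitude_cv = 0.1,
                        multiplicative_sd = 0.001, additive_sd = 0,
                        drift_frac = 0.005, artifact_rate_hz = 0.01,
                        artifact_amp = 0.02, artifact_duration_s = 1,
                        intensity_floor = 1e-12) {
  args <- list(
    physio_hbt_sd_uM = physio_hbt_sd_uM,
    physio_sto2_sd_pct = physio_sto2_sd_pct,
    amplitude_cv = amplitude_cv,
    multiplicative_sd = multiplicative_sd,
    additive_sd = additive_sd,
    drift_frac = drift_frac,
    artifact_rate_hz = artifact_rate_hz,
    artifact_amp = artifact_amp,
    artifact_duration_s = artifact_duration_s,
    intensity_floor = intensity_floor
  )
  if (any(unlist(args) < 0)) stop("noise model parameters must be >= 0", call. = FALSE)
  structure(args, class = "nirs_noise_model")
}

#' Fully deterministic noise model
#'
#' All noise sources set to zero: the generated truth is the ideal waveform
#' and the recording is the exact forward model times the channel gains.
#' @return Object of class `nirs_noise_model`.
#' @export
silent_noise_model <- function() {
  noise_model(
    physio_hbt_sd_uM = 0, physio_sto2_sd_pct = 0, amplitude_cv = 0,
    multiplicative_sd = 0, additive_sd = 0, drift_frac = 0,
    artifact_rate_hz = 0, artifact_amp = 0
  )
}

#' Default per-location hemodynamic parameter distributions
#'
#' Means and SDs of the subject-level generator parameters at each patch
#' location. Breath-hold maximum changes are % of baseline; deep-breathing
#' peak-to-peak amplitudes are uM (HbT) or StO2 percentage points; oscillation
#' times are the adjacent-extremum (half-period) times in seconds. Left-side
#' values follow the published cohort summaries; the right-side HbT values
#' mirror the left side, while the right StO2 deep-breathing values use their
#' own published summaries.
#'
#' @return Tibble with columns `location`, `parameter`, `mean`, `sd`.
#' @export
default_parameter_distributions <- function() {
  base <- tibble(
    parameter = c(
      "baseline_hbt_uM", "baseline_sto2_pct",
      "bh_max_pct_change_hbt", "bh_max_pct_change_sto2",
      "db_mean_pkpk_hbt", "db_mean_pkpk_sto2",
      "db_mean_osc_time_hbt", "db_mean_osc_time_sto2",
      "hbt_response_delay_s"
    )
  )
  per_loc <- list(
    left_radial   = c(60, 8, 70, 5, 1.4, 1.1, 0.3, 0.6, 0.9, 0.8, 0.3, 0.2, 7.0, 1.9, 3.7, 1.4, 2.0, 0.5),
    right_radial  = c(60, 8, 70, 5, 1.4, 1.1, 0.3, 0.6, 0.9, 0.8, 0.4, 0.5, 7.0, 1.9, 3.3, 1.2, 2.0, 0.5),
    left_carotid  = c(60, 8, 70, 5, 3.5, 3.7, 1.2, 3.2, 1.6, 1.1, 0.3, 0.2, 6.5, 2.1, 3.0, 0.8, 2.0, 0.5),
    right_carotid = c(60, 8, 70, 5, 3.5, 3.7, 1.2, 3.2, 1.6, 1.1, 0.5, 0.4, 6.5, 2.1, 3.3, 1.3, 2.0, 0.5)
  )
  dplyr::bind_rows(lapply(names(per_loc), function(loc) {
    v <- per_loc[[loc]]
    tibble(
      location = loc,
      parameter = base$parameter,
      mean = v[seq(1, 17, by = 2)],
      sd = v[seq(2, 18, by = 2)]
    )
  }))
}

# validity floors applied to parameter draws
.param_floor <- c(
  baseline_hbt_uM = 20, baseline_sto2_pct = 40,
  bh_max_pct_change_hbt = -Inf, bh_max_pct_change_sto2 = -Inf,
  db_mean_pkpk_hbt = 0.02, db_mean_pkpk_sto2 = 0.02,
  db_mean_osc_time_hbt = 1.0, db_mean_osc_time_sto2 = 1.0,
  hbt_response_delay_s = 0.5
)

# Draw per-subject x location parameters with equicorrelation `correlation`
# across locations (shared subject factor + location-specific factor).
draw_location_parameters <- function(subject_ids, distributions, correlation = 0.5) {
  if (correlation < 0 || correlation > 1) {
    stop("between-location correlation must be in [0, 1]", call. = FALSE)
  }
  if (any(distributions$sd < 0)) stop("negative SD in parameter distributions", call. = FALSE)
  n <- length(subject_ids)
  locs <- unique(distributions$location)
  pars <- unique(distributions$parameter)
  rows <- list()
  for (p in pars) {
    z_subj <- rnorm(n)
    for (loc in locs) {
      d <- distributions[distributions$parameter == p & distributions$location == loc, ]
      if (nrow(d) != 1) stop("missing distribution for ", p, " at ", loc, call. = FALSE)
      z <- sqrt(correlation) * z_subj + sqrt(1 - correlation) * rnorm(n)
      val <- d$mean + d$sd * z
      floor_p <- .param_floor[[p]]
      if (is.finite(floor_p)) val <- pmax(val, floor_p)
      if (p == "baseline_sto2_pct") val <- pmin(val, 95)
      rows[[length(rows) + 1]] <- tibble(
        subject_id = subject_ids, location = loc, parameter = p, value = val
      )
    }
  }
  dplyr::bind_rows(rows) |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
}

#' Generate subject demographic and anatomic profiles
#'
#' Demographics follow the study-cohort proportions (65% assigned female at
#' birth, 70% non-white, 40/40/20 fair/olive/dark skin tones) and vitals are
#' drawn from the cohort summary distributions. Carotid anatomy fields are
#' synthetic plausible adult values (metadata only: they do not feed the
#' optics by default).
#'
#' @param n_subjects Number of subjects.
#' @param seed Optional RNG seed.
#' @return Tibble with one row per subject.
#' @export
subject_profiles <- function(n_subjects, seed = NULL) {
  with_seed_local(seed, {
    n <- n_subjects
    n_f <- round(0.65 * n)
    n_nw <- round(0.70 * n)
    n_fair <- round(0.4 * n)
    n_olive <- round(0.4 * n)
    tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      sex_assigned_at_birth = sample(c(rep("female", n_f), rep("male", n - n_f))),
      race_group = sample(c(rep("nonwhite", n_nw), rep("white", n - n_nw))),
      skin_tone = sample(c(rep("fair", n_fair), rep("olive", n_olive),
                           rep("dark", n - n_fair - n_olive))),
      systolic_bp_mmHg = pmax(rnorm(n, 115, 11), 85),
      diastolic_bp_mmHg = pmax(rnorm(n, 71, 7), 45),
      heart_rate_bpm = pmax(rnorm(n, 72, 11), 45),
      left_bulb_depth_mm = pmax(rnorm(n, 20, 5), 8),
      right_bulb_depth_mm = pmax(rnorm(n, 20, 5), 8),
      left_bulb_diameter_mm = pmax(rnorm(n, 7, 1), 4),
      right_bulb_diameter_mm = pmax(rnorm(n, 7, 1), 4),
      left_ica_diameter_mm = pmax(rnorm(n, 5, 0.8), 2.5),
      right_ica_diameter_mm = pmax(rnorm(n, 5, 0.8), 2.5),
      left_eca_diameter_mm = pmax(rnorm(n, 4, 0.7), 2),
      right_eca_diameter_mm = pmax(rnorm(n, 4, 0.7), 2)
    )
  })
}

#' Ground-truth hemodynamic waveforms for one trial
#'
#' Builds the latent HbO2/Hb/HbT/StO2 time series implied by one row of
#' subject-by-location parameters: baseline with low-pass fluctuation in the
#' normal segments, a smooth HbT (and StO2) ramp peaking at the end of the
#' breath hold, a deep-breathing StO2 sinusoid with the HbT oscillation at
#' half its frequency and delayed by the response lag, and exponential
#' relaxation back to baseline after the breath hold and the deep breathing.
#' The analytically-true feature values are attached as the
#' `true_features` attribute (filled from the generating parameters, not
#' re-measured from the samples).
#'
#' @param params One-row data frame with the generator parameters (see
#'   [default_parameter_distributions()] for names).
#' @param protocol A [breathing_protocol()].
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param noise A [noise_model()]; only the truth-level components
#'   (physiological fluctuation, amplitude jitter) are used here.
#' @param seed Optional RNG seed.
#' @return Tibble `time_s, hbo2_uM, hb_uM, hbt_uM, sto2_pct` with attribute
#'   `true_features`.
#' @export
generate_truth <- function(params, protocol = breathing_protocol(),
                           sampling_rate_hz = 2.24, noise = noise_model(),
                           seed = NULL) {
  stopifnot(nrow(params) == 1)
  if (params$db_mean_osc_time_sto2 < 2 / sampling_rate_hz ||
      params$db_mean_osc_time_hbt < 2 / sampling_rate_hz) {
    stop("oscillation half-period shorter than two sample intervals", call. = FALSE)
  }
  with_seed_local(seed, {
    t <- protocol_time_grid(protocol, sampling_rate_hz)
    n <- length(t)
    seg <- protocol
    bh_start <- seg$start_s[seg$label == "breath_hold"]
    bh_end <- seg$end_s[seg$label == "breath_hold"]
    db_start <- seg$start_s[seg$label == "deep_breathing"]
    db_end <- seg$end_s[seg$label == "deep_breathing"]
    lead <- attr(protocol, "inhale_lead_s") %||% 5
    ramp_start <- bh_start + lead

    # breath-hold shape: smoothstep ramp peaking at the hold end, then decay
    bh_shape <- rep(0, n)
    in_ramp <- t >= ramp_start & t < bh_end
    bh_shape[in_ramp] <- smoothstep((t[in_ramp] - ramp_start) / (bh_end - ramp_start))
    post <- t >= bh_end & t < db_start
    bh_shape[post] <- exp(-(t[post] - bh_end) / 8)

    # the oscillation starts at zero phase `delay` seconds into the segment
    # (the HbT response lags the breathing-driven StO2 swing)
    db_osc <- function(half_period, pkpk, delay) {
      period <- 2 * half_period
      x <- rep(0, n)
      onset <- db_start + delay
      in_db <- t >= onset & t < db_end
      phase <- 2 * pi * (t[in_db] - onset) / period
      cyc <- floor((t[in_db] - onset) / half_period)
      ncyc <- diff(range(cyc)) + 1
      jit <- if (noise$amplitude_cv > 0) {
        pmax(1 + noise$amplitude_cv * rnorm(ncyc), 0.5)
      } else rep(1, ncyc)
      env <- smoothstep((t[in_db] - onset) / 1.5)
      x[in_db] <- (pkpk / 2) * jit[cyc - min(cyc) + 1] * env * sin(phase)
      after <- t >= db_end
      if (any(in_db) && any(after)) {
        x_end <- x[max(which(in_db))]
        x[after] <- x_end * exp(-(t[after] - db_end) / 5)
      }
      x
    }

    hbt <- params$baseline_hbt_uM *
      (1 + params$bh_max_pct_change_hbt / 100 * bh_shape) +
      db_osc(params$db_mean_osc_time_hbt, params$db_mean_pkpk_hbt,
             params$hbt_response_delay_s) +
      lowpass_noise(n, noise$physio_hbt_sd_uM)
    sto2 <- params$baseline_sto2_pct *
      (1 + params$bh_max_pct_change_sto2 / 100 * bh_shape) +
      db_osc(params$db_mean_osc_time_sto2, params$db_mean_pkpk_sto2, 0) +
      lowpass_noise(n, noise$physio_sto2_sd_pct)

    hbt <- pmax(hbt, 1)
    sto2 <- pmin(pmax(sto2, 0), 100)
    hbo2 <- sto2 / 100 * hbt
    out <- tibble(
      time_s = t,
      hbo2_uM = hbo2,
      hb_uM = hbt - hbo2,
      hbt_uM = hbt,
      sto2_pct = sto2
    )
    attr(out, "true_features") <- tibble(
      bh_max_pct_change_hbt = max(params$bh_max_pct_change_hbt, 0),
      bh_max_pct_change_sto2 = max(params$bh_max_pct_change_sto2, 0),
      db_mean_osc_time_hbt = params$db_mean_osc_time_hbt,
      db_mean_osc_time_sto2 = params$db_mean_osc_time_sto2,
      db_mean_pkpk_hbt = params$db_mean_pkpk_hbt,
      db_mean_pkpk_sto2 = params$db_mean_pkpk_sto2
    )
    attr(out, "protocol") <- protocol
    out
  })
}

#' Forward-model a truth trace into a raw patch recording
#'
#' Converts latent chromophore concentrations to detector intensities for
#' every wavelength x distance channel: `I = gain * R(mu_a(t), mu_s') *
#' (1 + noise) * drift * artifact + additive`, with the absorption at each
#' instant given by [mua_from_chromophores()] and the reflectance by
#' [diffuse_reflectance()]. Motion artifacts are multiplicative bumps shared
#' across all channels of the patch.
#'
#' @param truth Output of [generate_truth()].
#' @param geometry A [patch_geometry()].
#' @param spectra A [chromophore_spectra()].
#' @param mu_s_prime Named per-wavelength reduced scattering, 1/mm
#'   (default [scattering_prior()] at the geometry wavelengths).
#' @param noise A [noise_model()]; only the instrument-level components apply.
#' @param gains Optional named gains per channel (`"wl_rho"`); drawn
#'   log-normally around 1e6 when `NULL`.
#' @param A Boundary constant for the forward model.
#' @param seed Optional RNG seed.
#' @return Tibble `time_s, wavelength_nm, distance_mm, intensity, gain`.
#' @export
truth_to_recording <- function(truth, geometry = patch_geometry(),
                               spectra = chromophore_spectra(),
                               mu_s_prime = NULL,
                               noise = noise_model(), gains = NULL,
                               A = 2.95, seed = NULL) {
  if (is.null(mu_s_prime)) mu_s_prime <- scattering_prior(geometry$wavelengths_nm)
  with_seed_local(seed, {
    t <- truth$time_s
    n <- length(t)
    total_s <- max(t) + 1 / geometry$sampling_rate_hz

    # patch-level motion artifact profile (shared across channels)
    artifact <- rep(1, n)
    if (noise$artifact_rate_hz > 0 && noise$artifact_amp > 0) {
      n_ev <- rpois(1, noise$artifact_rate_hz * total_s)
      if (n_ev > 0) {
        for (te in runif(n_ev, 0, total_s)) {
          s <- sample(c(-1, 1), 1)
          artifact <- artifact +
            s * noise$artifact_amp *
              exp(-((t - te) / (noise$artifact_duration_s / 2))^2)
        }
      }
    }

    chans <- tidyr::expand_grid(
      wavelength_nm = geometry$wavelengths_nm,
      distance_mm = geometry$source_detector_distances_mm
    )
    clipped <- 0L
    out <- purrr::pmap_dfr(chans, function(wavelength_nm, distance_mm) {
      mua <- mua_from_chromophores(truth$hbo2_uM / 1000, truth$hb_uM / 1000,
                                   wavelength_nm, spectra)
      refl <- diffuse_reflectance(mua, mu_s_prime[[as.character(wavelength_nm)]],
                                  distance_mm, A = A)
      key <- paste0(wavelength_nm, "_", distance_mm)
      g <- if (!is.null(gains)) gains[[key]] else 1e6 * exp(rnorm(1, 0, 0.1))
      drift <- if (noise$drift_frac > 0) {
        1 + runif(1, -1, 1) * noise$drift_frac * (t / total_s)
      } else rep(1, n)
      mult <- if (noise$multiplicative_sd > 0) {
        1 + rnorm(n, 0, noise$multiplicative_sd)
      } else rep(1, n)
      intensity <- g * refl * drift * artifact * mult
      if (noise$additive_sd > 0) {
        intensity <- intensity + rnorm(n, 0, noise$additive_sd * stats::median(intensity))
      }
      bad <- intensity <= 0
      if (any(bad)) {
        clipped <<- clipped + sum(bad)
        intensity[bad] <- noise$intensity_floor
      }
      tibble(
        time_s = t, wavelength_nm = wavelength_nm, distance_mm = distance_mm,
        intensity = intensity, gain = g
      )
    })
    if (clipped > 0) {
      warning(sprintf("%d non-positive intensities clipped to the floor", clipped),
              call. = FALSE)
    }
    out
  })
}

#' Simulate a multi-subject, multi-location, multi-trial cohort
#'
#' Draws subject profiles and per-location hemodynamic parameters (with a
#' configurable equicorrelation between locations within a subject), then
#' generates ground-truth waveforms and raw recordings for every subject x
#' location x trial. Deterministic under a fixed seed.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param trials_per_subject Trials per subject at each location (default 3).
#' @param parameter_distributions Location-level parameter means/SDs, see
#'   [default_parameter_distributions()].
#' @param correlation Between-location correlation of subject parameters.
#' @param geometry,protocol,spectra,noise Pipeline components.
#' @param seed RNG seed for the whole cohort.
#' @return Object of class `nirs_cohort`: list with tibbles `profiles`,
#'   `parameters`, `true_features`, `truth`, `recordings`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_subjects = 2, trials_per_subject = 1, seed = 1)
#' dplyr::count(cohort$recordings, subject_id, location)
#' }
#' @export
generate_cohort <- function(n_subjects = 20, trials_per_subject = 3,
                            parameter_distributions = default_parameter_distributions(),
                            correlation = 0.5,
                            geometry = patch_geometry(),
                            protocol = breathing_protocol(),
                            spectra = chromophore_spectra(),
                            noise = noise_model(),
                            seed = 1) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1)
  with_seed_local(seed, {
    profiles <- subject_profiles(n_subjects)
    params <- draw_location_parameters(profiles$subject_id,
                                       parameter_distributions, correlation)
    mu_s <- scattering_prior(geometry$wavelengths_nm)

    grid <- tidyr::expand_grid(
      subject_id = profiles$subject_id,
      location = unique(parameter_distributions$location),
      trial = seq_len(trials_per_subject)
    )
    truth_list <- vector("list", nrow(grid))
    rec_list <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      p <- params[params$subject_id == grid$subject_id[i] &
                    params$location == grid$location[i], ]
      tr <- generate_truth(p, protocol, geometry$sampling_rate_hz, noise)
      rec <- truth_to_recording(tr, geometry, spectra, mu_s, noise)
      truth_list[[i]] <- dplyr::mutate(tr,
        subject_id = grid$subject_id[i], location = grid$location[i],
        trial = grid$trial[i], .before = 1
      )
      rec_list[[i]] <- dplyr::mutate(rec,
        subject_id = grid$subject_id[i], location = grid$location[i],
        trial = grid$trial[i], .before = 1
      )
    }
    true_features <- params |>
      dplyr::transmute(
        .data$subject_id, .data$location,
        bh_max_pct_change_hbt = pmax(.data$bh_max_pct_change_hbt, 0),
        bh_max_pct_change_sto2 = pmax(.data$bh_max_pct_change_sto2, 0),
        db_mean_osc_time_hbt = .data$db_mean_osc_time_hbt,
        db_mean_osc_time_sto2 = .data$db_mean_osc_time_sto2,
        db_mean_pkpk_hbt = .data$db_mean_pkpk_hbt,
        db_mean_pkpk_sto2 = .data$db_mean_pkpk_sto2
      )
    structure(
      list(
        profiles = profiles,
        parameters = params,
        true_features = true_features,
        truth = dplyr::bind_rows(truth_list),
        recordings = dplyr::bind_rows(rec_list),
        geometry = geometry, protocol = protocol, seed = seed
      ),
      class = "nirs_cohort"
    )
  })
}

#' @export
print.nirs_cohort <- function(x, ...) {
  cat("<nirs_cohort>\n")
  cat("  subjects: ", nrow(x$profiles), "\n", sep = "")
  cat("  locations:", paste(unique(x$parameters$location), collapse = ", "), "\n")
  cat("  trials:   ", length(unique(x$recordings$trial)), " per subject-location\n", sep = "")
  cat("  series:   ", nrow(dplyr::distinct(x$recordings, .data$subject_id, .data$location)),
      " artery-level recording series\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
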