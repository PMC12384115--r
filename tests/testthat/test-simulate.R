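test_that("protocol segments tile the trial with the published boundaries", {
  pr <- breathing_protocol()
  expect_equal(protocol_duration(pr), 150)
  expect_equal(pr$start_s[pr$label == "breath_hold"], 30)
  expect_equal(pr$end_s[pr$label == "breath_hold"], 60)
  expect_equal(pr$start_s[pr$label == "deep_breathing"], 90)

  t <- protocol_time_grid(pr, 2.24)
  expect_equal(length(t), floor(150 * 2.24))
  trace <- tibble::tibble(time_s = t)
  masks <- segment_masks(trace, pr)
  counts <- rowSums(vapply(masks, as.integer, integer(length(t))))
  expect_true(all(counts == 1))  # partition: every sample in exactly one segment
  # BH mask starts at the first sample with t >= 30 (half-open convention)
  expect_equal(min(t[masks$breath_hold]), t[which(t >= 30)[1]])
  expect_lt(max(t[masks$breath_hold]), 60)
  expect_error(segment_masks(tibble::tibble(time_s = t[t < 100]), pr), "protocol runs")
})

test_that("truth conserves hemoglobin and respects saturation bounds", {
  tr <- generate_truth(test_params(), seed = 3)
  expect_equal(tr$hbt_uM, tr$hbo2_uM + tr$hb_uM, tolerance = 1e-12)
  expect_true(all(tr$sto2_pct >= 0 & tr$sto2_pct <= 100))
  expect_equal(tr$sto2_pct, 100 * tr$hbo2_uM / tr$hbt_uM, tolerance = 1e-9)
})

test_that("a null subject stays at baseline with zero-change true features", {
  p <- test_params(bh_max_pct_change_hbt = 0, bh_max_pct_change_sto2 = 0,
                   db_mean_pkpk_hbt = 0, db_mean_pkpk_sto2 = 0)
  tr <- generate_truth(p, noise = silent_noise_model(), seed = 1)
  expect_equal(unique(tr$hbt_uM), 60)
  expect_equal(unique(tr$sto2_pct), 70)
  tf <- attr(tr, "true_features")
  expect_equal(unlist(tf[, c("bh_max_pct_change_hbt", "bh_max_pct_change_sto2",
                             "db_mean_pkpk_hbt", "db_mean_pkpk_sto2")]),
               c(bh_max_pct_change_hbt = 0, bh_max_pct_change_sto2 = 0,
                 db_mean_pkpk_hbt = 0, db_mean_pkpk_sto2 = 0))
})

test_that("the generator writes its own oscillation parameters into the waveform", {
  p <- test_params(db_mean_pkpk_sto2 = 0.3, db_mean_osc_time_sto2 = 3.5)
  tr <- generate_truth(p, noise = silent_noise_model(), seed = 1)
  masks <- segment_masks(tr, breathing_protocol())
  ex <- detect_extrema(tr$time_s[masks$deep_breathing],
                       tr$sto2_pct[masks$deep_breathing])
  expect_equal(mean_pkpk_amplitude(ex), 0.3, tolerance = 0.05)
  expect_equal(mean_oscillation_time(ex), 3.5, tolerance = 0.05)
  expect_error(generate_truth(test_params(db_mean_osc_time_sto2 = 0.5)),
               "two sample intervals")
})

test_that("noiseless StO2 oscillates at twice the HbT frequency", {
  tr <- generate_truth(test_params(db_mean_osc_time_hbt = 7,
                                   db_mean_osc_time_sto2 = 3.5,
                                   hbt_response_delay_s = 1),
                       noise = silent_noise_model(), seed = 1)
  masks <- segment_masks(tr, breathing_protocol())
  peak_freq <- function(x) {
    x <- x - mean(x)
    p <- Mod(fft(x))^2
    half <- 2:(floor(length(x) / 2) + 1)
    (which.max(p[half])) / length(x)  # cycles per sample
  }
  f_hbt <- peak_freq(tr$hbt_uM[masks$deep_breathing])
  f_sto2 <- peak_freq(tr$sto2_pct[masks$deep_breathing])
  expect_equal(f_sto2 / f_hbt, 2, tolerance = 0.3)
})

test_that("cohorts are reproducible and have the right design shape", {
  c1 <- generate_cohort(n_subjects = 3, trials_per_subject = 2, seed = 11)
  c2 <- generate_cohort(n_subjects = 3, trials_per_subject = 2, seed = 11)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$profiles, c2$profiles)
  series <- dplyr::distinct(c1$recordings, subject_id, location)
  expect_equal(nrow(series), 3 * 4)
  expect_equal(nrow(dplyr::distinct(c1$recordings, subject_id, location, trial)),
               3 * 4 * 2)
  expect_true(all(c1$recordings$intensity > 0))
  # full channel grid per trial
  one <- dplyr::filter(c1$recordings, subject_id == "S01",
                       location == "left_radial", trial == 1)
  expect_equal(nrow(one), 4 * 2 * floor(150 * 2.24))
})

test_that("cohort parameter draws converge to the published location means", {
  set.seed(202)
  params <- carotidnirs:::draw_location_parameters(
    sprintf("S%03d", 1:200), default_parameter_distributions(), correlation = 0.5
  )
  check <- list(
    c("left_radial", "db_mean_pkpk_hbt", 0.9, 0.8),
    c("left_carotid", "db_mean_pkpk_hbt", 1.6, 1.1),
    c("right_carotid", "db_mean_pkpk_sto2", 0.5, 0.4),
    c("right_radial", "db_mean_osc_time_sto2", 3.3, 1.2)
  )
  for (cs in check) {
    v <- params[[cs[2]]][params$location == cs[1]]
    se <- as.numeric(cs[4]) / sqrt(length(v))
    expect_lt(abs(mean(v) - as.numeric(cs[3])), 3 * se)
  }
  # between-location coupling is present
  lr <- params$db_mean_pkpk_hbt[params$location == "left_radial"]
  lc <- params$db_mean_pkpk_hbt[params$location == "left_carotid"]
  expect_gt(cor(lr, lc), 0.2)
})

test_that("profiles match the cohort demographic proportions", {
  pf <- subject_profiles(20, seed = 9)
  expect_equal(sum(pf$sex_assigned_at_birth == "female"), 13)
  expect_equal(sum(pf$race_group == "nonwhite"), 14)
  expect_equal(as.vector(table(pf$skin_tone)[c("fair", "olive", "dark")]),
               c(8L, 8L, 4L))
  expect_true(all(pf$systolic_bp_mmHg > 0 & pf$heart_rate_bpm > 0))
})

test_that("channel gains cancel in reconstructed change features", {
  truth <- generate_truth(test_params(), noise = silent_noise_model(), seed = 2)
  gains <- as.list(stats::setNames(
    rep(1e6, 8),
    as.vector(outer(c(670, 780, 808, 850), c(25, 32), paste, sep = "_"))
  ))
  rec1 <- truth_to_recording(truth, noise = silent_noise_model(), gains = gains)
  gains2 <- gains
  gains2[["808_25"]] <- gains2[["808_25"]] * 10
  gains2[["808_32"]] <- gains2[["808_32"]] * 10
  rec2 <- truth_to_recording(truth, noise = silent_noise_model(), gains = gains2)
  t1 <- reconstruct_trial(rec1)
  t2 <- reconstruct_trial(rec2)
  expect_equal(t1$d_hbt_uM, t2$d_hbt_uM, tolerance = 1e-8)
  expect_equal(t1$d_hbo2_uM, t2$d_hbo2_uM, tolerance = 1e-8)
})

test_that("a motion artifact lowers the deep-breathing SNR", {
  truth <- generate_truth(test_params(), noise = silent_noise_model(), seed = 4)
  clean <- noise_model(physio_hbt_sd_uM = 0, physio_sto2_sd_pct = 0,
                       amplitude_cv = 0, multiplicative_sd = 0.001,
                       drift_frac = 0, artifact_rate_hz = 0, artifact_amp = 0)
  dirty <- noise_model(physio_hbt_sd_uM = 0, physio_sto2_sd_pct = 0,
                       amplitude_cv = 0, multiplicative_sd = 0.001,
                       drift_frac = 0, artifact_rate_hz = 0.15,
                       artifact_amp = 0.05)
  snr_clean <- db_snr(reconstruct_trial(
    truth_to_recording(truth, noise = clean, seed = 7)
  ))
  snr_dirty <- db_snr(reconstruct_trial(
    truth_to_recording(truth, noise = dirty, seed = 7)
  ))
  expect_gt(as.numeric(snr_clean), as.numeric(snr_dirty))
})

test_that("impossible intensities are clipped with a warning", {
  truth <- generate_truth(test_params(), noise = silent_noise_model(), seed = 5)
  wild <- noise_model(multiplicative_sd = 2, physio_hbt_sd_uM = 0,
                      physio_sto2_sd_pct = 0, amplitude_cv = 0,
                      drift_frac = 0, artifact_rate_hz = 0, artifact_amp = 0)
  expect_warning(
    rec <- truth_to_recording(truth, noise = wild, seed = 3),
    "clipped"
  )
  expect_true(all(rec$intensity > 0))
})
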