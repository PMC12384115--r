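make_flat_recording <- function(value = 1000, gain = 1e6) {
  grid <- tidyr::expand_grid(
    time_s = protocol_time_grid(breathing_protocol(), 2.24),
    wavelength_nm = c(670, 780, 808, 850),
    distance_mm = c(25, 32)
  )
  dplyr::mutate(grid, intensity = value, gain = gain)
}

test_that("optical-density changes have the expected closed forms", {
  rec <- make_flat_recording()
  dod <- delta_optical_density(rec)
  expect_true(all(abs(dod$dod) < 1e-12))

  rec2 <- dplyr::mutate(rec,
    intensity = ifelse(time_s >= 100, intensity / exp(1), intensity))
  dod2 <- delta_optical_density(rec2)
  expect_equal(unique(round(dod2$dod[dod2$time_s >= 100], 12)), 1)
  # zero mean over the reference window by construction
  expect_lt(abs(mean(dod2$dod[dod2$time_s < 20])), 1e-12)
  # non-positive samples are flagged, not propagated
  rec3 <- rec
  rec3$intensity[5] <- -1
  dod3 <- delta_optical_density(rec3)
  expect_true(dod3$flagged[5])
  expect_true(is.na(dod3$dod[5]))
})

test_that("a known absorption step round-trips through dOD within 2%", {
  sp <- chromophore_spectra()
  msp <- scattering_prior(c(670, 780, 808, 850))
  mu_a0 <- mua_from_chromophores(0.042, 0.018, 780, sp)
  dmu <- 0.01 * mu_a0
  rho <- 25
  i0 <- diffuse_reflectance(mu_a0, msp[["780"]], rho)
  i1 <- diffuse_reflectance(mu_a0 + dmu, msp[["780"]], rho)
  dod <- log(i0 / i1)
  pred <- differential_pathlength_factor(mu_a0, msp[["780"]], rho) * rho * dmu
  expect_equal(dod, pred, tolerance = 0.02)
})

test_that("two-wavelength unmixing reproduces the manual 2x2 solution", {
  geom <- patch_geometry(source_detector_distances_mm = 25,
                         wavelengths_nm = c(670, 850))
  sp <- chromophore_spectra()
  msp <- scattering_prior(c(670, 850))
  mu_a0 <- c("670" = mua_from_chromophores(0.042, 0.018, 670, sp),
             "850" = mua_from_chromophores(0.042, 0.018, 850, sp))
  dpf <- c(
    differential_pathlength_factor(mu_a0[["670"]], msp[["670"]], 25),
    differential_pathlength_factor(mu_a0[["850"]], msp[["850"]], 25)
  )
  dc_true <- c(hbo2 = 2e-4, hb = -1e-4)  # mM
  E <- log(10) * extinction_matrix(sp, c(670, 850))
  dod_vals <- as.vector(E %*% dc_true) * dpf * 25
  dod <- tibble::tibble(
    time_s = c(0, 0), wavelength_nm = c(670, 850), distance_mm = 25,
    dod = dod_vals, ref_var = 1, flagged = FALSE
  )
  out <- unmix_concentrations(dod, geom, sp, mu_a0, msp)
  manual <- unname(solve(E * dpf * 25, dod_vals))  # direct matrix inverse
  expect_equal(out$d_hbo2_uM, manual[1] * 1000, tolerance = 1e-8)
  expect_equal(out$d_hb_uM, manual[2] * 1000, tolerance = 1e-8)
  expect_equal(out$d_hbo2_uM, dc_true[["hbo2"]] * 1000, tolerance = 1e-6)
  # zero input -> zero output
  dod0 <- dplyr::mutate(dod, dod = 0)
  out0 <- unmix_concentrations(dod0, geom, sp, mu_a0, msp)
  expect_true(all(abs(c(out0$d_hbo2_uM, out0$d_hb_uM)) < 1e-12))
})

test_that("absolute baseline recovers known optical truth within 3%", {
  trial <- noiseless_trial(seed = 6)
  b <- attr(trial$trace, "baseline")
  expect_false(b$fallback)
  expect_equal(b$hbt0_uM, 60, tolerance = 0.03)
  expect_equal(b$sto2_0_pct, 70, tolerance = 0.03)
})

test_that("degenerate distance profiles trigger the baseline fallback", {
  rec <- make_flat_recording()  # identical intensities at both distances
  expect_warning(b <- absolute_baseline(rec), "fell back")
  expect_true(b$fallback)
  expect_equal(b$hbt0_uM, 60)
})

test_that("a scattering-prior error biases the baseline but preserves trace shape", {
  trial <- noiseless_trial(seed = 8)
  wrong <- scattering_prior(c(670, 780, 808, 850), a = 0.9 * 1.2)
  tr2 <- reconstruct_trial(trial$recording, mu_s_prime = wrong)
  b1 <- attr(trial$trace, "baseline")
  b2 <- attr(tr2, "baseline")
  expect_gt(abs(b2$hbt0_uM - b1$hbt0_uM) / b1$hbt0_uM, 0.02)
  # change traces remain proportional: same physiology, rescaled pathlength
  expect_gt(cor(trial$trace$d_hbt_uM, tr2$d_hbt_uM), 0.999)
})

test_that("reconstruction is deterministic and additive", {
  trial <- noiseless_trial(seed = 9)
  tr2 <- reconstruct_trial(trial$recording)
  expect_identical(as.data.frame(trial$trace), as.data.frame(tr2))
  expect_equal(trial$trace$d_hbt_uM,
               trial$trace$d_hbo2_uM + trial$trace$d_hb_uM,
               tolerance = 1e-12)
})

test_that("noiseless round trip recovers deep-breathing amplitudes", {
  trial <- noiseless_trial(seed = 10)
  masks <- segment_masks(trial$trace, breathing_protocol())
  ex <- detect_extrema(trial$trace$time_s[masks$deep_breathing],
                       trial$trace$sto2_pct[masks$deep_breathing])
  expect_equal(mean_pkpk_amplitude(ex), 0.3, tolerance = 0.10)
  # HbO2 amplitude: truth oscillation amplitude from the latent table
  ex_truth <- detect_extrema(trial$truth$time_s[masks$deep_breathing],
                             trial$truth$hbo2_uM[masks$deep_breathing])
  ex_rec <- detect_extrema(trial$trace$time_s[masks$deep_breathing],
                           trial$trace$d_hbo2_uM[masks$deep_breathing])
  expect_equal(mean_pkpk_amplitude(ex_rec), mean_pkpk_amplitude(ex_truth),
               tolerance = 0.05)
})

test_that("pure gain drift is removed by detrending", {
  p <- test_params(bh_max_pct_change_hbt = 0, bh_max_pct_change_sto2 = 0,
                   db_mean_pkpk_hbt = 0, db_mean_pkpk_sto2 = 0)
  truth <- generate_truth(p, noise = silent_noise_model(), seed = 1)
  drifty <- noise_model(physio_hbt_sd_uM = 0, physio_sto2_sd_pct = 0,
                        amplitude_cv = 0, multiplicative_sd = 0,
                        drift_frac = 0.01, artifact_rate_hz = 0,
                        artifact_amp = 0)
  rec <- truth_to_recording(truth, noise = drifty, seed = 2)
  tr <- reconstruct_trial(rec, detrend = TRUE)
  expect_lt(max(abs(tr$d_hbt_uM)), 0.05)
})

test_that("recovery error grows monotonically with intensity noise", {
  noise_levels <- c(0.0005, 0.002, 0.008)
  n_seeds <- 8
  err <- matrix(NA_real_, n_seeds, length(noise_levels))
  truth <- generate_truth(test_params(), noise = silent_noise_model(), seed = 20)
  masks <- segment_masks(truth, breathing_protocol())
  for (j in seq_along(noise_levels)) {
    nm <- noise_model(physio_hbt_sd_uM = 0, physio_sto2_sd_pct = 0,
                      amplitude_cv = 0,
                      multiplicative_sd = noise_levels[j],
                      drift_frac = 0, artifact_rate_hz = 0, artifact_amp = 0)
    for (s in seq_len(n_seeds)) {
      rec <- truth_to_recording(truth, noise = nm, seed = 100 + s)
      tr <- reconstruct_trial(rec)
      err[s, j] <- sqrt(mean((tr$d_hbt_uM -
                                (truth$hbt_uM - mean(truth$hbt_uM[truth$time_s < 20])))^2))
    }
  }
  m <- colMeans(err)
  expect_true(all(diff(m) > 0))
})

test_that("flag-heavy recordings are marked low quality but still emitted", {
  rec <- make_flat_recording()
  bad_times <- unique(rec$time_s)[1:100]
  rec$intensity[rec$time_s %in% bad_times & rec$wavelength_nm == 670] <- -1
  expect_warning(tr <- reconstruct_trial(rec), "fell back")
  expect_s3_class(tr, "nirs_trace")
  expect_gt(sum(tr$flagged), 0)
})
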