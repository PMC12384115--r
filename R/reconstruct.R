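# Inversion of raw patch intensities to chromophore concentration changes and
# tissue oxygen saturation via the linearized modified Beer-Lambert law.

#' Change in optical density per channel
#'
#' `dOD(lambda, rho, t) = ln(I_ref / I(t))` with `I_ref` the mean intensity
#' over the reference window. Constant per-channel gains cancel exactly.
#' Non-positive intensities are flagged and excluded.
#'
#' @param recording Long tibble with `time_s, wavelength_nm, distance_mm,
#'   intensity` (one trial).
#' @param reference_window Two-element `c(start, end)` window, s (half-open).
#' @return Tibble with `time_s, wavelength_nm, distance_mm, dod, flagged`
#'   plus per-channel `ref_mean` and `ref_var` columns.
#' @export
delta_optical_density <- function(recording, reference_window = c(0, 20)) {
  stopifnot(length(reference_window) == 2, diff(reference_window) > 0)
  in_ref <- recording$time_s >= reference_window[1] &
    recording$time_s < reference_window[2]
  if (!any(in_ref)) stop("reference window contains no samples", call. = FALSE)
  recording |>
    dplyr::group_by(.data$wavelength_nm, .data$distance_mm) |>
    dplyr::mutate(
      flagged = !is.finite(.data$intensity) | .data$intensity <= 0,
      ref_mean = mean(.data$intensity[.data$time_s >= reference_window[1] &
                                        .data$time_s < reference_window[2] &
                                        !.data$flagged]),
      dod = log(.data$ref_mean / ifelse(.data$flagged, NA_real_, .data$intensity)),
      ref_var = stats::var(.data$dod[.data$time_s >= reference_window[1] &
                                       .data$time_s < reference_window[2]])
    ) |>
    dplyr::ungroup()
}

#' Absolute baseline optical properties and hemoglobin levels
#'
#' Spatially-resolved estimate of the absolute baseline: from the
#' gain-corrected reference-window intensities at the two detector distances,
#' the apparent attenuation slope of `ln(rho^2 I)` vs `rho` seeds a
#' per-wavelength root-finding step that matches the two-distance log-ratio
#' of the package's own forward model, yielding `mu_a(lambda)` given the
#' reduced-scattering prior. Unmixing the background-corrected `mu_a` across
#' wavelengths gives absolute HbO2/Hb, hence baseline HbT and StO2.
#'
#' @param recording One-trial recording with a `gain` column (instrument
#'   calibration); without it, relative gains are assumed equal.
#' @param geometry A [patch_geometry()] (needs >= 2 distances).
#' @param spectra A [chromophore_spectra()].
#' @param mu_s_prime Named reduced-scattering prior per wavelength, 1/mm.
#' @param reference_window Baseline window, s.
#' @param default_baseline Fallback `c(hbt_uM, sto2_pct)` used (with a
#'   warning) when the estimate is unphysical.
#' @param A Boundary constant.
#' @return List `hbt0_uM`, `sto2_0_pct`, `mu_a` (named per wavelength),
#'   `fallback` (logical).
#' @export
absolute_baseline <- function(recording, geometry = patch_geometry(),
                              spectra = chromophore_spectra(),
                              mu_s_prime = NULL,
                              reference_window = c(0, 20),
                              default_baseline = c(hbt_uM = 60, sto2_pct = 70),
                              A = 2.95) {
  if (length(geometry$source_detector_distances_mm) < 2) {
    stop("absolute baseline needs at least two detector distances", call. = FALSE)
  }
  if (is.null(mu_s_prime)) mu_s_prime <- scattering_prior(geometry$wavelengths_nm)
  rho <- range(geometry$source_detector_distances_mm)
  fallback <- function(msg) {
    warning("absolute baseline fell back to defaults: ", msg, call. = FALSE)
    list(hbt0_uM = unname(default_baseline[1]),
         sto2_0_pct = unname(default_baseline[2]),
         mu_a = NULL, fallback = TRUE)
  }

  ref <- recording |>
    dplyr::filter(.data$time_s >= reference_window[1],
                  .data$time_s < reference_window[2]) |>
    dplyr::group_by(.data$wavelength_nm, .data$distance_mm) |>
    dplyr::summarise(
      i_cal = mean(.data$intensity / (if ("gain" %in% names(recording)) .data$gain else 1)),
      .groups = "drop"
    )

  mu_a <- vapply(geometry$wavelengths_nm, function(wl) {
    i1 <- ref$i_cal[ref$wavelength_nm == wl & ref$distance_mm == rho[1]]
    i2 <- ref$i_cal[ref$wavelength_nm == wl & ref$distance_mm == rho[2]]
    if (length(i1) != 1 || length(i2) != 1 || i1 <= 0 || i2 <= 0) return(NA_real_)
    meas <- log(i1 / i2)
    if (meas <= 0) return(NA_real_)  # degenerate: no decay with distance
    msp <- mu_s_prime[[as.character(wl)]]
    g <- function(mua) {
      log(diffuse_reflectance(mua, msp, rho[1], A) /
            diffuse_reflectance(mua, msp, rho[2], A)) - meas
    }
    lo <- 1e-6
    hi <- 1
    if (g(lo) > 0 || g(hi) < 0) return(NA_real_)
    stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
  names(mu_a) <- as.character(geometry$wavelengths_nm)

  if (any(is.na(mu_a))) return(fallback("attenuation slope out of range"))
  mua_chrom <- mu_a - vapply(geometry$wavelengths_nm,
                             function(wl) background_mua(spectra, wl), numeric(1))
  if (any(mua_chrom <= 0)) return(fallback("negative chromophore absorption"))

  E <- log(10) * extinction_matrix(spectra, geometry$wavelengths_nm)
  conc <- tryCatch(qr.solve(E, mua_chrom), error = function(e) NULL)
  if (is.null(conc) || any(conc <= 0)) return(fallback("unphysical concentrations"))
  hbt0 <- sum(conc) * 1000
  sto2_0 <- 100 * conc[1] / sum(conc)
  list(hbt0_uM = unname(hbt0), sto2_0_pct = unname(sto2_0),
       mu_a = mu_a, fallback = FALSE)
}

#' Spectral unmixing of optical-density changes
#'
#' Per time sample, solves the modified Beer-Lambert system
#' `dOD(lambda, rho) / (DPF(lambda, rho) * rho) = ln(10) *
#' (eps_HbO2 dC_HbO2 + eps_Hb dC_Hb)` by weighted least squares pooling all
#' wavelength x distance channels; weights are the inverse reference-window
#' variance of each channel's dOD.
#'
#' @param dod Output of [delta_optical_density()].
#' @param geometry A [patch_geometry()].
#' @param spectra A [chromophore_spectra()].
#' @param baseline_mu_a Named per-wavelength baseline absorption (1/mm) at
#'   which the DPF is evaluated and held fixed.
#' @param mu_s_prime Named reduced-scattering values per wavelength, 1/mm.
#' @param A Boundary constant.
#' @return Tibble `time_s, d_hbo2_uM, d_hb_uM, d_hbt_uM, flagged`.
#' @export
unmix_concentrations <- function(dod, geometry = patch_geometry(),
                                 spectra = chromophore_spectra(),
                                 baseline_mu_a = NULL, mu_s_prime = NULL,
                                 A = 2.95) {
  wls <- geometry$wavelengths_nm
  if (length(wls) < 2) stop("need at least two wavelengths to unmix", call. = FALSE)
  if (is.null(mu_s_prime)) mu_s_prime <- scattering_prior(wls)
  if (is.null(baseline_mu_a)) {
    baseline_mu_a <- vapply(wls, function(wl) {
      mua_from_chromophores(0.042, 0.018, wl, spectra)
    }, numeric(1))
    names(baseline_mu_a) <- as.character(wls)
  }

  chans <- tidyr::expand_grid(
    wavelength_nm = wls,
    distance_mm = geometry$source_detector_distances_mm
  ) |>
    dplyr::mutate(
      dpf = differential_pathlength_factor(
        baseline_mu_a[as.character(.data$wavelength_nm)],
        mu_s_prime[as.character(.data$wavelength_nm)],
        .data$distance_mm, A = A
      ),
      scale = .data$dpf * .data$distance_mm
    )

  E <- log(10) * extinction_matrix(spectra, wls)
  if (qr(E)$rank < 2) stop("extinction matrix is rank deficient", call. = FALSE)
  X <- E[match(chans$wavelength_nm, wls), , drop = FALSE]

  wide <- dod |>
    dplyr::mutate(channel = paste0(.data$wavelength_nm, "_", .data$distance_mm)) |>
    dplyr::select("time_s", "channel", "dod")
  key <- paste0(chans$wavelength_nm, "_", chans$distance_mm)
  Y <- wide |>
    tidyr::pivot_wider(names_from = "channel", values_from = "dod") |>
    dplyr::arrange(.data$time_s)
  tvec <- Y$time_s
  Ym <- t(as.matrix(Y[, key, drop = FALSE])) / chans$scale  # channels x time

  ref_var <- dod |>
    dplyr::distinct(.data$wavelength_nm, .data$distance_mm, .data$ref_var)
  w <- ref_var$ref_var[match(
    key, paste0(ref_var$wavelength_nm, "_", ref_var$distance_mm)
  )]
  w <- ifelse(is.finite(w) & w > 0, 1 / w, 1)
  w <- w / mean(w)

  XtW <- t(X * w)
  P <- solve(XtW %*% X, XtW)  # 2 x channels projector

  complete <- colSums(is.na(Ym)) == 0
  conc <- matrix(NA_real_, nrow = 2, ncol = length(tvec))
  if (any(complete)) conc[, complete] <- P %*% Ym[, complete, drop = FALSE]
  # times with flagged channels: refit on the channels that remain
  for (j in which(!complete)) {
    ok <- !is.na(Ym[, j])
    if (sum(ok) >= 2) {
      Xo <- X[ok, , drop = FALSE]
      XtWo <- t(Xo * w[ok])
      fit <- tryCatch(solve(XtWo %*% Xo, XtWo %*% Ym[ok, j]),
                      error = function(e) c(NA_real_, NA_real_))
      conc[, j] <- fit
    }
  }
  tibble(
    time_s = tvec,
    d_hbo2_uM = conc[1, ] * 1000,
    d_hb_uM = conc[2, ] * 1000,
    d_hbt_uM = (conc[1, ] + conc[2, ]) * 1000,
    flagged = !complete
  )
}

#' Reconstruct one trial
#'
#' Composes [absolute_baseline()], [delta_optical_density()] and
#' [unmix_concentrations()] into a full reconstructed trace with an absolute
#' StO2 estimate `100 * (HbO2_0 + dHbO2) / (HbT_0 + dHbT)` clamped to
#' `[0, 100]` (clamps counted, not erased). With `detrend = TRUE` a linear
#' drift fitted per channel over the first and last normal-breathing segments
#' is removed from the dOD before unmixing.
#'
#' @param recording One-trial long recording tibble.
#' @param geometry,spectra,mu_s_prime,A Forward-model components.
#' @param protocol A [breathing_protocol()] (needed for detrending windows).
#' @param reference_window dOD reference window, s.
#' @param detrend Remove per-channel linear drift (default `FALSE`).
#' @param default_baseline Fallback absolute baseline, see
#'   [absolute_baseline()].
#' @return Object of class `nirs_trace`: tibble `time_s, d_hbo2_uM, d_hb_uM,
#'   d_hbt_uM, sto2_pct, flagged` with attributes `baseline` (the absolute
#'   baseline list), `n_clamped`, and `low_quality` (> 20% flagged samples).
#' @export
reconstruct_trial <- function(recording, geometry = patch_geometry(),
                              spectra = chromophore_spectra(),
                              mu_s_prime = NULL,
                              protocol = breathing_protocol(),
                              reference_window = c(0, 20),
                              detrend = FALSE,
                              default_baseline = c(hbt_uM = 60, sto2_pct = 70),
                              A = 2.95) {
  if (is.null(mu_s_prime)) mu_s_prime <- scattering_prior(geometry$wavelengths_nm)
  base <- absolute_baseline(recording, geometry, spectra, mu_s_prime,
                            reference_window, default_baseline, A = A)
  dod <- delta_optical_density(recording, reference_window)

  if (detrend) {
    dod <- dod |>
      dplyr::group_by(.data$wavelength_nm, .data$distance_mm) |>
      dplyr::group_modify(function(d, key) {
        in_fit <- d$time_s < protocol$end_s[1] |
          d$time_s >= protocol$start_s[nrow(protocol)]
        ok <- in_fit & !is.na(d$dod)
        if (sum(ok) >= 3) {
          fit <- stats::lm(dod ~ time_s, data = d[ok, ])
          d$dod <- d$dod - as.numeric(predict(fit, newdata = d["time_s"]))
        }
        d
      }) |>
      dplyr::ungroup()
  }

  mu_a0 <- base$mu_a
  conc <- unmix_concentrations(dod, geometry, spectra, mu_a0, mu_s_prime, A = A)

  hbo2_0 <- base$hbt0_uM * base$sto2_0_pct / 100
  sto2 <- 100 * (hbo2_0 + conc$d_hbo2_uM) / (base$hbt0_uM + conc$d_hbt_uM)
  n_clamped <- sum(sto2 < 0 | sto2 > 100, na.rm = TRUE)
  sto2 <- pmin(pmax(sto2, 0), 100)

  out <- dplyr::mutate(conc, sto2_pct = sto2)
  attr(out, "baseline") <- base
  attr(out, "n_clamped") <- n_clamped
  attr(out, "low_quality") <- mean(out$flagged) > 0.2
  class(out) <- c("nirs_trace", class(out))
  out
}

#' Reconstruct every trial of a cohort
#'
#' @param recordings Cohort recordings tibble (`subject_id, location, trial`
#'   plus the per-channel columns) or a [generate_cohort()] object.
#' @inheritParams reconstruct_trial
#' @return List with `traces` (long tibble of reconstructed samples) and
#'   `baselines` (one row per trial: `hbt0_uM, sto2_0_pct, fallback,
#'   n_clamped, low_quality`).
#' @export
reconstruct_cohort <- function(recordings, geometry = patch_geometry(),
                               spectra = chromophore_spectra(),
                               mu_s_prime = NULL,
                               protocol = breathing_protocol(),
                               reference_window = c(0, 20),
                               detrend = FALSE,
                               default_baseline = c(hbt_uM = 60, sto2_pct = 70),
                               A = 2.95) {
  if (inherits(recordings, "nirs_cohort")) recordings <- recordings$recordings
  keys <- dplyr::distinct(recordings, .data$subject_id, .data$location, .data$trial)
  key_of <- function(df) paste(df$subject_id, df$location, df$trial, sep = "\r")
  parts <- split(recordings, factor(key_of(recordings), levels = key_of(keys)))
  traces <- vector("list", nrow(keys))
  bases <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    rec <- parts[[i]]
    tr <- reconstruct_trial(rec, geometry, spectra, mu_s_prime, protocol,
                            reference_window, detrend, default_baseline, A = A)
    b <- attr(tr, "baseline")
    traces[[i]] <- dplyr::mutate(as_tibble(tr),
      subject_id = keys$subject_id[i], location = keys$location[i],
      trial = keys$trial[i], .before = 1
    )
    bases[[i]] <- tibble(
      subject_id = keys$subject_id[i], location = keys$location[i],
      trial = keys$trial[i],
      hbt0_uM = b$hbt0_uM, sto2_0_pct = b$sto2_0_pct, fallback = b$fallback,
      n_clamped = attr(tr, "n_clamped"),
      low_quality = attr(tr, "low_quality")
    )
  }
  list(traces = dplyr::bind_rows(traces), baselines = dplyr::bind_rows(bases))
}
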