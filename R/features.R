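# Extraction of the six breathing-protocol parameters of interest, with
# SNR-based trial selection and the two-standard-deviation outlier screen.

#' Baseline value of a trace feature
#'
#' Arithmetic mean of the feature over the first 20 s of normal breathing
#' (half-open window).
#'
#' @param trace Data frame with `time_s` and the feature column.
#' @param feature Column name, e.g. `"hbt_uM"` or `"sto2_pct"`.
#' @param window Baseline window `c(start, end)`, s.
#' @return Scalar baseline.
#' @export
baseline_value <- function(trace, feature, window = c(0, 20)) {
  sel <- trace$time_s >= window[1] & trace$time_s < window[2]
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  mean(trace[[feature]][sel], na.rm = TRUE)
}

#' Maximum percent change during the breath hold
#'
#' `100 * (max over the breath-hold segment - baseline) / baseline`.
#'
#' @param trace Data frame with `time_s` and the feature column.
#' @param feature Column name.
#' @param baseline Baseline value (denominator); must be non-zero.
#' @param protocol A [breathing_protocol()].
#' @return Percent change, or `NA` with an `undefined` attribute if the
#'   baseline is zero.
#' @export
bh_max_percent_change <- function(trace, feature, baseline,
                                  protocol = breathing_protocol()) {
  if (!is.finite(baseline) || baseline == 0) {
    out <- NA_real_
    attr(out, "undefined") <- "zero baseline"
    return(out)
  }
  masks <- segment_masks(trace, protocol)
  mx <- max(trace[[feature]][masks$breath_hold], na.rm = TRUE)
  100 * (mx - baseline) / baseline
}

#' Alternating extrema of an oscillating segment
#'
#' Deterministic peak/trough detection: light moving-average smoothing, local
#' extrema from slope sign changes, a prominence floor (discarding adjacent
#' peak-trough excursions smaller than `prominence_frac` of the segment's
#' interquartile range), and enforced alternation keeping the more extreme of
#' same-sign neighbours.
#'
#' @param time_s,values Segment samples (>= 5).
#' @param smooth_window Moving-average window in samples (odd; default 3).
#' @param prominence_frac Prominence floor as a fraction of the segment IQR.
#' @return Tibble `time_s, value, type` (`"peak"`/`"trough"`) in time order;
#'   zero rows when no usable extrema remain.
#' @export
detect_extrema <- function(time_s, values, smooth_window = 3,
                           prominence_frac = 0.2) {
  n <- length(values)
  if (n < 5) stop("segment too short for extremum detection", call. = FALSE)
  v <- if (smooth_window > 1) {
    as.numeric(stats::filter(values, rep(1 / smooth_window, smooth_window),
                             sides = 2))
  } else values
  v[is.na(v)] <- values[is.na(v)]  # fill filter edges with the raw samples
  d <- diff(v)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  idx <- which(diff(s) != 0) + 1
  if (length(idx) == 0) return(empty_extrema())
  type <- ifelse(s[idx - 1] > 0, "peak", "trough")

  # detection and pruning both act on the smoothed series; the reported
  # values are the raw samples at the retained indices
  floor_amp <- prominence_frac * stats::IQR(values, na.rm = TRUE)
  keep_alternating <- function(idx, type) {
    out_i <- integer(0)
    out_t <- character(0)
    for (k in seq_along(idx)) {
      if (length(out_i) > 0 && type[k] == tail(out_t, 1)) {
        last <- tail(out_i, 1)
        better <- if (type[k] == "peak") v[idx[k]] > v[last]
                  else v[idx[k]] < v[last]
        if (better) out_i[length(out_i)] <- idx[k]
      } else {
        out_i <- c(out_i, idx[k])
        out_t <- c(out_t, type[k])
      }
    }
    list(idx = out_i, type = out_t)
  }
  alt <- keep_alternating(idx, type)
  # prominence pruning: each extremum must swing at least the floor on both
  # sides, with the segment's first/last samples as virtual neighbours (this
  # rejects plateau artifacts at the segment edges); iterate to a fixed point
  repeat {
    m <- length(alt$idx)
    if (m == 0) break
    ext <- c(v[1], v[alt$idx], v[n])
    exc <- abs(diff(ext))
    prom <- pmin(exc[seq_len(m)], exc[seq_len(m) + 1])
    if (all(prom >= floor_amp)) break
    k <- which.min(prom)
    alt$idx <- alt$idx[-k]
    alt$type <- alt$type[-k]
    alt <- keep_alternating(alt$idx, alt$type)
  }
  if (length(alt$idx) == 0) return(empty_extrema())
  tibble(time_s = time_s[alt$idx], value = values[alt$idx], type = alt$type)
}

empty_extrema <- function() {
  tibble(time_s = numeric(0), value = numeric(0), type = character(0))
}

zoo_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- x
  out[idx > 0] <- x[idx[idx > 0]]
  out
}

#' Mean oscillation time from an extrema list
#'
#' Mean time between one peak/trough and the next, i.e. the mean gap between
#' ADJACENT alternating extrema (a half period for a pure sinusoid).
#'
#' @param extrema Output of [detect_extrema()].
#' @return Seconds, or `NA` when fewer than two extrema exist.
#' @export
mean_oscillation_time <- function(extrema) {
  if (nrow(extrema) < 2) return(NA_real_)
  stopifnot(OSC_TIME_IS_HALF_PERIOD)
  mean(diff(extrema$time_s))
}

#' Mean peak-to-peak amplitude from an extrema list
#'
#' Mean of `|peak - adjacent trough|` over consecutive alternating pairs.
#'
#' @param extrema Output of [detect_extrema()].
#' @return Amplitude in the feature's units, `NA` when fewer than two extrema.
#' @export
mean_pkpk_amplitude <- function(extrema) {
  if (nrow(extrema) < 2) return(NA_real_)
  mean(abs(diff(extrema$value)))
}

#' Sinusoid-assuming SNR of the deep-breathing HbT trace
#'
#' Mirrors the classic sinusoidal SNR definition: the deep-breathing segment
#' is linearly detrended, Hann-windowed, and periodogram-transformed; the
#' largest non-DC bin (+/- 2 bins for leakage) is the fundamental, its first
#' five harmonics (+/- 1 bin) are excluded, and SNR is the ratio of the
#' fundamental's power to the remaining noise power, in dB (capped at 100).
#'
#' @param trace Reconstructed trace with `time_s` and a `d_hbt_uM` column (or
#'   the column named by `feature`).
#' @param protocol A [breathing_protocol()].
#' @param feature Column to score (default `"d_hbt_uM"`).
#' @return SNR in dB; attribute `unreliable` is set when the segment spans
#'   fewer than two fundamental periods.
#' @export
db_snr <- function(trace, protocol = breathing_protocol(), feature = "d_hbt_uM") {
  masks <- segment_masks(trace, protocol)
  x <- trace[[feature]][masks$deep_breathing]
  t <- trace$time_s[masks$deep_breathing]
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("deep-breathing segment too short for SNR", call. = FALSE)
  x <- x - as.numeric(stats::lm.fit(cbind(1, seq_len(n)), x)$fitted.values)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  p <- Mod(fft(x * w))^2
  half <- 2:(floor(n / 2) + 1)
  ps <- p[half]
  fund <- which.max(ps)
  sig_bins <- intersect(fund + (-2:2), seq_along(ps))
  harm_bins <- integer(0)
  for (h in 2:6) {
    hb <- (fund) * h
    harm_bins <- c(harm_bins, intersect(hb + (-1:1), seq_along(ps)))
  }
  # the two lowest bins absorb residual trend after detrending; treat them as
  # DC leakage, not noise
  noise_bins <- setdiff(seq_along(ps), c(1:2, sig_bins, harm_bins))
  sig <- sum(ps[sig_bins])
  # median-based noise level (chi-square bias corrected): robust to leakage
  # skirts of the fundamental and harmonics
  noise_bar <- if (length(noise_bins) > 0) {
    stats::median(ps[noise_bins]) / log(2)
  } else 0
  # extrapolate the noise level over the whole band (signal bins included)
  noise <- noise_bar * length(ps)
  snr <- if (noise <= sig * 1e-10 || noise == 0) 100 else {
    min(10 * log10(sig / noise), 100)
  }
  period_bins <- n / fund  # samples per fundamental period
  if (n < 2 * period_bins) attr(snr, "unreliable") <- TRUE
  snr
}

#' Select the least-noisy trial
#'
#' Picks the trial with the largest deep-breathing SNR; when no trial reaches
#' the threshold, the location is excluded. Ties go to the earliest trial.
#'
#' @param trial_snrs Numeric vector of SNRs (dB), in trial order.
#' @param threshold Minimum acceptable SNR (dB), default 1.
#' @return List `selected` (trial index or `NA`), `excluded` (logical),
#'   `reason`.
#' @export
select_trial <- function(trial_snrs, threshold = 1) {
  if (length(trial_snrs) < 1) stop("need at least one trial", call. = FALSE)
  if (all(!is.finite(trial_snrs)) || max(trial_snrs, na.rm = TRUE) < threshold) {
    return(list(selected = NA_integer_, excluded = TRUE,
                reason = sprintf("all trial SNRs below %g dB", threshold)))
  }
  list(selected = which.max(trial_snrs), excluded = FALSE, reason = NA_character_)
}

#' Two-standard-deviation outlier screen
#'
#' Single pass: values farther than two sample standard deviations from the
#' mean are removed. With fewer than three values the screen is a no-op.
#'
#' @param values Numeric vector.
#' @return List `kept`, `removed`, `removed_idx`.
#' @export
remove_outliers <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3) {
    warning("fewer than 3 values: outlier screen skipped", call. = FALSE)
    return(list(kept = values, removed = numeric(0), removed_idx = integer(0)))
  }
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  bad <- ok & abs(values - m) > 2 * s
  list(kept = values[!bad & ok], removed = values[bad],
       removed_idx = which(bad))
}

# feature names in canonical order
FEATURE_NAMES <- c(
  "bh_max_pct_change_hbt", "bh_max_pct_change_sto2",
  "db_mean_osc_time_hbt", "db_mean_osc_time_sto2",
  "db_mean_pkpk_hbt", "db_mean_pkpk_sto2"
)

features_one_trial <- function(trace, hbt0_uM, protocol, smooth_window,
                               prominence_frac) {
  hbt_abs <- hbt0_uM + trace$d_hbt_uM
  tr <- tibble(time_s = trace$time_s, hbt_uM = hbt_abs,
               sto2_pct = trace$sto2_pct)
  base_hbt <- baseline_value(tr, "hbt_uM")
  base_sto2 <- baseline_value(tr, "sto2_pct")
  masks <- segment_masks(tr, protocol)
  ex_hbt <- detect_extrema(tr$time_s[masks$deep_breathing],
                           tr$hbt_uM[masks$deep_breathing],
                           smooth_window, prominence_frac)
  ex_sto2 <- detect_extrema(tr$time_s[masks$deep_breathing],
                            tr$sto2_pct[masks$deep_breathing],
                            smooth_window, prominence_frac)
  tibble(
    bh_max_pct_change_hbt = bh_max_percent_change(tr, "hbt_uM", base_hbt, protocol),
    bh_max_pct_change_sto2 = bh_max_percent_change(tr, "sto2_pct", base_sto2, protocol),
    db_mean_osc_time_hbt = mean_oscillation_time(ex_hbt),
    db_mean_osc_time_sto2 = mean_oscillation_time(ex_sto2),
    db_mean_pkpk_hbt = mean_pkpk_amplitude(ex_hbt),
    db_mean_pkpk_sto2 = mean_pkpk_amplitude(ex_sto2)
  )
}

#' Extract the six parameters of interest for a cohort
#'
#' For every subject x location: scores each trial's deep-breathing HbT SNR,
#' selects the least-noisy trial (excluding the location when all trials fall
#' below the SNR threshold), and computes the six features from the selected
#' trial. Excluded locations keep their row with `NA` features and a reason.
#'
#' @param reconstruction Output of [reconstruct_cohort()] (list with `traces`
#'   and `baselines`).
#' @param protocol A [breathing_protocol()].
#' @param snr_threshold Trial-selection SNR threshold, dB.
#' @param smooth_window,prominence_frac Extremum-detection settings, see
#'   [detect_extrema()].
#' @return Tibble: one row per subject x location with the six feature
#'   columns, `db_snr`, `selected_trial`, `excluded`, `reason`.
#' @export
extract_features <- function(reconstruction, protocol = breathing_protocol(),
                             snr_threshold = 1, smooth_window = 3,
                             prominence_frac = 0.2) {
  traces <- reconstruction$traces
  baselines <- reconstruction$baselines
  keys <- dplyr::distinct(traces, .data$subject_id, .data$location)
  key_of <- function(df) paste(df$subject_id, df$location, sep = "\r")
  parts <- split(traces, factor(key_of(traces), levels = key_of(keys)))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- parts[[i]]
    trials <- sort(unique(sub$trial))
    snrs <- vapply(trials, function(tr) {
      as.numeric(db_snr(sub[sub$trial == tr, ], protocol))
    }, numeric(1))
    sel <- select_trial(snrs, snr_threshold)
    if (sel$excluded) {
      feats <- tibble(!!!stats::setNames(
        as.list(rep(NA_real_, length(FEATURE_NAMES))), FEATURE_NAMES
      ))
      rows[[i]] <- dplyr::bind_cols(
        keys[i, ], feats,
        tibble(db_snr = max(snrs), selected_trial = NA_integer_,
               excluded = TRUE, reason = sel$reason)
      )
      next
    }
    tr_sel <- trials[sel$selected]
    b <- dplyr::semi_join(baselines, keys[i, ], by = c("subject_id", "location"))
    hbt0 <- b$hbt0_uM[b$trial == tr_sel]
    feats <- features_one_trial(sub[sub$trial == tr_sel, ], hbt0, protocol,
                                smooth_window, prominence_frac)
    rows[[i]] <- dplyr::bind_cols(
      keys[i, ], feats,
      tibble(db_snr = snrs[sel$selected], selected_trial = tr_sel,
             excluded = FALSE, reason = NA_character_)
    )
  }
  dplyr::bind_rows(rows)
}

#' Screen features for outliers across subjects
#'
#' Applies the single-pass two-SD rule to every feature within each location
#' group; screened values become `NA`. Applied exactly once in the pipeline.
#'
#' @param features Output of [extract_features()].
#' @return The feature tibble with outliers set to `NA`; attribute `removed`
#'   records location, parameter and subject of each removal.
#' @export
screen_outliers <- function(features) {
  removed <- list()
  for (loc in unique(features$location)) {
    for (p in FEATURE_NAMES) {
      sel <- features$location == loc
      v <- features[[p]][sel]
      if (sum(is.finite(v)) < 3) next
      scr <- remove_outliers(v)
      if (length(scr$removed_idx) > 0) {
        gi <- which(sel)[scr$removed_idx]
        removed[[length(removed) + 1]] <- tibble(
          location = loc, parameter = p,
          subject_id = features$subject_id[gi],
          value = scr$removed
        )
        features[[p]][gi] <- NA_real_
      }
    }
  }
  attr(features, "removed") <- if (length(removed)) dplyr::bind_rows(removed) else
    tibble(location = character(0), parameter = character(0),
           subject_id = character(0), value = numeric(0))
  features
}
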