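# Nonparametric equivalence testing: continuity-corrected Wilcoxon TOST with
# Hodges-Lehmann estimates, Bonferroni adjustment, Kendall correlations,
# Kruskal-Wallis effect sizes, and paired-TOST sample-size calculation.

# One-sided Wilcoxon signed-rank p-value for H0: center(d) = mu, using the
# tie-corrected normal approximation with a +/-0.5 continuity correction
# (the same approximation stats::wilcox.test uses with exact = FALSE,
# correct = TRUE). Zeros after shifting are dropped per the usual convention.
signed_rank_p <- function(d, mu = 0, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- d - mu
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) {
    warning("all differences tie with the shift; signed-rank p is indeterminate",
            call. = FALSE)
    return(0.5)
  }
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  mu_w <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    warning("zero variance in signed ranks", call. = FALSE)
    return(0.5)
  }
  z <- if (alternative == "greater") (W - mu_w - 0.5) / sqrt(sigma2)
       else (W - mu_w + 0.5) / sqrt(sigma2)
  if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
}

# Hodges-Lehmann pseudo-median: median of all Walsh averages of d.
walsh_median <- function(d) {
  n <- length(d)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  stats::median((d[idx[, 1]] + d[idx[, 2]]) / 2)
}

# fast path used by simulations: TOST p-value only
wilcox_tost_p <- function(d, delta) {
  p_lower <- signed_rank_p(d, mu = -delta, alternative = "greater")
  p_upper <- signed_rank_p(d, mu = delta, alternative = "less")
  max(p_lower, p_upper)
}

#' Wilcoxon two one-sided equivalence test (Wilcox-TOST)
#'
#' Tests whether the paired difference `x - y` lies within `(-delta, +delta)`
#' using two one-sided continuity-corrected Wilcoxon signed-rank tests: the
#' lower test shifts the differences by `+delta` and tests for a positive
#' center, the upper test shifts by `-delta` and tests for a negative center;
#' the TOST p-value is the larger of the two. The median of differences (MoD)
#' is the Hodges-Lehmann pseudo-median of the paired differences and the 95%
#' confidence interval comes from signed-rank inversion.
#'
#' @param x,y Paired samples of equal length (n >= 4), or `y = NULL` to treat
#'   `x` as precomputed differences.
#' @param delta Equivalence threshold (> 0), in the units of the data.
#' @param alpha Significance level for the equivalence call.
#' @param m Bonferroni multiplicity applied to the TOST p (default 1).
#' @param conf_level Confidence level of the MoD interval.
#' @return Object of class `wilcox_tost`: list with `n`, `delta`, `p_lower`,
#'   `p_upper`, `p_tost`, `p_adjusted`, `mod`, `ci_low`, `ci_high`,
#'   `equivalent`.
#' @examples
#' set.seed(1)
#' x <- rnorm(20, 0.3, 0.2)
#' wilcox_tost(x, x + rnorm(20, 0, 0.1), delta = 0.5)
#' @export
wilcox_tost <- function(x, y = NULL, delta, alpha = 0.05, m = 1,
                        conf_level = 0.95) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
    x - y
  }
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(delta) != 1 || delta <= 0) stop("delta must be a positive scalar", call. = FALSE)

  p_lower <- signed_rank_p(d, mu = -delta, alternative = "greater")
  p_upper <- signed_rank_p(d, mu = delta, alternative = "less")
  p_tost <- max(p_lower, p_upper)
  p_adj <- bonferroni_adjust(p_tost, m)

  mod <- walsh_median(d)
  ci <- tryCatch(
    suppressWarnings(stats::wilcox.test(
      d, conf.int = TRUE, conf.level = conf_level,
      exact = FALSE, correct = TRUE
    )$conf.int),
    error = function(e) c(min(d), max(d))
  )
  structure(
    list(
      n = n, delta = delta, alpha = alpha, m = m,
      p_lower = p_lower, p_upper = p_upper, p_tost = p_tost,
      p_adjusted = p_adj,
      mod = mod, ci_low = min(ci[1], mod), ci_high = max(ci[2], mod),
      equivalent = p_adj <= alpha
    ),
    class = "wilcox_tost"
  )
}

#' @export
print.wilcox_tost <- function(x, digits = 4, ...) {
  cat("Wilcoxon TOST equivalence test\n")
  cat(sprintf("  n = %d pairs, threshold = %g\n", x$n, x$delta))
  cat(sprintf("  MoD %.4g [%.4g, %.4g]\n", x$mod, x$ci_low, x$ci_high))
  cat(sprintf("  p_tost = %.4g (lower %.4g, upper %.4g), adjusted (m=%d) = %.4g\n",
              x$p_tost, x$p_lower, x$p_upper, x$m, x$p_adjusted))
  cat(sprintf("  equivalent at alpha %.3g: %s\n", x$alpha,
              if (x$equivalent) "yes" else "no"))
  invisible(x)
}

#' @export
tidy.wilcox_tost <- function(x, ...) {
  tibble(
    n = x$n, delta = x$delta, mod = x$mod,
    ci_low = x$ci_low, ci_high = x$ci_high,
    p_lower = x$p_lower, p_upper = x$p_upper,
    p_tost = x$p_tost, p_adjusted = x$p_adjusted,
    equivalent = x$equivalent
  )
}

#' @export
glance.wilcox_tost <- function(x, ...) {
  tibble(n = x$n, p_adjusted = x$p_adjusted, equivalent = x$equivalent)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)`, the per-parameter correction for the number of artery
#' pairs compared.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Number of tests (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, m * p)
}

#' Kendall rank correlation with correlation-strength class
#'
#' Tau-b (tie corrected) with a p-value from the exact distribution for
#' untied small samples and the tie-corrected normal approximation otherwise.
#' Classes: `marginal` when `0.2 < |tau| <= 0.4`, `moderate` when
#' `|tau| > 0.4`, assigned only when the (possibly adjusted) p is <= 0.05.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param m Bonferroni multiplicity for the reported class.
#' @return Tibble `tau, p, p_adjusted, class`.
#' @export
kendall_tau <- function(x, y, m = 1) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must be equal length, n >= 3", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(tau = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                  class = "undefined"))
  }
  tau <- stats::cor(x, y, method = "kendall")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- suppressWarnings(stats::cor.test(
    x, y, method = "kendall",
    exact = !ties && length(x) <= 8
  )$p.value)
  p_adj <- bonferroni_adjust(p, m)
  cls <- if (p_adj > 0.05) "none"
    else if (abs(tau) > 0.4) "moderate"
    else if (abs(tau) > 0.2) "marginal"
    else "none"
  tibble(tau = tau, p = p, p_adjusted = p_adj, class = cls)
}

#' Kruskal-Wallis test with Kruskal's eta-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H with `eta^2 = (H - k + 1) / (n - k)`,
#' floored at zero.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 levels, total n > k).
#' @return Tibble `H, df, p, eta2, n, k`.
#' @export
kruskal_eta2 <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (n <= k) stop("need more observations than groups", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(tibble(H = 0, df = k - 1, p = 1, eta2 = 0, n = n, k = k))
  }
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  tibble(
    H = H, df = unname(kt$parameter), p = kt$p.value,
    eta2 = max((H - k + 1) / (n - k), 0), n = n, k = k
  )
}

#' Power of the parametric paired TOST
#'
#' Noncentral-t approximation: the probability that both one-sided paired
#' t-tests against the `+/-delta` bounds reject, computed as
#' `P(lower rejects) + P(upper rejects) - 1` (floored at 0).
#'
#' @param n Number of pairs.
#' @param sd_diff SD of the paired differences.
#' @param delta Equivalence threshold (> |true_diff|).
#' @param alpha One-sided level.
#' @param true_diff True mean difference.
#' @return Power in `[0, 1]`.
#' @export
paired_tost_power <- function(n, sd_diff, delta, alpha = 0.05, true_diff = 0) {
  df <- n - 1
  se <- sd_diff / sqrt(n)
  tc <- qt(1 - alpha, df)
  p_lower <- pt(tc, df, ncp = (true_diff + delta) / se, lower.tail = FALSE)
  p_upper <- pt(-tc, df, ncp = (true_diff - delta) / se)
  max(p_lower + p_upper - 1, 0)
}

#' Sample size for the paired TOST
#'
#' Smallest n (pairs) achieving the target power for declaring equivalence
#' within `+/-delta` at one-sided level `alpha`, using the parametric
#' noncentral-t power of [paired_tost_power()].
#'
#' @param sd_diff SD of the paired differences (> 0).
#' @param delta Equivalence threshold; must exceed `|true_diff|`.
#' @param power Target power in (0, 1).
#' @param alpha One-sided level.
#' @param true_diff Assumed true difference.
#' @param n_max Search cap.
#' @return Integer sample size.
#' @export
tost_sample_size <- function(sd_diff, delta, power = 0.8, alpha = 0.05,
                             true_diff = 0, n_max = 10000) {
  if (sd_diff <= 0) stop("sd_diff must be positive", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  if (delta <= abs(true_diff)) {
    stop("infeasible: delta must exceed |true_diff|", call. = FALSE)
  }
  for (n in 4:n_max) {
    if (paired_tost_power(n, sd_diff, delta, alpha, true_diff) >= power) return(n)
  }
  stop("no n <= n_max reaches the target power", call. = FALSE)
}

# artery pairs compared, in reporting order
artery_pairs <- function() {
  list(
    c("left_radial", "left_carotid"),
    c("right_radial", "right_carotid"),
    c("left_radial", "right_radial"),
    c("left_carotid", "right_carotid")
  )
}

#' Published equivalence thresholds for the six parameters
#'
#' The per-parameter equivalence bounds used in the reference analysis:
#' breath-hold maximum % change thresholds 3.7% (HbT) and 3.2% (StO2),
#' deep-breathing peak-to-peak 1.2 uM (HbT) and 0.5% (StO2), and oscillation
#' times 2.1 s (HbT) and 1.4 s (StO2).
#'
#' @return Named numeric vector keyed by feature name.
#' @export
default_equivalence_thresholds <- function() {
  c(
    bh_max_pct_change_hbt = 3.7,
    bh_max_pct_change_sto2 = 3.2,
    db_mean_pkpk_hbt = 1.2,
    db_mean_pkpk_sto2 = 0.5,
    db_mean_osc_time_hbt = 2.1,
    db_mean_osc_time_sto2 = 1.4
  )
}

#' Threshold-from-SD rule
#'
#' A pluggable rule deriving an equivalence bound from the two arm SDs
#' (default: their maximum). Note this rule does not reproduce every
#' published threshold; the shipped defaults in
#' [default_equivalence_thresholds()] are the printed values.
#'
#' @param sd_x,sd_y Arm standard deviations.
#' @return Threshold.
#' @export
threshold_from_sd <- function(sd_x, sd_y) {
  max(sd_x, sd_y)
}

#' Run the full equivalence battery on a feature table
#'
#' For each of the six parameters and each of the four artery pairs
#' (left radial-left carotid, right radial-right carotid, left-right radial,
#' left-right carotid), subjects with both locations present enter a paired
#' [wilcox_tost()] at the parameter's threshold, Bonferroni-adjusted by the
#' number of pairs tested per parameter. When a `profiles` table is given,
#' Kendall correlations of each feature against vitals (and carotid anatomy
#' for carotid locations) and Kruskal-Wallis effect sizes for sex, race and
#' skin tone are also computed.
#'
#' @param features Feature table from [extract_features()] (ideally after
#'   [screen_outliers()]).
#' @param thresholds Named thresholds, see [default_equivalence_thresholds()].
#' @param alpha Equivalence level on the adjusted p.
#' @param m Bonferroni multiplicity (default: pairs per parameter, 4).
#' @param profiles Optional subject profile table.
#' @return Object of class `nirs_equivalence`: list with tibbles
#'   `equivalence`, `correlations`, `group_effects`, `skipped`.
#' @export
equivalence_battery <- function(features,
                                thresholds = default_equivalence_thresholds(),
                                alpha = 0.05, m = 4, profiles = NULL) {
  if (nrow(features) == 0) {
    warning("empty feature table: no comparisons run", call. = FALSE)
    return(structure(list(
      equivalence = tibble(), correlations = tibble(),
      group_effects = tibble(), skipped = tibble()
    ), class = "nirs_equivalence"))
  }
  eq_rows <- list()
  skipped <- list()
  for (p in FEATURE_NAMES) {
    for (pair in artery_pairs()) {
      a <- features[features$location == pair[1], c("subject_id", p)]
      b <- features[features$location == pair[2], c("subject_id", p)]
      j <- dplyr::inner_join(a, b, by = "subject_id", suffix = c("_x", "_y"))
      d <- j[[paste0(p, "_x")]] - j[[paste0(p, "_y")]]
      d <- d[is.finite(d)]
      label <- paste(pair, collapse = " vs ")
      if (length(d) < 4) {
        skipped[[length(skipped) + 1]] <- tibble(
          parameter = p, pair = label,
          reason = sprintf("only %d complete pairs", length(d))
        )
        next
      }
      res <- wilcox_tost(d, delta = thresholds[[p]], alpha = alpha, m = m)
      eq_rows[[length(eq_rows) + 1]] <- dplyr::bind_cols(
        tibble(parameter = p, pair = label), tidy(res)
      )
    }
  }
  correlations <- tibble()
  group_effects <- tibble()
  if (!is.null(profiles)) {
    correlations <- feature_correlations(features, profiles)
    group_effects <- feature_group_effects(features, profiles)
  }
  structure(
    list(
      equivalence = dplyr::bind_rows(eq_rows),
      correlations = correlations,
      group_effects = group_effects,
      skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
        tibble(parameter = character(0), pair = character(0), reason = character(0))
    ),
    class = "nirs_equivalence"
  )
}

feature_correlations <- function(features, profiles) {
  vitals <- c("heart_rate_bpm", "systolic_bp_mmHg", "diastolic_bp_mmHg")
  anat <- list(
    left_carotid = c("left_bulb_depth_mm", "left_bulb_diameter_mm",
                     "left_ica_diameter_mm", "left_eca_diameter_mm"),
    right_carotid = c("right_bulb_depth_mm", "right_bulb_diameter_mm",
                      "right_ica_diameter_mm", "right_eca_diameter_mm")
  )
  df <- dplyr::left_join(features, profiles, by = "subject_id")
  rows <- list()
  for (loc in unique(df$location)) {
    covars <- c(vitals, anat[[loc]])
    sub <- df[df$location == loc, ]
    for (p in FEATURE_NAMES) {
      for (cv in covars) {
        ok <- is.finite(sub[[p]]) & is.finite(sub[[cv]])
        if (sum(ok) < 3) next
        kt <- kendall_tau(sub[[p]][ok], sub[[cv]][ok], m = length(covars))
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(location = loc, parameter = p, covariate = cv), kt
        )
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else tibble()
}

feature_group_effects <- function(features, profiles) {
  factors <- c("sex_assigned_at_birth", "race_group", "skin_tone")
  df <- dplyr::left_join(features, profiles, by = "subject_id")
  rows <- list()
  for (loc in unique(df$location)) {
    sub <- df[df$location == loc, ]
    for (p in FEATURE_NAMES) {
      for (fc in factors) {
        ok <- is.finite(sub[[p]]) & !is.na(sub[[fc]])
        g <- factor(sub[[fc]][ok])
        if (nlevels(g) < 2 || sum(ok) <= nlevels(g)) next
        ke <- kruskal_eta2(sub[[p]][ok], g)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(location = loc, parameter = p, factor = fc), ke
        )
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else tibble()
}

#' @export
print.nirs_equivalence <- function(x, ...) {
  cat("<nirs_equivalence>\n")
  if (nrow(x$equivalence) == 0) {
    cat("  no comparisons run\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$equivalence))) {
    r <- x$equivalence[i, ]
    cat(sprintf(
      "  %-24s %-32s MoD %8.4g [%8.4g, %8.4g]; p = %.3g%s\n",
      r$parameter, r$pair, r$mod, r$ci_low, r$ci_high, r$p_adjusted,
      if (r$equivalent) " *" else ""
    ))
  }
  if (nrow(x$skipped) > 0) cat("  skipped:", nrow(x$skipped), "comparisons\n")
  invisible(x)
}

#' @export
tidy.nirs_equivalence <- function(x, ...) {
  x$equivalence
}
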