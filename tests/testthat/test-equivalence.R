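test_that("signed-rank p-values agree with the base R implementation", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    d <- round(rnorm(n, sd = sample(c(0.5, 1, 2), 1)), sample(0:2, 1))
    d <- d[d != 0]
    if (length(d) < 4) next
    for (alt in c("greater", "less")) {
      mine <- carotidnirs:::signed_rank_p(d, mu = 0, alternative = alt)
      ref <- suppressWarnings(stats::wilcox.test(
        d, mu = 0, alternative = alt, exact = FALSE, correct = TRUE
      )$p.value)
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  }
})

test_that("TOST p matches exhaustive sign enumeration on the worked example", {
  d <- c(0.01, -0.01, 0.02, -0.02, 0.01, -0.01)
  p_norm <- carotidnirs:::wilcox_tost_p(d, delta = 1)
  p_exact <- enum_wilcox_tost_p(d, delta = 1)
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("normal approximation stays within 0.02 of enumeration for n <= 10", {
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    n <- sample(5:10, 1)
    d <- rnorm(n, mean = runif(1, -0.5, 0.5))
    delta <- runif(1, 0.2, 1.5)
    p_norm <- carotidnirs:::wilcox_tost_p(d, delta)
    p_exact <- enum_wilcox_tost_p(d, delta)
    worst <- max(worst, abs(p_norm - p_exact))
  }
  expect_lt(worst, 0.02)
})

test_that("TOST p-value is monotone in the equivalence threshold", {
  set.seed(3)
  d <- rnorm(15, 0, 0.5)
  deltas <- c(0.05, 0.2, 0.5, 1, 3, 10)
  ps <- vapply(deltas, function(dl) carotidnirs:::wilcox_tost_p(d, dl), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_lt(ps[length(ps)], 0.001)
  expect_gt(ps[1], 0.5)
})

test_that("wilcox_tost returns a coherent equivalence result", {
  set.seed(8)
  arms <- draw_paired_arms(20, 0.3, 0.3, 0.2, 0.2, 0.5)
  res <- wilcox_tost(arms$x, arms$y, delta = 0.5, m = 4)
  expect_s3_class(res, "wilcox_tost")
  expect_equal(res$p_tost, max(res$p_lower, res$p_upper))
  expect_gte(res$p_adjusted, res$p_tost)
  expect_true(res$ci_low <= res$mod && res$mod <= res$ci_high)
  # MoD is the median of Walsh averages of the differences
  d <- arms$x - arms$y
  walsh <- outer(d, d, "+")[upper.tri(matrix(0, 20, 20), diag = TRUE)] / 2
  expect_equal(res$mod, median(walsh))
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_named(glance(res), c("n", "p_adjusted", "equivalent"))
  expect_error(wilcox_tost(1:3, 2:4, delta = 1), "at least 4")
  expect_error(wilcox_tost(1:10, delta = -1), "positive scalar")
  expect_warning(wilcox_tost(rep(0.5, 10), delta = 0.5), "indeterminate")
})

test_that("confidence interval width shrinks with sample size", {
  widths <- vapply(c(10, 20, 40), function(n) {
    set.seed(400 + n)
    mean(replicate(20, {
      d <- rnorm(n, 0, 1)
      r <- wilcox_tost(d, delta = 2)
      r$ci_high - r$ci_low
    }))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("paper-matched arm simulation declares equivalence almost always", {
  set.seed(1234)
  hits <- replicate(500, {
    arms <- draw_paired_arms(20, 0.3, 0.3, 0.2, 0.2, 0.5)
    p <- bonferroni_adjust(carotidnirs:::wilcox_tost_p(arms$x - arms$y, 0.5), 4)
    p <= 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a difference of twice the threshold is never called equivalent", {
  set.seed(555)
  hits <- replicate(100, {
    arms <- draw_paired_arms(20, 1.0 + 2 * 0.5, 1.0, 0.3, 0.3, 0.5)
    p <- bonferroni_adjust(carotidnirs:::wilcox_tost_p(arms$x - arms$y, 0.5), 4)
    p > 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Bonferroni adjustment caps and dominates the raw p", {
  expect_equal(bonferroni_adjust(0.01, 4), 0.04)
  expect_equal(bonferroni_adjust(0.5, 4), 1)
  set.seed(2)
  p <- runif(50)
  expect_true(all(bonferroni_adjust(p, 3) >= p))
  expect_error(bonferroni_adjust(1.2, 2), "0, 1")
  expect_error(bonferroni_adjust(0.5, 0), ">= 1")
})

test_that("Kendall tau matches pair enumeration and handles edge cases", {
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2))$tau, 1 / 3)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2))$tau,
               enum_kendall_tau(c(1, 2, 3), c(1, 3, 2)))
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(kendall_tau(x, y)$tau, enum_kendall_tau(x, y), tolerance = 1e-12)
  }
  expect_equal(kendall_tau(rep(1, 5), 1:5)$class, "undefined")
  # classes respect both the magnitude cuts and the significance gate
  strong <- kendall_tau(1:20, 1:20)
  expect_equal(strong$class, "moderate")
})

test_that("Kruskal-Wallis eta-squared follows its defining formula", {
  set.seed(7)
  v <- rnorm(20)
  g <- factor(rep(c("a", "b", "c"), length.out = 20))
  out <- kruskal_eta2(v, g)
  H <- unname(stats::kruskal.test(v, g)$statistic)
  expect_equal(out$eta2, max((H - 3 + 1) / (20 - 3), 0))
  # H = 3.2, k = 3, n = 20 must give (3.2 - 2)/17
  expect_equal((3.2 - 3 + 1) / (20 - 3), 0.07058824, tolerance = 1e-7)
  same <- kruskal_eta2(rep(2, 9), factor(rep(1:3, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$eta2, 0)
  expect_error(kruskal_eta2(1:2, factor(1:2)), "more observations")
})

test_that("null-group eta-squared is negligible on average", {
  set.seed(11)
  e <- replicate(500, {
    v <- rnorm(20)
    g <- factor(rep(c("a", "b", "c"), length.out = 20))
    kruskal_eta2(v, g)$eta2
  })
  expect_lt(mean(e), 0.05)
})

test_that("TOST sample size matches a Monte-Carlo power curve within one", {
  sd_diff <- 1; delta <- 1
  n_star <- tost_sample_size(sd_diff, delta, power = 0.8, alpha = 0.05)
  mc_power <- function(n, reps = 40000) {
    set.seed(1000 + n)
    d <- matrix(rnorm(n * reps, 0, sd_diff), nrow = n)
    m <- colMeans(d)
    s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
    se <- s / sqrt(n)
    tc <- qt(0.95, n - 1)
    mean((m + delta) / se >= tc & (m - delta) / se <= -tc)
  }
  # the chosen n reaches the target and n - 2 does not: the MC crossing
  # point sits within one of the parametric answer
  expect_gte(mc_power(n_star), 0.8 - 0.02)
  expect_lt(mc_power(max(n_star - 2, 4)), 0.8 + 0.02)
  expect_lte(tost_sample_size(sd_diff, 2 * delta), n_star)
  expect_gte(tost_sample_size(sd_diff, delta, power = 0.9), n_star)
  expect_error(tost_sample_size(1, 0.5, true_diff = 0.6), "infeasible")
})

test_that("the equivalence battery runs all pairs and honours thresholds", {
  thr <- default_equivalence_thresholds()
  expect_equal(unname(thr[c("db_mean_pkpk_hbt", "db_mean_pkpk_sto2",
                            "bh_max_pct_change_hbt", "bh_max_pct_change_sto2",
                            "db_mean_osc_time_hbt", "db_mean_osc_time_sto2")]),
               c(1.2, 0.5, 3.7, 3.2, 2.1, 1.4))

  set.seed(60)
  locs <- c("left_radial", "right_radial", "left_carotid", "right_carotid")
  features <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:12),
                                 location = locs)
  for (p in carotidnirs:::FEATURE_NAMES) features[[p]] <- rnorm(nrow(features), 3, 0.1)
  features$db_snr <- 10; features$selected_trial <- 1L
  features$excluded <- FALSE; features$reason <- NA_character_
  res <- equivalence_battery(features)
  expect_s3_class(res, "nirs_equivalence")
  expect_equal(nrow(res$equivalence), 6 * 4)
  expect_true(all(res$equivalence$p_adjusted >= res$equivalence$p_tost))
  expect_true(all(res$equivalence$delta ==
                    thr[res$equivalence$parameter]))

  # dropping one arm's subjects skips those comparisons with a reason
  features2 <- features[!(features$location == "right_carotid" &
                            features$subject_id %in% sprintf("S%02d", 1:9)), ]
  res2 <- equivalence_battery(features2)
  expect_true(all(grepl("complete pairs", res2$skipped$reason)))
  expect_equal(nrow(res2$equivalence) + nrow(res2$skipped), 24)

  expect_warning(res3 <- equivalence_battery(features[0, ]), "empty")
  expect_equal(nrow(res3$equivalence), 0)
})

test_that("boundary-true differences keep the equivalence rate near alpha", {
  set.seed(71)
  reps <- 2000
  hits <- replicate(reps, {
    d <- rnorm(20, mean = 0.5, sd = 0.2)
    carotidnirs:::wilcox_tost_p(d, delta = 0.5) <= 0.05
  })
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / reps) + 0.02)
})
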