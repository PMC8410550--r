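test_that("Welch's t test matches its reference behaviour", {
  a <- c(1.1, 2.3, 3.1, 4.2)
  # identical samples: no evidence either way
  same <- welch_t(a, a, "less")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  # frozen independent evaluation of the one-sided p
  b <- c(2.0, 3.5, 4.1, 5.9, 6.3)
  res <- welch_t(a, b, "less")
  expect_equal(res$statistic, -1.6421319879076455, tolerance = 1e-10)
  expect_equal(res$p_value, 0.0723281371692312, tolerance = 1e-10)
  # equal n and variance: Welch statistic equals Student's t
  set.seed(2)
  x <- rnorm(30); y <- rnorm(30)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y) # force equal variance
  expect_equal(welch_t(x, y, "less")$statistic,
               t.test(x, y, var.equal = TRUE, alternative = "less")$statistic[[1]],
               tolerance = 1e-10)
  # degenerate zero-variance convention
  expect_message(r0 <- welch_t(c(1, 1), c(1, 1), "less"), "zero variance")
  expect_equal(r0$p_value, 1)
  suppressMessages({
    expect_equal(welch_t(c(0, 0), c(1, 1), "less")$p_value, 0)
    expect_equal(welch_t(c(0, 0), c(1, 1), "greater")$p_value, 1)
  })
})

test_that("Wilcoxon rank-sum matches exact enumeration and midranks", {
  # all 6 arrangements equally likely; observed is the most extreme one
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4), "less")$p_value, 1 / 6)
  set.seed(3)
  x <- rnorm(15)
  expect_gte(wilcoxon_ranksum(x, x, "less")$p_value, 0.5)
  # tied data: statistic equals the midrank pair count
  a <- c(1, 2, 2, 3, 7); b <- c(2, 3, 3, 5)
  U <- 0
  for (ai in a) for (bj in b) U <- U + (ai > bj) + 0.5 * (ai == bj)
  expect_equal(wilcoxon_ranksum(a, b, "less")$statistic, U)
})

test_that("Cohen's d and its confidence interval follow the pooled-SD form", {
  set.seed(6)
  x <- rnorm(20)
  expect_equal(cohens_d(x, x)$estimate, 0)
  d <- cohens_d(c(0, 2), c(-1, 1))
  expect_equal(d$estimate, 0.7071067811865475)
  se <- sqrt(d$estimate^2 / (2 * 4) + 4 / 4)
  expect_equal(d$ci_high - d$ci_low, 2 * qnorm(0.975) * se)
  expect_true(d$ci_low <= d$estimate && d$estimate <= d$ci_high)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
  # a one-SD mean shift recovers d ~ 1
  big <- cohens_d(rnorm(1000, 1), rnorm(1000, 0))
  expect_lt(abs(big$estimate - 1), 0.1)
})

test_that("Cliff's delta matches pair counting and links to the AUC", {
  set.seed(10)
  x <- rnorm(15)
  expect_equal(cliffs_delta(x, x)$estimate, 0)
  expect_equal(cliffs_delta(11:15, 1:5)$estimate, 1)
  a <- rnorm(15, 0.4); b <- rnorm(12)
  cd <- cliffs_delta(a, b)
  expect_equal(cd$estimate, oracle_cliffs(a, b))
  expect_true(cd$ci_low <= cd$estimate && cd$estimate <= cd$ci_high)
  expect_true(cd$ci_low >= -1 && cd$ci_high <= 1)
  # antisymmetry
  expect_equal(cliffs_delta(b, a)$estimate, -cd$estimate)
  # delta = 2*AUC - 1 with patients as `a`
  scores <- c(a, b)
  labels <- rep(c("patient", "control"), c(15, 12))
  expect_equal(cd$estimate, 2 * auc(scores, labels) - 1, tolerance = 1e-12)
})

test_that("paired effect-size comparison detects a consistent z advantage", {
  es_raw <- seq(0.1, 0.4, length.out = 18)
  expect_error(compare_effectsize_paired(es_raw, es_raw), "zero variance")
  expect_error(compare_effectsize_paired(es_raw + 0.1, es_raw), "zero variance")
  set.seed(14)
  es_z <- es_raw + 0.1 + rnorm(18, 0, 0.02)
  res <- compare_effectsize_paired(es_z, es_raw)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$effect_size, 0)
  expect_equal(res$effect_size, mean(es_z - es_raw) / sd(es_z - es_raw))
})

test_that("one-tailed tests hold their nominal size under the null", {
  set.seed(99)
  reps <- 1000
  pw <- pt_w <- numeric(reps)
  for (i in seq_len(reps)) {
    a <- rnorm(50); b <- rnorm(50)
    pw[i] <- welch_t(a, b, "less", effect = FALSE)$p_value
    pt_w[i] <- wilcoxon_ranksum(a, b, "less", effect = FALSE)$p_value
  }
  expect_gt(mean(pw < 0.05), 0.03); expect_lt(mean(pw < 0.05), 0.07)
  expect_gt(mean(pt_w < 0.05), 0.03); expect_lt(mean(pt_w < 0.05), 0.07)
  # the two tails are complementary for continuous data
  a <- rnorm(12); b <- rnorm(14)
  expect_equal(welch_t(a, b, "less", effect = FALSE)$p_value +
                 welch_t(a, b, "greater", effect = FALSE)$p_value, 1)
})

test_that("per-ROI comparisons test the modality's fixed direction", {
  expect_equal(modality_direction("FA"), "less")
  expect_equal(modality_direction("FAt"), "less")
  expect_equal(modality_direction("FW"), "greater")
  expect_error(modality_direction("MD"), "unknown modality")
  # strong FW increase in every tract: the majority of ROIs significant
  cfg <- cohort_config(n_controls = 250, n_patients = 250, seed = 55,
                       affected_roi_counts = 17L,
                       effect_size_range = list(FW = c(0.3, 0.3)),
                       noise_sd = c(FW = 0.015))
  ch <- simulate_cohort(cfg)
  res <- roi_group_comparison(ch, "FW", "raw")
  expect_equal(nrow(res), 18L)
  expect_true(all(res$direction == "greater"))
  expect_gt(mean(res$p_value < 0.05), 0.5)
  # effect sizes positive (patients higher), strongest in the skeleton average
  expect_gt(res$effect_size[res$roi == "WM_skeleton"], 0.2)
})

test_that("summary-measure group comparisons run with modality-specific tails", {
  ch <- small_cohort(n_controls = 60, n_patients = 60, seed = 77)
  z <- compute_zscores(ch, "FA", grid = tiny_grid())$zscores
  sm <- summary_measures(z)
  grp <- ch$subjects$group
  res <- summary_group_comparison(sm[grp == "control", ], sm[grp == "patient", ],
                                  modality = "FA")
  expect_true(all(c("load", "severity", "mean_z", "sd_z") %in% res$measure))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$ci_low <= res$effect_size & res$effect_size <= res$ci_high))
})
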