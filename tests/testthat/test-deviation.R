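test_that("the Bonferroni z threshold matches the normal quantile", {
  expect_equal(round(bonferroni_z_threshold(18, 0.05), 4), 2.9913)
  expect_equal(round(bonferroni_z_threshold(1, 0.05), 4), 1.9600)
  # frozen independent quantile evaluation at 1 - 0.05/4
  expect_equal(bonferroni_z_threshold(2, 0.05), 2.241402727604947,
               tolerance = 1e-12)
  expect_error(bonferroni_z_threshold(18, 0), "alpha")
  expect_error(bonferroni_z_threshold(18, 1.5), "alpha")
})

make_z <- function(Z) {
  Z <- as.matrix(Z)
  dimnames(Z) <- list(NULL, sprintf("roi%02d", seq_len(ncol(Z))))
  dplyr::bind_cols(tibble::tibble(id = sprintf("s%02d", seq_len(nrow(Z)))),
                   tibble::as_tibble(Z))
}

test_that("abnormality counts match a brute-force double loop", {
  thr <- bonferroni_z_threshold()
  Z0 <- matrix(0, 5, 18)
  cnt <- count_abnormal_per_roi(make_z(Z0), thr, "infra")
  expect_true(all(cnt$n_abnormal == 0))
  expect_equal(attr(cnt, "n_subjects_any"), 0L)

  Z1 <- matrix(0, 1, 18); Z1[1, 1] <- -5
  cnt1 <- count_abnormal_per_roi(make_z(Z1), thr, "infra")
  expect_equal(cnt1$n_abnormal[1], 1)
  expect_true(all(cnt1$n_abnormal[-1] == 0))
  expect_equal(attr(cnt1, "n_subjects_any"), 1L)
  expect_equal(count_abnormal_per_roi(make_z(Z1), thr, "supra")$n_abnormal[1], 0)

  set.seed(33)
  Z <- matrix(rnorm(20 * 18, sd = 2), 20, 18)
  for (dir in c("infra", "supra")) {
    got <- count_abnormal_per_roi(make_z(Z), thr, dir)
    loop <- integer(18); any_loop <- 0L
    for (i in 1:20) {
      hit <- FALSE
      for (j in 1:18) {
        abn <- if (dir == "infra") Z[i, j] < -thr else Z[i, j] > thr
        if (abn) { loop[j] <- loop[j] + 1L; hit <- TRUE }
      }
      if (hit) any_loop <- any_loop + 1L
    }
    expect_equal(got$n_abnormal, loop)
    expect_equal(attr(got, "n_subjects_any"), any_loop)
  }
})

test_that("summary measures follow their definitions", {
  thr <- bonferroni_z_threshold()
  z1 <- c(3.5, -3.5, rep(0, 16))
  sm <- summary_measures(make_z(rbind(z1)), thr)
  expect_equal(sm$load, 2 / 18)
  expect_equal(sm$mean_z, mean(z1))
  expect_equal(sm$sd_z, sd(z1))

  z2 <- c(1, -4, 2, rep(0, 15))
  expect_equal(summary_measures(make_z(rbind(z2)), thr)$severity, -4)

  sr <- list(lower = -3.36, upper = -0.6)
  smr <- summary_measures(make_z(rbind(rep(-1, 18))), thr, sig_range = sr)
  expect_equal(smr$frac_sig_range, 1.0)

  # monotone: raising the threshold never increases load
  set.seed(4)
  Z <- matrix(rnorm(30 * 18, sd = 3), 30, 18)
  loads <- vapply(c(1, 2, 3, 4), function(t) {
    sum(summary_measures(make_z(Z), t)$load)
  }, numeric(1))
  expect_true(all(diff(loads) <= 0))
  # severity invariant under ROI permutation
  perm <- sample(18)
  expect_equal(summary_measures(make_z(Z), thr)$severity,
               summary_measures(make_z(Z[, perm]), thr)$severity)
})

test_that("the regularised z-density matches a per-bin kernel sum", {
  d0 <- z_density(0, kde_bandwidth = 1)
  expect_equal(nrow(d0), 50L)
  expect_equal(d0$density, rev(d0$density)) # symmetric about 0
  expect_true(all(d0$density >= 0))
  expect_equal(which.max(d0$density), 25L) # one of the two central bins

  set.seed(8)
  z <- rnorm(18)
  bw <- 0.7
  got <- z_density(z, kde_bandwidth = bw)
  centers <- z_density_bins()
  loop <- vapply(centers, function(cc) {
    s <- 0
    for (zz in z) s <- s + exp(-0.5 * ((cc - zz) / bw)^2) / sqrt(2 * pi)
    s / (length(z) * bw)
  }, numeric(1))
  expect_equal(got$density, loop, tolerance = 1e-12)
  # interior mass integrates to ~1 over the 0.4-wide bins
  expect_equal(sum(got$density) * 0.4, 1, tolerance = 0.01)
  # translation equivariance within one bin width
  g1 <- z_density(z, kde_bandwidth = bw)
  g2 <- z_density(z + 2, kde_bandwidth = bw)
  shift <- centers[which.max(g2$density)] - centers[which.max(g1$density)]
  expect_lt(abs(shift - 2), 0.4 + 1e-9)
})

test_that("the significant range recovers a known density shift", {
  set.seed(91)
  n <- 60
  Zc <- matrix(rnorm(n * 18), n, 18)
  Zp <- matrix(rnorm(n * 18), n, 18)
  # patients: extra mass in (-3, -1) in a third of the ROIs
  Zp[, 1:6] <- runif(n * 6, -3, -1)
  dc <- z_densities(make_z(Zc))
  dp <- z_densities(make_z(Zp))
  sr <- significant_range(dc, dp, alpha = 0.05)
  expect_s3_class(sr, "nd_sigrange")
  expect_lt(sr$lower, -1)
  expect_gt(sr$upper, -3)
  expect_true(sr$lower < sr$upper)
  # per-bin p-values equal a direct Welch test bin by bin
  Dc <- as.matrix(dc[, -1]); Dp <- as.matrix(dp[, -1])
  for (b in c(1, 18, 36)) {
    expect_equal(sr$p_values[b],
                 t.test(Dp[, b], Dc[, b], alternative = "greater",
                        var.equal = FALSE)$p.value)
  }
  # identical groups: empty-range sentinel
  sr0 <- significant_range(dc, dc, alpha = 0.05)
  expect_true(is.na(sr0$lower) && is.na(sr0$upper))
  expect_true(all(sr0$p_values >= 0.5 - 1e-9 | sr0$p_values == 1))
  # degenerate bins (zero variance in both groups) get p = 1
  Dz <- matrix(0, 4, 50); Dz[, 25] <- c(1, 2, 3, 4)
  srz <- significant_range(Dz, Dz, alpha = 0.05)
  expect_true(all(srz$p_values[-25] == 1))
  g <- glance(sr)
  expect_named(g, c("lower", "upper", "n_significant", "alpha"))
})
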