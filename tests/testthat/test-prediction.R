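test_that("fold design reproduces the balanced partition contract", {
  for (s in c(1, 2, 99)) {
    fs <- fold_sizes(make_folds(512, 601, k = 10, seed = s))
    combo <- sort(paste(fs$n_controls, fs$n_patients))
    expect_equal(combo, sort(c(rep("51 60", 7), rep("52 60", 2), "51 61")))
  }
  # trivial case: every fold (1, 1)
  fs <- fold_sizes(make_folds(10, 10, k = 10, seed = 1))
  expect_true(all(fs$n_controls == 1) && all(fs$n_patients == 1))
  # 7 controls / 9 patients in 3 folds: {(3,3),(2,3),(2,3)}
  fs <- fold_sizes(make_folds(7, 9, k = 3, seed = 4))
  expect_equal(sort(paste(fs$n_controls, fs$n_patients)),
               c("2 3", "2 3", "3 3"))
  # every subject appears exactly once
  f <- make_folds(23, 31, k = 5, seed = 2)
  expect_equal(nrow(f), 54L)
  expect_equal(nrow(dplyr::distinct(f, group, index)), 54L)
  expect_error(make_folds(5, 50, k = 10), "at least k")
})

test_that("feature sets have the documented shapes and column order", {
  ch <- small_cohort(n_controls = 30, n_patients = 20, seed = 21)
  g <- tiny_grid()
  zs <- lapply(stats::setNames(c("FA", "FAt", "FW"), c("FA", "FAt", "FW")),
               function(m) compute_zscores(ch, m, grid = g)$zscores)
  one <- build_feature_set(ch, "z:FA:Fmajor", zscores = zs)
  expect_equal(ncol(one), 1L)
  both <- build_feature_set(ch, "z:FAt+FW:all", zscores = zs)
  expect_equal(ncol(both), 36L)
  expect_equal(colnames(both)[1], "FAt_Fmajor")
  expect_equal(colnames(both)[19], "FW_Fmajor") # FAt block first, then FW
  raw <- build_feature_set(ch, "raw:FA:all")
  expect_equal(ncol(raw), 18L)
  sm <- list(FA = summary_measures(zs$FA))
  with_sum <- build_feature_set(ch, "z:FA:all+summaries", zscores = zs,
                                summaries = sm)
  expect_equal(ncol(with_sum), 23L)
  expect_error(build_feature_set(ch, "z:FA:all+summaries", zscores = zs,
                                 summaries = list(FA = sm$FA[1:5, ])),
               "aligned")
  expect_error(build_feature_set(ch, "pca:FA:all"), "kind")
})

test_that("ridge logistic regression minimises the stated objective", {
  set.seed(31)
  n <- 60
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  eta <- 0.5 + X[, 1] - 0.8 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  lambda <- 0.7
  fit <- fit_l2_logistic(X, y, lambda = lambda)
  # independent general-purpose minimiser of the same objective
  Xs <- scale(X)
  obj <- function(th) {
    e <- th[1] + drop(Xs %*% th[-1])
    mean(log(1 + exp(e)) - y * e) + lambda / 2 * sum(th[-1]^2)
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), opt$par,
               tolerance = 1e-5)
  # heavy penalty: coefficients vanish, intercept -> log-odds of prevalence
  hv <- fit_l2_logistic(X, y, lambda = 1e6)
  expect_lt(max(abs(hv$coefficients)), 1e-4)
  expect_equal(hv$intercept, qlogis(mean(y)), tolerance = 1e-3)
  # perfectly separable 1-D data stay finite with the correct sign
  xs <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  ys <- c(0, 0, 0, 1, 1, 1)
  sep <- fit_l2_logistic(xs, ys, lambda = 0.5)
  expect_true(is.finite(sep$coefficients[1]) && sep$coefficients[1] > 0)
  expect_error(fit_l2_logistic(X, rep(1, n)), "both classes")
})

test_that("ridge fit agrees with glmnet on the shared parameterisation", {
  skip_if_not_installed("glmnet")
  set.seed(41)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(0.3 + X[, 1] - 0.5 * X[, 3]))
  lambda <- 0.3
  fit <- fit_l2_logistic(X, y, lambda = lambda)
  Xs <- scale(X)
  gn <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                       lambda = c(5, 2, 1, 0.5, lambda),
                       standardize = FALSE, thresh = 1e-14)
  co <- as.numeric(glmnet::coef.glmnet(gn, s = lambda, exact = TRUE,
                                       x = Xs, y = y))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), co,
               tolerance = 1e-4)
})

test_that("the AUC is the Mann-Whitney probability with midrank ties", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1)
  set.seed(51)
  s <- rnorm(2000); l <- rbinom(2000, 1, 0.5)
  expect_lt(abs(auc(s, l) - 0.5), 0.05)
  # 8-point instance with a tie vs pair counting
  sc <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.2, 0.4, 0.9)
  y <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(auc(sc, y), oracle_auc(sc, y))
  # random instances: rank formula == loop count; complementary scores
  for (i in 1:5) {
    n <- sample(10:60, 1)
    sc <- sample(seq_len(30), n, replace = TRUE) / 10
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(auc(sc, y), oracle_auc(sc, y))
  }
  sc <- rnorm(40); y <- rep(c(TRUE, FALSE), 20)
  expect_equal(auc(sc, y) + auc(-sc, y), 1)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("cross-validation is order-invariant and actually refits per fold", {
  ch <- small_cohort(n_controls = 40, n_patients = 40, seed = 61)
  g <- tiny_grid()
  cv1 <- cross_validate(ch, "z:FA:all", k = 4, seed = 3, grid = g)
  # permute subject rows: same seed must give identical per-fold AUCs
  perm <- withr::with_seed(1, sample(nrow(ch$subjects)))
  chp <- ch
  chp$subjects <- ch$subjects[perm, ]
  chp$measures <- lapply(ch$measures, function(tab) tab[perm, ])
  cv2 <- cross_validate(chp, "z:FA:all", k = 4, seed = 3, grid = g)
  expect_equal(cv1$auc, cv2$auc, tolerance = 1e-12)
  # replacing the per-fold normative refit with a full-data fit changes folds
  cv_leaky <- cross_validate(ch, "z:FA:all", k = 4, seed = 3, grid = g,
                             refit_per_fold = FALSE)
  expect_false(isTRUE(all.equal(cv1$auc, cv_leaky$auc)))
  # mean AUC is the unweighted fold mean
  expect_equal(glance(cv1)$mean_auc, mean(cv1$auc))
  expect_error(cross_validate(ch, "z:FA:all", k = 50, grid = g), "at least k")
})

test_that("a pure-noise feature barely moves the regularised classifier", {
  cfg <- cohort_config(n_controls = 100, n_patients = 100, seed = 71,
                       noise_sd = c(FAt = 0.02))
  ch <- simulate_cohort(cfg)
  z <- compute_zscores(ch, "FAt", grid = tiny_grid())$zscores
  X <- build_feature_set(ch, "z:FAt:all", zscores = list(FAt = z))
  y <- ch$subjects$group
  folds <- make_folds(100, 100, k = 5, seed = 1)
  ids <- c(sort(ch$subjects$id[y == "control"]), sort(ch$subjects$id[y == "patient"]))
  fold_of <- stats::setNames(folds$fold, ids)
  run_cv <- function(Xmat) {
    mean(vapply(1:5, function(f) {
      te <- names(fold_of)[fold_of == f]; tr <- setdiff(rownames(Xmat), te)
      fit <- fit_l2_logistic(Xmat[tr, , drop = FALSE],
                             ch$subjects$group[match(tr, ch$subjects$id)])
      auc(predict(fit, Xmat[te, , drop = FALSE]),
          ch$subjects$group[match(te, ch$subjects$id)])
    }, numeric(1)))
  }
  base_auc <- run_cv(X)
  Xn <- cbind(X, noise = withr::with_seed(5, rnorm(nrow(X))))
  expect_lt(abs(run_cv(Xn) - base_auc), 0.03)
})

test_that("distributed effects surface in skeleton coefficients and sex strata", {
  # skeleton-wide design: most tracts affected in every patient, uniformly,
  # so the aggregated skeleton average carries the strongest signal
  ch <- simulate_cohort(cohort_config(n_controls = 150, n_patients = 150,
                                      seed = 81,
                                      affected_roi_counts = 10:17,
                                      affect_weights = rep(1, 17),
                                      noise_sd = c(FAt = 0.02, FW = 0.015)))
  g <- tiny_grid()
  cv <- cross_validate(ch, "z:FAt+FW:all", k = 5, seed = 2, grid = g)
  co <- cv_coefficients(cv) |>
    dplyr::group_by(term) |>
    dplyr::summarise(m = mean(abs(estimate))) |>
    dplyr::arrange(dplyr::desc(m))
  expect_true(any(grepl("WM_skeleton", co$term[1:5])))

  # sex-specific FW effect: females should be easier to classify
  cfg0 <- null_config(120, 120, seed = 83, noise_sd = c(FW = 0.015))
  ch0 <- simulate_cohort(cfg0)
  fem_pat <- ch0$subjects$sex == "F" & ch0$subjects$group == "patient"
  ch0$measures$FW[fem_pat, 2:19] <- ch0$measures$FW[fem_pat, 2:19] + 0.012
  sx <- sex_stratified_cv(ch0, "z:FW:all", k = 4, seed = 2, grid = g)
  gl <- glance(sx)
  expect_gt(gl$mean_auc[gl$sex == "F"], gl$mean_auc[gl$sex == "M"])
  # fold counts per sex follow the balanced contract on the restricted sizes
  for (s in c("M", "F")) {
    nsub <- table(ch0$subjects$group[ch0$subjects$sex == s])
    fs <- fold_sizes(make_folds(nsub[["control"]], nsub[["patient"]],
                                k = 4, seed = 2))
    expect_equal(sum(fs$n_controls), nsub[["control"]])
    expect_true(max(fs$n_controls) - min(fs$n_controls) <= 1)
  }
})
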