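resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Balanced stratified fold assignment
#'
#' Partitions each group into `k` folds of near-equal size: every fold gets
#' `floor(n/k)` subjects of a group and the `n %% k` remainder subjects are
#' spread one per fold, with the remainder folds of the two groups kept
#' disjoint whenever `k` allows. With 512 controls and 601 patients in 10
#' folds this reproduces the design of seven (51, 60) folds, two (52, 60)
#' folds and one (51, 61) fold. Which subjects land in which fold is
#' randomised by `seed`.
#'
#' @param n_controls,n_patients Group sizes.
#' @param k Number of folds (>= 2; each group must have >= k subjects).
#' @param seed Optional integer seed for the assignment.
#' @return Tibble of class `nd_folds`: `group` (`"control"`/`"patient"`),
#'   `index` (within-group subject index), `fold` (1..k).
#' @examples
#' folds <- make_folds(512, 601, k = 10, seed = 1)
#' fold_sizes(folds)
#' @export
make_folds <- function(n_controls, n_patients, k = 10, seed = NULL) {
  if (k < 2) abort("`k` must be >= 2")
  if (n_controls < k || n_patients < k) {
    abort(sprintf("each group needs at least k = %d subjects (got %d controls, %d patients)",
                  k, n_controls, n_patients))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  rem_c <- n_controls %% k
  rem_p <- n_patients %% k
  if (rem_c + rem_p <= k) {
    sel <- resample(seq_len(k), rem_c + rem_p)
    extra_c <- sel[seq_len(rem_c)]
    extra_p <- sel[rem_c + seq_len(rem_p)]
  } else {
    extra_c <- resample(seq_len(k), rem_c)
    pool <- c(resample(setdiff(seq_len(k), extra_c)), resample(extra_c))
    extra_p <- pool[seq_len(rem_p)]
  }
  assign_one <- function(n, extras, group) {
    sizes <- rep(n %/% k, k)
    sizes[extras] <- sizes[extras] + 1L
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), sizes)
    tibble::tibble(group = group, index = seq_len(n), fold = fold)
  }
  out <- dplyr::bind_rows(assign_one(n_controls, extra_c, "control"),
                          assign_one(n_patients, extra_p, "patient"))
  attr(out, "k") <- k
  class(out) <- c("nd_folds", class(out))
  out
}

#' Fold composition of a fold assignment
#'
#' @param folds An `nd_folds` table from [make_folds()].
#' @return Tibble `fold`, `n_controls`, `n_patients`.
#' @export
fold_sizes <- function(folds) {
  folds |>
    dplyr::count(.data$fold, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename(n_controls = "control", n_patients = "patient") |>
    dplyr::arrange(.data$fold)
}

# ---- feature sets -----------------------------------------------------------

SUMMARY_MEASURE_NAMES <- c("load", "severity", "mean_z", "sd_z", "frac_sig_range")

parse_feature_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    abort(sprintf("feature spec `%s` must have the form kind:modalities:rois[+summaries]", spec))
  }
  kind <- parts[1]
  if (!kind %in% c("raw", "z")) {
    abort(sprintf("feature spec `%s`: kind must be `raw` or `z`", spec))
  }
  modalities <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
  bad <- setdiff(modalities, MODALITIES)
  if (length(bad)) abort(sprintf("feature spec `%s`: unknown modality `%s`", spec, bad[1]))
  roi_part <- strsplit(parts[3], "+", fixed = TRUE)[[1]]
  with_summaries <- "summaries" %in% roi_part
  rois <- setdiff(roi_part, "summaries")
  if (with_summaries && kind != "z") {
    abort(sprintf("feature spec `%s`: summaries are only defined for z features", spec))
  }
  list(name = spec, kind = kind, modalities = modalities,
       rois = rois, with_summaries = with_summaries)
}

# values_by_mod / summaries_by_mod: named lists of tibbles (id + columns)
assemble_features <- function(parsed, ids, values_by_mod,
                              summaries_by_mod = NULL, roi_names) {
  rois <- if (identical(parsed$rois, "all")) roi_names else parsed$rois
  bad <- setdiff(rois, roi_names)
  if (length(bad)) abort(sprintf("feature spec `%s`: unknown ROI `%s`", parsed$name, bad[1]))
  blocks <- purrr::map(parsed$modalities, function(m) {
    tab <- values_by_mod[[m]]
    if (is.null(tab)) abort(sprintf("feature spec `%s`: no %s values supplied", parsed$name, m))
    idx <- match(ids, tab$id)
    if (anyNA(idx)) abort(sprintf("feature spec `%s`: subject ids are not aligned with the %s table", parsed$name, m))
    block <- as.matrix(tab[idx, rois, drop = FALSE])
    colnames(block) <- paste(m, rois, sep = "_")
    block
  })
  if (parsed$with_summaries) {
    sblocks <- purrr::map(parsed$modalities, function(m) {
      stab <- summaries_by_mod[[m]]
      if (is.null(stab)) abort(sprintf("feature spec `%s`: no %s summary measures supplied", parsed$name, m))
      idx <- match(ids, stab$id)
      if (anyNA(idx)) abort(sprintf("feature spec `%s`: subject ids are not aligned with the %s summaries", parsed$name, m))
      cols <- intersect(SUMMARY_MEASURE_NAMES, names(stab))
      block <- as.matrix(stab[idx, cols, drop = FALSE])
      block[is.na(block)] <- 0  # empty significant range contributes no signal
      colnames(block) <- paste(m, cols, sep = "_")
      block
    })
    blocks <- c(blocks, sblocks)
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- ids
  X
}

#' Build a named feature set
#'
#' Feature specs use the grammar `kind:modalities:rois[+summaries]`, e.g.
#' `"raw:FA:all"` (18 raw FA values), `"z:FA:Fmajor"` (one z-score),
#' `"z:FAt+FW:all"` (36 z-scores, FAt block first), or
#' `"z:FA:all+summaries"` (18 z-scores + 5 summary measures). Column order
#' is deterministic: modalities in the order listed, ROIs in canonical
#' cohort order, summary measures appended last.
#'
#' @param cohort An `nd_cohort` (defines subjects and, for `raw`, values).
#' @param spec Feature spec string.
#' @param zscores Named list (per modality) of `nd_zscores` covering all
#'   subjects; required for `z` specs.
#' @param summaries Named list (per modality) of [summary_measures()] tables;
#'   required for `+summaries` specs.
#' @return Numeric matrix, subjects x features, rownames = subject ids, with
#'   attributes `name` and `provenance`.
#' @export
build_feature_set <- function(cohort, spec, zscores = NULL, summaries = NULL) {
  parsed <- parse_feature_spec(spec)
  values <- if (parsed$kind == "raw") cohort$measures else zscores
  if (is.null(values)) abort(sprintf("feature spec `%s` needs z-score tables", spec))
  X <- assemble_features(parsed, cohort$subjects$id, values, summaries,
                         cohort$roi_names)
  attr(X, "name") <- spec
  attr(X, "provenance") <- if (parsed$with_summaries) "combined" else parsed$kind
  X
}

# ---- ridge logistic regression ---------------------------------------------

#' L2-penalised logistic regression
#'
#' Minimises `-(1/n) * loglik + (lambda/2) * ||beta||^2` by Newton
#' iterations, with the intercept unpenalised and features standardised to
#' zero mean / unit SD using the training statistics (constant columns are
#' left centred with scale 1). Deterministic given its inputs.
#'
#' @param X Numeric matrix, observations x features.
#' @param y Class labels: logical, 0/1, or `"control"`/`"patient"` (patient
#'   is the positive class).
#' @param lambda Ridge penalty (>= 0) on the standardised scale.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `nd_ridgelogit`: `intercept`, `coefficients`
#'   (standardised scale, named), `center`, `scale`, `lambda`, `iterations`.
#' @export
fit_l2_logistic <- function(X, y, lambda = 1, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as_binary_label(y)
  if (length(unique(y)) < 2) abort("both classes must be present in `y`")
  stopifnot(lambda >= 0, nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Xa <- cbind(`(Intercept)` = 1, Xs)
  pen <- c(0, rep(lambda, p))
  theta <- numeric(p + 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% theta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(Xa, mu - y)) / n + pen * theta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xa * w, Xa) / n + diag(pen, p + 1)
    step <- solve(H, g)
    theta <- theta - step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf("ridge logistic fit did not converge in %d iterations (last step %.3g, lambda = %g, p = %d)",
                  max_iter, max(abs(step)), lambda, p))
  }
  structure(
    list(intercept = unname(theta[1]),
         coefficients = stats::setNames(theta[-1], colnames(X)),
         center = ctr, scale = scl, lambda = lambda, iterations = it),
    class = "nd_ridgelogit"
  )
}

as_binary_label <- function(y) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("control", "patient"))) {
      abort("character labels must be \"control\"/\"patient\"")
    }
    return(as.numeric(y == "patient"))
  }
  if (!all(y %in% c(0, 1))) abort("numeric labels must be 0/1")
  as.numeric(y)
}

#' Predict from a ridge logistic fit
#'
#' @param object An `nd_ridgelogit`.
#' @param newdata Feature matrix with the training columns.
#' @param type `"response"` (probability of the patient class) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.nd_ridgelogit <- function(object, newdata, type = c("response", "link"),
                                  ...) {
  type <- match.arg(type)
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L, object$scale, "/")
  eta <- object$intercept + drop(Xs %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a randomly chosen
#' patient scores above a randomly chosen control, ties counted one half.
#'
#' @param scores Numeric classifier scores (higher = more patient-like).
#' @param labels Class labels as in [fit_l2_logistic()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary_label(labels) == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- cross-validation -------------------------------------------------------

# per-fold normative machinery: z tables for train and test subjects and,
# when needed, summary-measure tables with the significant range estimated
# on training data only.
fold_feature_tables <- function(cohort, train_ids, test_ids, modalities,
                                need_summaries, grid, threshold, alpha) {
  train_cohort <- filter_cohort(cohort, train_ids)
  sexes <- unique(train_cohort$subjects$sex)
  test_subj <- cohort$subjects[match(test_ids, cohort$subjects$id), ]
  z_by_mod <- list(); s_by_mod <- list()
  for (m in modalities) {
    curves <- fit_normative(train_cohort, modalities = m, sexes = sexes,
                            grid = grid)
    ztr <- compute_zscores(train_cohort, m, grid = grid, curves = curves)$zscores
    # test subjects (both groups) scored directly against training-control curves
    vals <- measure_matrix(cohort, m)[test_ids, , drop = FALSE]
    Zte <- matrix(NA_real_, length(test_ids), ncol(vals),
                  dimnames = list(test_ids, colnames(vals)))
    for (s in unique(test_subj$sex)) {
      rows <- which(test_subj$sex == s)
      ages <- test_subj$age[rows]
      for (r in colnames(vals)) {
        cur <- get_curve(curves, r, m, s)
        Zte[rows, r] <- pmin(pmax(
          (vals[rows, r] - nw_mean(ages, cur)) / nw_sd(ages, cur), -10), 10)
      }
    }
    zte <- new_zscore_matrix(test_ids, Zte, m)
    z_by_mod[[m]] <- dplyr::bind_rows(ztr, zte)
    if (need_summaries) {
      grp_tr <- train_cohort$subjects$group
      sr <- significant_range(
        z_densities(ztr[grp_tr == "control", ]),
        z_densities(ztr[grp_tr == "patient", ]),
        alpha = alpha
      )
      s_by_mod[[m]] <- dplyr::bind_rows(
        summary_measures(ztr, threshold, sig_range = sr),
        summary_measures(zte, threshold, sig_range = sr)
      )
    }
  }
  list(z = z_by_mod, summaries = s_by_mod)
}

#' Cross-validated classification from normative-model features
#'
#' Evaluates one or more feature sets with k-fold cross-validation. In every
#' round the normative curves (including the bandwidth choice) are re-fitted
#' on the training controls only; training controls are scored leave-one-out
#' within the training set, training patients and all test subjects are
#' scored against the training-control curves; when a feature set includes
#' the summary measures, the significant z-range is estimated on the training
#' fold only. Features are standardised with training statistics inside the
#' ridge fit. The reported `mean_auc` is the unweighted mean over folds.
#'
#' @param cohort An `nd_cohort`.
#' @param specs Character vector of feature specs, see [build_feature_set()].
#' @param k Number of folds.
#' @param lambda Ridge penalty.
#' @param seed Integer seed for the fold assignment.
#' @param grid Bandwidth search grid for the per-fold normative fits.
#' @param threshold Abnormality threshold for the summary measures.
#' @param alpha Per-bin level for the significant-range estimation.
#' @param refit_per_fold If `FALSE`, the normative model is fitted once on
#'   all controls and shared across folds (leaks the test controls into the
#'   reference set; available to quantify that bias, not for reporting).
#' @return An object of class `nd_cv`: tibble with columns `feature_set`,
#'   `fold`, `auc`, `n_train`, `n_test`; attributes `coefficients` (tibble
#'   `feature_set`, `fold`, `term`, `estimate`), `k`, `lambda`, `seed`.
#'   `glance()` gives one row per feature set with `mean_auc`.
#' @export
cross_validate <- function(cohort, specs, k = 10, lambda = 1, seed = 1,
                           grid = bandwidth_grid(),
                           threshold = bonferroni_z_threshold(),
                           alpha = 0.05, refit_per_fold = TRUE) {
  parsed <- purrr::map(specs, parse_feature_spec)
  z_mods <- unique(unlist(purrr::map(
    purrr::keep(parsed, ~ .x$kind == "z"), "modalities")))
  need_summaries <- any(purrr::map_lgl(parsed, "with_summaries"))

  subj <- cohort$subjects
  ctrl_ids <- sort(subj$id[subj$group == "control"])
  pat_ids <- sort(subj$id[subj$group == "patient"])
  folds <- make_folds(length(ctrl_ids), length(pat_ids), k = k, seed = seed)
  fold_of <- stats::setNames(folds$fold, c(ctrl_ids, pat_ids)[
    ifelse(folds$group == "control", 0L, length(ctrl_ids)) + folds$index])

  results <- list(); coefs <- list()
  for (f in seq_len(k)) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- names(fold_of)[fold_of != f]
    tr_grp <- subj$group[match(train_ids, subj$id)]
    te_grp <- subj$group[match(test_ids, subj$id)]
    if (length(unique(te_grp)) < 2 || length(unique(tr_grp)) < 2) {
      abort(sprintf("fold %d is missing a class", f))
    }
    tables <- if (length(z_mods)) {
      if (refit_per_fold) {
        fold_feature_tables(cohort, train_ids, test_ids, z_mods,
                            need_summaries, grid, threshold, alpha)
      } else {
        full <- full_feature_tables(cohort, z_mods, need_summaries, grid,
                                    threshold, alpha)
        full
      }
    } else {
      list(z = NULL, summaries = NULL)
    }
    for (pp in parsed) {
      values <- if (pp$kind == "raw") cohort$measures else tables$z
      Xtr <- assemble_features(pp, train_ids, values, tables$summaries,
                               cohort$roi_names)
      Xte <- assemble_features(pp, test_ids, values, tables$summaries,
                               cohort$roi_names)
      fit <- fit_l2_logistic(Xtr, tr_grp, lambda = lambda)
      scores <- predict(fit, Xte)
      results[[length(results) + 1L]] <- tibble::tibble(
        feature_set = pp$name, fold = f, auc = auc(scores, te_grp),
        n_train = length(train_ids), n_test = length(test_ids)
      )
      coefs[[length(coefs) + 1L]] <- tibble::tibble(
        feature_set = pp$name, fold = f,
        term = names(fit$coefficients), estimate = unname(fit$coefficients)
      )
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "coefficients") <- dplyr::bind_rows(coefs)
  attr(out, "k") <- k
  attr(out, "lambda") <- lambda
  attr(out, "seed") <- seed
  class(out) <- c("nd_cv", class(out))
  out
}

# shared (leaky) variant used only to quantify the value of per-fold refits
full_feature_tables <- function(cohort, modalities, need_summaries, grid,
                                threshold, alpha) {
  z_by_mod <- list(); s_by_mod <- list()
  grp <- cohort$subjects$group
  for (m in modalities) {
    z <- compute_zscores(cohort, m, grid = grid)$zscores
    z_by_mod[[m]] <- z
    if (need_summaries) {
      sr <- significant_range(z_densities(z[grp == "control", ]),
                              z_densities(z[grp == "patient", ]),
                              alpha = alpha)
      s_by_mod[[m]] <- summary_measures(z, threshold, sig_range = sr)
    }
  }
  list(z = z_by_mod, summaries = s_by_mod)
}

#' Fold-level coefficients of a cross-validation run
#'
#' @param cv An `nd_cv` object.
#' @return Tibble `feature_set`, `fold`, `term`, `estimate`.
#' @export
cv_coefficients <- function(cv) attr(cv, "coefficients")

#' Sex-stratified cross-validation
#'
#' Runs the full [cross_validate()] procedure (fold design, per-fold
#' normative refitting, bandwidth choice) separately within each sex.
#'
#' @inheritParams cross_validate
#' @param sexes Sexes to analyse.
#' @return An `nd_cv` tibble with an extra `sex` column; per-sex coefficient
#'   tables are concatenated in the `coefficients` attribute.
#' @export
sex_stratified_cv <- function(cohort, specs, k = 10, lambda = 1, seed = 1,
                              grid = bandwidth_grid(),
                              threshold = bonferroni_z_threshold(),
                              alpha = 0.05, sexes = c("M", "F")) {
  pieces <- purrr::map(sexes, function(s) {
    ids <- cohort$subjects$id[cohort$subjects$sex == s]
    sub <- filter_cohort(cohort, ids)
    if (length(unique(sub$subjects$group)) < 2) {
      abort(sprintf("sex stratum %s lacks one of the groups", s))
    }
    cv <- cross_validate(sub, specs, k = k, lambda = lambda, seed = seed,
                         grid = grid, threshold = threshold, alpha = alpha)
    co <- cv_coefficients(cv)
    co$sex <- s
    cv$sex <- s
    list(cv = cv, co = co)
  })
  out <- dplyr::bind_rows(purrr::map(pieces, "cv"))
  attr(out, "coefficients") <- dplyr::bind_rows(purrr::map(pieces, "co"))
  attr(out, "k") <- k
  attr(out, "lambda") <- lambda
  attr(out, "seed") <- seed
  class(out) <- c("nd_cv", class(out))
  out
}
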