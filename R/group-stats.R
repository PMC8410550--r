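test_result <- function(method, statistic, p_value, effect_size = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        direction = NA_character_, df = NA_real_) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 ci_low = ci_low, ci_high = ci_high, direction = direction)
}

#' One-tailed Welch's t test
#'
#' Welch's unequal-variance t test with Satterthwaite degrees of freedom;
#' `direction = "less"` tests whether `a` has the smaller mean, `"greater"`
#' the larger. Cohen's d (with CI) is attached as the effect size. When both
#' samples have zero variance, the convention is `p = 1` for equal means
#' (no evidence) and `p = 0`/`1` by direction otherwise; a message is
#' emitted.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param direction `"less"` or `"greater"` (tail for `a` relative to `b`).
#' @param effect Attach Cohen's d and its CI (default `TRUE`).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `effect_size`, `ci_low`, `ci_high`, `direction`.
#' @export
welch_t <- function(a, b, direction = c("less", "greater"), effect = TRUE) {
  direction <- match.arg(direction)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    inform("Welch t: zero variance in both samples; using degenerate p convention")
    ma <- mean(a); mb <- mean(b)
    p <- if (ma == mb) 1 else if ((direction == "less") == (ma < mb)) 0 else 1
    return(test_result("welch_t", statistic = 0, p_value = p,
                       direction = direction))
  }
  ht <- t.test(a, b, alternative = direction, var.equal = FALSE)
  res <- test_result("welch_t", statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p_value = ht$p.value,
                     direction = direction)
  if (effect) {
    d <- cohens_d(a, b)
    res$effect_size <- d$estimate
    res$ci_low <- d$ci_low
    res$ci_high <- d$ci_high
  }
  res
}

#' One-tailed two-sample Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration when the combined sample size is
#' at most 20 and there are no ties, otherwise the normal approximation with
#' continuity correction. Cliff's delta (with CI) is attached as the effect
#' size.
#'
#' @param a,b Numeric samples (each n >= 1).
#' @param direction `"less"` or `"greater"` (tail for `a` relative to `b`).
#' @param effect Attach Cliff's delta and its CI (default `TRUE`).
#' @return One-row tibble as in [welch_t()]; `statistic` is the
#'   Mann-Whitney U of `a` over `b`.
#' @export
wilcoxon_ranksum <- function(a, b, direction = c("less", "greater"),
                             effect = TRUE) {
  direction <- match.arg(direction)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = direction, exact = exact, correct = TRUE)
  )
  res <- test_result("wilcoxon_ranksum", statistic = unname(ht$statistic),
                     p_value = ht$p.value, direction = direction)
  if (effect) {
    d <- cliffs_delta(a, b)
    res$effect_size <- d$estimate
    res$ci_low <- d$ci_low
    res$ci_high <- d$ci_high
  }
  res
}

#' Cohen's d with large-sample confidence interval
#'
#' Classical Cohen's d: mean difference over the pooled SD (Bessel-corrected,
#' n - 1 weights), without small-sample (Hedges) correction. The CI uses the
#' standard asymptotic variance
#' \eqn{d^2 / (2(n_1 + n_2)) + (n_1 + n_2)/(n_1 n_2)}.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param conf.level Confidence level for the interval.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
cohens_d <- function(a, b, conf.level = 0.95) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) abort("Cohen's d undefined: pooled SD is zero")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  se <- sqrt(d^2 / (2 * (n1 + n2)) + (n1 + n2) / (n1 * n2))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(estimate = d, ci_low = d - zq * se, ci_high = d + zq * se,
                 n1 = n1, n2 = n2)
}

#' Cliff's delta with Feng & Cliff confidence interval
#'
#' The dominance effect size
#' \eqn{\delta = [\#(a_i > b_j) - \#(a_i < b_j)] / (n_1 n_2) \in [-1, 1]},
#' the difference between the probability that a value from `a` exceeds one
#' from `b` and the probability of the reverse. The CI uses the consistent
#' variance estimate of the within-row and within-column dominance means with
#' the asymmetric bounded transformation, so the interval respects
#' \[-1, 1\].
#'
#' @param a,b Numeric samples (each n >= 1).
#' @param conf.level Confidence level.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
cliffs_delta <- function(a, b, conf.level = 0.95) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  dmat <- sign(outer(a, b, "-"))
  delta <- mean(dmat)
  di <- rowMeans(dmat)
  dj <- colMeans(dmat)
  if (n1 > 1 && n2 > 1) {
    sd2 <- (n2^2 * sum((di - delta)^2) + n1^2 * sum((dj - delta)^2) -
              sum((dmat - delta)^2)) / (n1 * n2 * (n1 - 1) * (n2 - 1))
    sd2 <- max(sd2, 0)
  } else {
    sd2 <- NA_real_
  }
  zq <- qnorm(1 - (1 - conf.level) / 2)
  if (!is.na(sd2) && abs(delta) < 1 && sd2 > 0) {
    denom <- 1 - delta^2 + zq^2 * sd2
    half <- zq * sqrt(sd2) * sqrt((1 - delta^2)^2 + zq^2 * sd2)
    lo <- (delta - delta^3 - half) / denom
    hi <- (delta - delta^3 + half) / denom
  } else {
    lo <- hi <- delta
  }
  tibble::tibble(estimate = delta, ci_low = lo, ci_high = hi, n1 = n1, n2 = n2)
}

#' Paired comparison of two effect-size profiles
#'
#' One-sided paired t test across ROIs that the first profile (typically
#' effect sizes from z-scores) exceeds the second (raw values), plus the
#' paired Cohen's d (mean difference / SD of differences).
#'
#' @param es_z,es_raw Equal-length numeric vectors of per-ROI effect sizes.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `effect_size` (paired d), `ci_low`, `ci_high`, `direction`.
#' @export
compare_effectsize_paired <- function(es_z, es_raw) {
  stopifnot(length(es_z) == length(es_raw), length(es_z) >= 2)
  diffs <- es_z - es_raw
  if (sd(diffs) <= 1e-10 * max(1, max(abs(diffs)))) {
    abort("paired effect-size comparison undefined: zero variance of differences")
  }
  ht <- t.test(diffs, alternative = "greater")
  test_result("paired_t", statistic = unname(ht$statistic),
              df = unname(ht$parameter), p_value = ht$p.value,
              effect_size = mean(diffs) / sd(diffs), direction = "greater")
}

#' One-tailed test direction per modality
#'
#' The patient group is expected to show lower FA and FAt but higher FW.
#'
#' @param modality `"FA"`, `"FAt"` or `"FW"`.
#' @return `"less"` or `"greater"` (tail of the patient group).
#' @export
modality_direction <- function(modality) {
  if (!modality %in% names(MODALITY_DIRECTION)) {
    abort(sprintf("unknown modality `%s`", modality))
  }
  unname(MODALITY_DIRECTION[[modality]])
}

#' Per-ROI group comparison
#'
#' One-tailed Welch test and Cohen's d per ROI, patients versus controls, in
#' the modality's fixed direction (lower FA/FAt, higher FW in patients).
#' Works on raw measure values or on a z-score table.
#'
#' @param cohort An `nd_cohort` (supplies group membership).
#' @param modality Modality to test.
#' @param value_kind `"raw"` (cohort measures) or `"z"` (supply `zscores`).
#' @param zscores An `nd_zscores` covering all subjects (required for
#'   `value_kind = "z"`).
#' @return Tibble of class `nd_roi_tests`, one row per ROI: `roi`, `modality`,
#'   `value_kind`, `statistic`, `df`, `p_value`, `effect_size`, `ci_low`,
#'   `ci_high`, `direction`, `significance` (star convention: `***` p < .001,
#'   `**` p < .01, `*` p < .05).
#' @export
roi_group_comparison <- function(cohort, modality, value_kind = c("raw", "z"),
                                 zscores = NULL) {
  value_kind <- match.arg(value_kind)
  grp <- cohort$subjects$group
  if (!all(c("control", "patient") %in% grp)) {
    abort("both groups must be present for a group comparison")
  }
  M <- if (value_kind == "raw") {
    measure_matrix(cohort, modality)
  } else {
    if (is.null(zscores)) abort("`zscores` must be supplied for value_kind = \"z\"")
    zscore_matrix(zscores)[cohort$subjects$id, , drop = FALSE]
  }
  dir_pat <- modality_direction(modality)
  pat <- grp == "patient"
  out <- purrr::map_dfr(colnames(M), function(r) {
    res <- welch_t(M[pat, r], M[!pat, r], direction = dir_pat)
    res$roi <- r
    res
  })
  out <- dplyr::mutate(
    out,
    modality = modality, value_kind = value_kind,
    significance = dplyr::case_when(
      .data$p_value < 0.001 ~ "***",
      .data$p_value < 0.01 ~ "**",
      .data$p_value < 0.05 ~ "*",
      TRUE ~ ""
    )
  ) |>
    dplyr::select("roi", "modality", "value_kind", "statistic", "df",
                  "p_value", "effect_size", "ci_low", "ci_high", "direction",
                  "significance")
  class(out) <- c("nd_roi_tests", class(out))
  out
}

#' Group comparison of the per-subject summary measures
#'
#' One-tailed Wilcoxon rank-sum test with Cliff's delta per summary measure.
#' The tail directions follow the expected patient-group behaviour under the
#' modality's effect direction: more load, more extreme severity, shifted
#' mean z (toward the modality direction), larger spread, and more ROIs in
#' the significant range. Each measure's tail is controlled by the
#' `directions` argument; the defaults are package choices, not fixed by the
#' method.
#'
#' @param summaries_controls,summaries_patients Tibbles from
#'   [summary_measures()].
#' @param modality Modality the z-scores came from (sets the `mean_z` and
#'   `severity` tails).
#' @param directions Optional named character vector overriding the tail
#'   (`"less"`/`"greater"`, patient side) per measure.
#' @return Tibble, one row per measure, same columns as [wilcoxon_ranksum()]
#'   plus `measure`.
#' @export
summary_group_comparison <- function(summaries_controls, summaries_patients,
                                     modality = "FA", directions = NULL) {
  mdir <- modality_direction(modality)
  defaults <- c(load = "greater",
                severity = mdir,
                mean_z = mdir,
                sd_z = "greater",
                frac_sig_range = "greater")
  if (!is.null(directions)) defaults[names(directions)] <- directions
  measures <- intersect(names(defaults), names(summaries_controls))
  purrr::map_dfr(measures, function(mm) {
    a <- summaries_patients[[mm]]
    b <- summaries_controls[[mm]]
    if (all(is.na(a)) || all(is.na(b))) return(NULL)
    res <- wilcoxon_ranksum(a[!is.na(a)], b[!is.na(b)],
                            direction = defaults[[mm]])
    res$measure <- mm
    dplyr::select(res, "measure", dplyr::everything())
  })
}
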