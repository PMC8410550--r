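#' Tidy a fitted normative curve set
#'
#' @param x An `nd_normative` from [fit_normative()].
#' @param ... Unused.
#' @return Tibble `roi`, `modality`, `sex`, `n`, `bandwidth` (the
#'   supplementary-table layout of chosen bandwidths).
#' @export
tidy.nd_normative <- function(x, ...) {
  tibble::as_tibble(x[, c("roi", "modality", "sex", "n", "bandwidth")])
}

#' Tidy a single normative curve (its reference points)
#'
#' @param x An `nd_curve`.
#' @param ... Unused.
#' @return Tibble `age`, `value` of the reference controls.
#' @export
tidy.nd_curve <- function(x, ...) {
  tibble::tibble(age = x$ages, value = x$values)
}

#' One-row summary of a normative curve
#'
#' @param x An `nd_curve`.
#' @param ... Unused.
#' @return Tibble `roi`, `modality`, `sex`, `n`, `bandwidth`.
#' @export
glance.nd_curve <- function(x, ...) {
  tibble::tibble(roi = x$roi, modality = x$modality, sex = x$sex,
                 n = length(x$ages), bandwidth = x$bandwidth)
}

#' Tidy a cross-validation result (per-fold AUCs)
#'
#' @param x An `nd_cv`.
#' @param ... Unused.
#' @return The per-fold tibble (`feature_set`, `fold`, `auc`, ...).
#' @export
tidy.nd_cv <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Per-feature-set summary of a cross-validation result
#'
#' @param x An `nd_cv`.
#' @param ... Unused.
#' @return Tibble with one row per feature set (and sex, if stratified):
#'   `mean_auc` (unweighted mean over folds), `sd_auc`, `n_folds`.
#' @export
glance.nd_cv <- function(x, ...) {
  by <- intersect(c("feature_set", "sex"), names(x))
  tibble::as_tibble(x) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
                     n_folds = dplyr::n(), .groups = "drop")
}

#' Tidy a ridge logistic fit
#'
#' @param x An `nd_ridgelogit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (standardised scale; intercept first).
#' @export
tidy.nd_ridgelogit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' Tidy a significant-range result (per-bin tests)
#'
#' @param x An `nd_sigrange`.
#' @param ... Unused.
#' @return Tibble `bin`, `p_value`, `significant`.
#' @export
tidy.nd_sigrange <- function(x, ...) {
  tibble::tibble(bin = x$bin_centers, p_value = x$p_values,
                 significant = x$significant)
}

#' One-row summary of a significant range
#'
#' @param x An `nd_sigrange`.
#' @param ... Unused.
#' @return Tibble `lower`, `upper`, `n_significant`, `alpha`.
#' @export
glance.nd_sigrange <- function(x, ...) {
  tibble::tibble(lower = x$lower, upper = x$upper,
                 n_significant = sum(x$significant), alpha = x$alpha)
}
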