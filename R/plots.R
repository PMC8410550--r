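#' Plot a normative curve with its reference controls
#'
#' Normative mean across age with a +/- `band` SD ribbon, over the reference
#' control points.
#'
#' @param object An `nd_curve`.
#' @param band Half-width of the ribbon in SD units.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nd_curve <- function(object, band = 2, ...) {
  fit <- predict(object)
  ggplot2::ggplot(fit, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - band * .data$sd,
                                      ymax = .data$mean + band * .data$sd),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::geom_point(data = tidy(object),
                        ggplot2::aes(x = .data$age, y = .data$value),
                        alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "age (years)", y = object$modality,
      title = sprintf("%s %s, sex %s (h = %.2g years)",
                      object$roi, object$modality, object$sex,
                      object$bandwidth)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold AUCs of a cross-validation result
#'
#' @param object An `nd_cv`.
#' @param ... Unused.
#' @return A ggplot: per-fold AUCs with the fold-mean marked per feature set.
#' @export
autoplot.nd_cv <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$feature_set, y = .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "AUC (per fold; diamond = mean)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
  if ("sex" %in% names(dat)) p <- p + ggplot2::facet_wrap(~sex)
  p
}

#' Plot per-ROI effect sizes of a group comparison
#'
#' Effect-size bars with 95% CI error bars and a significance star per ROI.
#'
#' @param object An `nd_roi_tests` from [roi_group_comparison()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nd_roi_tests <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$roi, y = .data$effect_size)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$significance), vjust = -0.4) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Cohen's d (%s, %s values)",
                              dat$modality[1], dat$value_kind[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a subject's regularised z-score density
#'
#' @param object An `nd_zdensity` from [z_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nd_zdensity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$density)) +
    ggplot2::geom_col(width = 0.38, fill = "steelblue", alpha = 0.8) +
    ggplot2::labs(x = "z-score", y = "density") +
    ggplot2::theme_minimal()
}
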