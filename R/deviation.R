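#' Bonferroni-corrected z threshold
#'
#' The two-sided standard-normal quantile at `1 - alpha / (2 * n_tests)`.
#' With 18 ROIs at alpha = 0.05 this is 2.9913: z-scores beyond +/- this
#' value are called supra-/infra-normal.
#'
#' @param n_tests Number of simultaneous tests (>= 1).
#' @param alpha Family-wise significance level in (0, 1).
#' @return The z threshold.
#' @examples
#' bonferroni_z_threshold(18, 0.05)
#' @export
bonferroni_z_threshold <- function(n_tests = 18, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1")
  }
  if (n_tests < 1) abort("`n_tests` must be >= 1")
  qnorm(1 - alpha / (2 * n_tests))
}

#' Count abnormal deviations per ROI
#'
#' Counts, per ROI, how many subjects have an infra-normal (`z < -threshold`)
#' or supra-normal (`z > threshold`) deviation, and how many subjects have at
#' least one abnormal ROI.
#'
#' @param zscores An `nd_zscores` table (or any tibble `id` + ROI columns).
#' @param threshold Positive z threshold, see [bonferroni_z_threshold()].
#' @param direction `"infra"` or `"supra"`.
#' @return Tibble with columns `roi`, `n_abnormal`, `frac_abnormal`, plus
#'   attributes `n_subjects_any` (subjects with >= 1 abnormal ROI) and
#'   `n_subjects`.
#' @export
count_abnormal_per_roi <- function(zscores, threshold,
                                   direction = c("infra", "supra")) {
  direction <- match.arg(direction)
  stopifnot(threshold > 0)
  Z <- zscore_matrix(zscores)
  hit <- if (direction == "infra") Z < -threshold else Z > threshold
  out <- tibble::tibble(
    roi = colnames(Z),
    n_abnormal = unname(colSums(hit)),
    frac_abnormal = unname(colSums(hit)) / nrow(Z)
  )
  attr(out, "n_subjects_any") <- sum(rowSums(hit) >= 1)
  attr(out, "n_subjects") <- nrow(Z)
  out
}

#' Per-subject deviation summary measures
#'
#' For each subject's vector of ROI z-scores:
#' \describe{
#'   \item{load}{fraction of ROIs with `|z| > threshold`}
#'   \item{severity}{the z-score with the largest absolute value (sign kept)}
#'   \item{mean_z, sd_z}{mean and SD of the z-scores}
#'   \item{frac_sig_range}{fraction of ROIs with z inside the discriminative
#'     significant range (`NA` if no range is supplied or the range is
#'     empty)}
#' }
#'
#' @param zscores An `nd_zscores` table.
#' @param threshold Abnormality threshold, see [bonferroni_z_threshold()].
#' @param sig_range Optional `nd_sigrange` from [significant_range()] (or a
#'   list with `lower`/`upper`).
#' @return Tibble: `id`, `load`, `severity`, `mean_z`, `sd_z`,
#'   `frac_sig_range`.
#' @export
summary_measures <- function(zscores, threshold = bonferroni_z_threshold(),
                             sig_range = NULL) {
  Z <- zscore_matrix(zscores)
  p <- ncol(Z)
  sev <- Z[cbind(seq_len(nrow(Z)), max.col(abs(Z), ties.method = "first"))]
  frac_sig <- rep(NA_real_, nrow(Z))
  if (!is.null(sig_range) && is.finite(sig_range$lower)) {
    frac_sig <- rowSums(Z > sig_range$lower & Z < sig_range$upper) / p
  }
  tibble::tibble(
    id = zscores$id,
    load = unname(rowSums(abs(Z) > threshold)) / p,
    severity = unname(sev),
    mean_z = unname(rowMeans(Z)),
    sd_z = unname(apply(Z, 1L, sd)),
    frac_sig_range = unname(frac_sig)
  )
}

#' Bin centers of the z-score density grid
#'
#' 50 equally spaced bins covering (-10, 10); bin width 0.4.
#'
#' @return Numeric vector of 50 bin centers.
#' @export
z_density_bins <- function() {
  width <- 20 / 50
  seq(-10 + width / 2, 10 - width / 2, by = width)
}

#' Regularised z-score density of one subject
#'
#' Gaussian-kernel density estimate built from a subject's ROI z-scores,
#' evaluated at the 50 bin centers of [z_density_bins()]. The default
#' bandwidth is Silverman's rule on the subject's z-scores, floored at one
#' bin width (0.4) — 18 points need strong regularisation.
#'
#' @param z Numeric vector of z-scores (one subject).
#' @param kde_bandwidth Kernel SD; `NULL` for the default rule.
#' @return Tibble of class `nd_zdensity` with columns `bin` and `density`.
#' @export
z_density <- function(z, kde_bandwidth = NULL) {
  z <- z[is.finite(z)]
  stopifnot(length(z) >= 1)
  bw <- kde_bandwidth %||% max(bw.nrd0(z), 0.4)
  stopifnot(bw > 0)
  centers <- z_density_bins()
  dens <- vapply(centers, function(cc) mean(dnorm((cc - z) / bw)) / bw,
                 numeric(1))
  out <- tibble::tibble(bin = centers, density = dens)
  class(out) <- c("nd_zdensity", class(out))
  attr(out, "bandwidth") <- bw
  out
}

# densities for all subjects: n x 50 matrix (rows = subjects)
z_density_rows <- function(Z, kde_bandwidth = NULL) {
  centers <- z_density_bins()
  t(apply(Z, 1L, function(z) {
    bw <- kde_bandwidth %||% max(bw.nrd0(z), 0.4)
    vapply(centers, function(cc) mean(dnorm((cc - z) / bw)) / bw, numeric(1))
  }))
}

#' Per-subject z-score densities for a whole group
#'
#' @param zscores An `nd_zscores` table.
#' @param kde_bandwidth Kernel SD; `NULL` for the per-subject default rule.
#' @return Tibble `id` + columns `bin_01`..`bin_50` of densities.
#' @export
z_densities <- function(zscores, kde_bandwidth = NULL) {
  D <- z_density_rows(zscore_matrix(zscores), kde_bandwidth)
  colnames(D) <- sprintf("bin_%02d", seq_len(ncol(D)))
  dplyr::bind_cols(tibble::tibble(id = zscores$id), tibble::as_tibble(D))
}

#' Discriminative range of z-scores
#'
#' Compares the per-subject z-score densities between patients and controls
#' bin by bin with a one-tailed Welch t test (alternative: higher density in
#' the patient group). Bins with `p < alpha` are significant; the returned
#' range is the longest contiguous run of significant bins, reported by its
#' outer bin edges. Bins with zero variance in both groups get `p = 1`.
#' Per-bin p-values are not multiplicity-corrected by default, mirroring a
#' per-bin alpha; pass `p_adjust_method` for an adjusted variant.
#'
#' @param densities_controls,densities_patients Density tables from
#'   [z_densities()] (or bare matrices, subjects x 50).
#' @param alpha Per-bin significance level.
#' @param p_adjust_method Optional method passed to [stats::p.adjust()]
#'   before thresholding (default `"none"`).
#' @return An object of class `nd_sigrange`: list with `lower`, `upper`
#'   (`NA` when no bin is significant), `p_values` (length 50),
#'   `significant` (logical, length 50), `alpha` and `bin_centers`.
#' @export
significant_range <- function(densities_controls, densities_patients,
                              alpha = 0.05, p_adjust_method = "none") {
  as_mat <- function(d) {
    if (is.data.frame(d)) as.matrix(d[, setdiff(names(d), "id"), drop = FALSE]) else d
  }
  Dc <- as_mat(densities_controls)
  Dp <- as_mat(densities_patients)
  stopifnot(ncol(Dc) == 50, ncol(Dp) == 50, nrow(Dc) >= 2, nrow(Dp) >= 2)
  pvals <- vapply(seq_len(50), function(b) {
    a <- Dp[, b]; bb <- Dc[, b]
    if (var(a) == 0 && var(bb) == 0) return(1)
    welch_t(a, bb, direction = "greater", effect = FALSE)$p_value
  }, numeric(1))
  padj <- stats::p.adjust(pvals, method = p_adjust_method)
  sig <- padj < alpha
  centers <- z_density_bins()
  width <- centers[2] - centers[1]
  lower <- upper <- NA_real_
  if (any(sig)) {
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    i <- which(runs$values)[which.max(runs$lengths[runs$values])]
    lower <- centers[starts[i]] - width / 2
    upper <- centers[ends[i]] + width / 2
  }
  structure(
    list(lower = lower, upper = upper, p_values = pvals, significant = sig,
         alpha = alpha, bin_centers = centers),
    class = "nd_sigrange"
  )
}

#' @export
print.nd_sigrange <- function(x, ...) {
  if (is.na(x$lower)) {
    cat("<nd_sigrange> no significant bins at alpha =", x$alpha, "\n")
  } else {
    cat(sprintf("<nd_sigrange> %.3g < z < %.3g (%d significant bins, alpha = %g)\n",
                x$lower, x$upper, sum(x$significant), x$alpha))
  }
  invisible(x)
}
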