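#' Fit one sex-stratified normative curve
#'
#' The curve's reference set is exactly the sex-matched controls of the
#' cohort for the given ROI and modality; the bandwidth minimises the
#' leave-one-out CV error over `grid`.
#'
#' @param cohort An `nd_cohort` (only its controls are used).
#' @param roi,modality,sex Stratum to fit.
#' @param grid Bandwidth search grid, see [bandwidth_grid()].
#' @param sd_floor Lower bound for evaluated SDs.
#' @return An `nd_curve`.
#' @export
fit_normative_curve <- function(cohort, roi, modality, sex,
                                grid = bandwidth_grid(), sd_floor = 1e-6) {
  ctrl <- cohort$subjects$group == "control" & cohort$subjects$sex == sex
  if (sum(ctrl) < 3) {
    abort(sprintf("cannot fit normative curve for %s/%s/sex %s: %d sex-matched controls (need >= 3)",
                  roi, modality, sex, sum(ctrl)))
  }
  vals <- measure_matrix(cohort, modality)
  if (!roi %in% colnames(vals)) abort(sprintf("unknown ROI `%s`", roi))
  ages <- cohort$subjects$age[ctrl]
  y <- vals[ctrl, roi]
  h <- select_bandwidth(ages, y, grid)
  normative_curve(ages, y, h, roi = roi, modality = modality, sex = sex,
                  sd_floor = sd_floor)
}

#' Fit the full set of normative curves for a cohort
#'
#' Fits one curve per (ROI, sex) stratum and modality from the cohort's
#' controls, with per-stratum bandwidth selection. Because all ROIs of a
#' stratum share the same reference ages, the CV search reuses the kernel
#' weights across ROIs.
#'
#' @inheritParams fit_normative_curve
#' @param modalities Modalities to fit (default: all present).
#' @param sexes Sex strata to fit (default both).
#' @return A tibble of class `nd_normative` with columns `roi`, `modality`,
#'   `sex`, `n`, `bandwidth` and a list-column `curve` of `nd_curve` objects.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_controls = 60, n_patients = 20,
#'                                         seed = 3, noise_sd = c(FA = 0.02)))
#' curves <- fit_normative(cohort, grid = bandwidth_grid(n = 10))
#' curves
#' @export
fit_normative <- function(cohort, modalities = names(cohort$measures),
                          sexes = c("M", "F"), grid = bandwidth_grid(),
                          sd_floor = 1e-6) {
  rows <- purrr::map_dfr(modalities, function(m) {
    vals <- measure_matrix(cohort, m)
    purrr::map_dfr(sexes, function(s) {
      ctrl <- cohort$subjects$group == "control" & cohort$subjects$sex == s
      if (sum(ctrl) < 3) {
        abort(sprintf("cannot fit normative curves for %s/sex %s: %d sex-matched controls (need >= 3)",
                      m, s, sum(ctrl)))
      }
      ages <- cohort$subjects$age[ctrl]
      Y <- vals[ctrl, , drop = FALSE]
      h <- select_bandwidth_matrix(ages, Y, grid)
      tibble::tibble(
        roi = colnames(Y), modality = m, sex = s, n = sum(ctrl),
        bandwidth = unname(h),
        curve = purrr::map2(colnames(Y), h, function(r, hh) {
          normative_curve(ages, Y[, r], hh, roi = r, modality = m, sex = s,
                          sd_floor = sd_floor)
        })
      )
    })
  })
  class(rows) <- c("nd_normative", class(rows))
  rows
}

get_curve <- function(curves, roi, modality, sex) {
  i <- which(curves$roi == roi & curves$modality == modality & curves$sex == sex)
  if (length(i) != 1) {
    abort(sprintf("no fitted normative curve for stratum %s/%s/sex %s",
                  roi, modality, sex))
  }
  curves$curve[[i]]
}

#' Deviation z-score of a single observation
#'
#' \eqn{z = (y - \hat m_h(x)) / \hat\sigma_h(x)}, truncated to \[-10, 10\].
#'
#' @param age Subject age in years.
#' @param sex Subject sex; must match the curve's stratum.
#' @param value Observed measure value.
#' @param curve The sex-matched `nd_curve`.
#' @return The truncated z-score.
#' @export
zscore <- function(age, sex, value, curve) {
  if (!is.na(curve$sex) && !identical(sex, curve$sex)) {
    abort(sprintf("subject sex `%s` does not match curve stratum `%s`", sex, curve$sex))
  }
  z <- (value - nw_mean(age, curve)) / nw_sd(age, curve)
  pmin(pmax(z, -10), 10)
}

new_zscore_matrix <- function(ids, Z, modality) {
  tab <- dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(Z))
  attr(tab, "modality") <- modality
  class(tab) <- c("nd_zscores", class(tab))
  tab
}

#' Z-scores of the patient group against fitted normative curves
#'
#' Each patient is scored per ROI against the sex-matched curve evaluated at
#' the patient's age.
#'
#' @param cohort An `nd_cohort`.
#' @param curves An `nd_normative` table from [fit_normative()].
#' @param modality Modality to score.
#' @return A tibble of class `nd_zscores`: `id` plus one column per ROI, all
#'   values truncated to \[-10, 10\].
#' @export
zscores_patients <- function(cohort, curves, modality) {
  pats <- cohort$subjects[cohort$subjects$group == "patient", ]
  vals <- measure_matrix(cohort, modality)[pats$id, , drop = FALSE]
  Z <- matrix(NA_real_, nrow(pats), ncol(vals),
              dimnames = list(pats$id, colnames(vals)))
  for (s in unique(pats$sex)) {
    rows <- which(pats$sex == s)
    ages <- pats$age[rows]
    for (r in colnames(vals)) {
      cur <- get_curve(curves, r, modality, s)
      m <- nw_mean(ages, cur)
      sdv <- nw_sd(ages, cur)
      Z[rows, r] <- pmin(pmax((vals[rows, r] - m) / sdv, -10), 10)
    }
  }
  new_zscore_matrix(pats$id, Z, modality)
}

#' Leave-one-out z-scores of the control group
#'
#' Each control is compared with a normative model composed of all other
#' sex-matched controls, excluding the one being evaluated. The bandwidth is
#' selected once per (ROI, sex) stratum on the full control stratum and
#' reused for every leave-one-out reference set (set
#' `reselect_bandwidth = TRUE` to re-select per left-out subject instead).
#'
#' @inheritParams zscores_patients
#' @param grid Bandwidth search grid.
#' @param curves Optional pre-fitted `nd_normative` table whose bandwidths
#'   are reused (must cover every stratum); if `NULL`, bandwidths are
#'   selected here.
#' @param reselect_bandwidth Re-select the bandwidth on each leave-one-out
#'   reference set (slower; default `FALSE`).
#' @param sd_floor Lower bound for evaluated SDs.
#' @return A tibble of class `nd_zscores` for the controls.
#' @export
zscores_controls_loo <- function(cohort, modality, grid = bandwidth_grid(),
                                 curves = NULL, reselect_bandwidth = FALSE,
                                 sd_floor = 1e-6) {
  ctrls <- cohort$subjects[cohort$subjects$group == "control", ]
  vals <- measure_matrix(cohort, modality)[ctrls$id, , drop = FALSE]
  Z <- matrix(NA_real_, nrow(ctrls), ncol(vals),
              dimnames = list(ctrls$id, colnames(vals)))
  for (s in unique(ctrls$sex)) {
    rows <- which(ctrls$sex == s)
    if (length(rows) < 4) {
      abort(sprintf("leave-one-out z-scores need >= 4 controls per sex stratum; sex %s has %d",
                    s, length(rows)))
    }
    ages <- ctrls$age[rows]
    Y <- vals[rows, , drop = FALSE]
    hs <- if (!is.null(curves)) {
      vapply(colnames(Y), function(r) get_curve(curves, r, modality, s)$bandwidth,
             numeric(1))
    } else {
      select_bandwidth_matrix(ages, Y, grid)
    }
    for (r in colnames(Y)) {
      y <- Y[, r]
      if (reselect_bandwidth) {
        z <- vapply(seq_along(rows), function(j) {
          h_j <- select_bandwidth(ages[-j], y[-j], grid)
          cur <- normative_curve(ages[-j], y[-j], h_j, sd_floor = sd_floor)
          (y[j] - nw_mean(ages[j], cur)) / nw_sd(ages[j], cur)
        }, numeric(1))
      } else {
        z <- loo_zscores_stratum(ages, y, hs[[r]], sd_floor)
      }
      Z[rows, r] <- pmin(pmax(z, -10), 10)
    }
  }
  new_zscore_matrix(ctrls$id, Z, modality)
}

# vectorised LOO z within one stratum at fixed bandwidth: the reference set
# for subject j is all other subjects; weights = kernel matrix with zeroed
# diagonal.
loo_zscores_stratum <- function(ages, y, h, sd_floor = 1e-6) {
  e <- -0.5 * (outer(ages, ages, "-") / h)^2
  diag(e) <- -Inf
  emax <- apply(e, 1L, max)
  if (any(emax <= log(.Machine$double.xmin) + 1)) {
    stop_extrapolation(ages[emax <= log(.Machine$double.xmin) + 1])
  }
  w <- exp(e - emax)
  denom <- rowSums(w)
  m <- drop(w %*% y) / denom
  v <- drop(w %*% y^2) / denom - m^2
  sdv <- pmax(sqrt(pmax(v, 0)), sd_floor)
  (y - m) / sdv
}

#' Z-scores for every subject of a cohort
#'
#' Patients are scored against curves fitted on all controls; controls are
#' scored leave-one-out. Convenience wrapper used by the pipeline.
#'
#' @inheritParams zscores_controls_loo
#' @param curves Optional pre-fitted `nd_normative` (fitted here if `NULL`).
#' @return A list with elements `zscores` (an `nd_zscores` covering all
#'   subjects, in cohort order) and `curves` (the fitted `nd_normative`).
#' @export
compute_zscores <- function(cohort, modality, grid = bandwidth_grid(),
                            curves = NULL) {
  if (is.null(curves)) {
    curves <- fit_normative(cohort, modalities = modality,
                            sexes = unique(cohort$subjects$sex), grid = grid)
  }
  zp <- zscores_patients(cohort, curves, modality)
  zc <- zscores_controls_loo(cohort, modality, grid = grid, curves = curves)
  all_z <- dplyr::bind_rows(zc, zp)
  all_z <- all_z[match(cohort$subjects$id, all_z$id), ]
  list(zscores = new_zscore_matrix(all_z$id,
                                   as.matrix(all_z[, -1, drop = FALSE]),
                                   modality),
       curves = curves)
}

# matrix view of an nd_zscores table
zscore_matrix <- function(z) {
  m <- as.matrix(z[, -1, drop = FALSE])
  rownames(m) <- z$id
  m
}
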