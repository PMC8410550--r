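#' Canonical ROI labels
#'
#' The analysis operates on 18 white-matter regions: 17 fiber tracts plus the
#' whole white-matter skeleton average. Only four region names are fixed by
#' convention (the forceps major and minor, the fornix, and the skeleton
#' average); the remaining tracts carry generic labels.
#'
#' @return Character vector of 18 ROI labels; the skeleton average is last.
#' @export
default_roi_names <- function() {
  c("Fmajor", "Fminor", "Fornix", sprintf("Tract%02d", 4:17), "WM_skeleton")
}

#' Default age-trajectory coefficients for the synthetic cohort
#'
#' Each tract's normative mean is `base + lin * (age - 30) + quad * (age - 30)^2`,
#' a quadratic with a peak near age 30 for FA/FAt and a monotone increase for
#' FW, matching the lifespan shapes these measures follow in healthy adults.
#' The skeleton average is derived from the tracts, so coefficients cover the
#' 17 tracts only.
#'
#' @param roi_names ROI labels as from [default_roi_names()].
#' @return Named list (`FA`, `FAt`, `FW`) of tibbles with columns
#'   `roi`, `base`, `lin`, `quad`.
#' @export
default_trajectories <- function(roi_names = default_roi_names()) {
  tracts <- utils::head(roi_names, -1L)
  r <- seq_along(tracts) - 1
  list(
    FA  = tibble::tibble(roi = tracts, base = 0.40 + 0.014 * r, lin = 0,     quad = -4e-5),
    FAt = tibble::tibble(roi = tracts, base = 0.45 + 0.014 * r, lin = 0,     quad = -4e-5),
    FW  = tibble::tibble(roi = tracts, base = 0.10 + 0.002 * r, lin = 8e-4,  quad = 0)
  )
}

#' Default additive sex offsets (applied to males) for the synthetic cohort
#'
#' @inheritParams default_trajectories
#' @return Named list of numeric vectors (one per tract) per modality.
#' @export
default_sex_offsets <- function(roi_names = default_roi_names()) {
  tracts <- utils::head(roi_names, -1L)
  r <- seq_along(tracts) - 1
  list(
    FA  = stats::setNames(0.004 + 4e-4 * r, tracts),
    FAt = stats::setNames(0.004 + 4e-4 * r, tracts),
    FW  = stats::setNames(-0.002 - 1e-4 * r, tracts)
  )
}

#' Configuration of a synthetic cohort
#'
#' Defines the generative model behind [simulate_cohort()]: group sizes, age
#' and sex marginals, smooth ROI-specific age trajectories with sex offsets,
#' residual noise, and subtle group effects placed in a per-patient random
#' subset of tracts (lower FA/FAt, higher FW). Defaults reproduce the study
#' conditions of the harmonized multi-site cohort the pipeline is designed
#' for: 512 controls (age 30.15 [14.26] years, 54.49% male) and 601 patients
#' (age 31.46 [12.31] years, 63.23% male).
#'
#' @param n_controls,n_patients Group sizes (positive integers).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param roi_names 18 ROI labels; the last is the derived skeleton average.
#' @param age_mean_sd_controls,age_mean_sd_patients Length-2 numeric,
#'   mean and SD of the (truncated) normal age distribution in years.
#' @param male_fraction_controls,male_fraction_patients Proportion of males.
#' @param trajectory_params Per-modality tibbles of tract trajectory
#'   coefficients; see [default_trajectories()].
#' @param sex_offset Per-modality additive shift applied to males per tract.
#' @param effect_size_range Per-modality length-2 numeric: the magnitude of
#'   the group effect in an affected tract, on a Cohen's-d scale relative to
#'   `noise_sd` (drawn uniformly from this range per patient and tract).
#'   Directions are fixed: FA and FAt decrease, FW increases in patients.
#' @param affected_roi_counts Integer vector from which each patient's number
#'   of affected tracts is drawn uniformly (default 1..6 of the 17 tracts).
#' @param affect_weights Relative probability of each tract being included in
#'   a patient's affected subset. The default decays geometrically across the
#'   tract list, making pathology spatially heterogeneous but concentrated in
#'   a few tracts (the forceps major leads), rather than exchangeable across
#'   the skeleton.
#' @param noise_sd Per-modality residual SD (modality units).
#' @param sd_slope Per-modality relative slope of the residual SD across age
#'   (0 = homoscedastic, the default): `sd(age) = noise_sd * (1 + sd_slope *
#'   (age - 30) / 40)`, floored at `0.2 * noise_sd`.
#' @param age_range Ages are truncated to this interval (years).
#'
#' @return An object of class `nd_cohort_config`.
#' @seealso [simulate_cohort()], [oracle_curves()]
#' @export
cohort_config <- function(n_controls = 512L,
                          n_patients = 601L,
                          seed = 1L,
                          roi_names = default_roi_names(),
                          age_mean_sd_controls = c(30.15, 14.26),
                          age_mean_sd_patients = c(31.46, 12.31),
                          male_fraction_controls = 0.5449,
                          male_fraction_patients = 0.6323,
                          trajectory_params = default_trajectories(roi_names),
                          sex_offset = default_sex_offsets(roi_names),
                          effect_size_range = list(FA = c(0.15, 0.45),
                                                   FAt = c(0.25, 0.55),
                                                   FW = c(0.25, 0.55)),
                          affected_roi_counts = 1:6,
                          affect_weights = exp(-0.3 * (0:16)),
                          noise_sd = c(FA = 0.02, FAt = 0.02, FW = 0.015),
                          sd_slope = c(FA = 0, FAt = 0, FW = 0),
                          age_range = c(8, 70)) {
  cfg <- list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    seed = as.integer(seed), roi_names = as.character(roi_names),
    age_mean_sd_controls = as.numeric(age_mean_sd_controls),
    age_mean_sd_patients = as.numeric(age_mean_sd_patients),
    male_fraction_controls = male_fraction_controls,
    male_fraction_patients = male_fraction_patients,
    trajectory_params = trajectory_params, sex_offset = sex_offset,
    effect_size_range = effect_size_range,
    affected_roi_counts = as.integer(affected_roi_counts),
    affect_weights = as.numeric(affect_weights),
    noise_sd = noise_sd, sd_slope = sd_slope, age_range = as.numeric(age_range)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "nd_cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid cohort configuration: `%s` %s", field, why))
  }
  if (cfg$n_controls <= 0) bad("n_controls", "must be > 0")
  if (cfg$n_patients <= 0) bad("n_patients", "must be > 0")
  if (length(cfg$roi_names) != 18L || anyDuplicated(cfg$roi_names)) {
    bad("roi_names", "must hold exactly 18 distinct labels")
  }
  for (f in c("male_fraction_controls", "male_fraction_patients")) {
    p <- cfg[[f]]
    if (!is.numeric(p) || p < 0 || p > 1) bad(f, "must be a proportion in [0, 1]")
  }
  for (f in c("age_mean_sd_controls", "age_mean_sd_patients")) {
    v <- cfg[[f]]
    if (length(v) != 2L || v[2] <= 0) bad(f, "must be (mean, sd) with sd > 0")
  }
  if (any(cfg$noise_sd <= 0)) bad("noise_sd", "must be > 0 for every modality")
  mods <- names(cfg$noise_sd)
  if (!all(mods %in% MODALITIES)) bad("noise_sd", "names must be among FA, FAt, FW")
  if (!all(mods %in% names(cfg$trajectory_params))) {
    bad("trajectory_params", "must cover every modality in noise_sd")
  }
  if (!all(mods %in% names(cfg$effect_size_range))) {
    bad("effect_size_range", "must cover every modality in noise_sd")
  }
  for (m in mods) {
    r <- cfg$effect_size_range[[m]]
    if (any(r < 0) || length(r) != 2L || r[2] < r[1]) {
      bad("effect_size_range", sprintf("for %s must be nonnegative (lo, hi)", m))
    }
    if (nrow(cfg$trajectory_params[[m]]) != 17L) {
      bad("trajectory_params", sprintf("for %s must have one row per tract (17)", m))
    }
  }
  if (any(cfg$affected_roi_counts < 1) || any(cfg$affected_roi_counts > 17)) {
    bad("affected_roi_counts", "must lie in 1..17")
  }
  if (length(cfg$affect_weights) != 17L || any(cfg$affect_weights < 0) ||
      sum(cfg$affect_weights) <= 0) {
    bad("affect_weights", "must be 17 nonnegative weights with a positive sum")
  }
  if (diff(cfg$age_range) <= 0) bad("age_range", "must be increasing (lo, hi)")
  invisible(cfg)
}

cohort_modalities <- function(cfg) names(cfg$noise_sd)

# trajectory mean for the 17 tracts: n x 17 matrix
trajectory_matrix <- function(cfg, modality, age, male) {
  tp <- cfg$trajectory_params[[modality]]
  a <- age - 30
  m <- outer(rep(1, length(age)), tp$base) +
    outer(a, tp$lin) + outer(a^2, tp$quad)
  off <- cfg$sex_offset[[modality]]
  m + outer(as.numeric(male), as.numeric(off))
}

noise_sd_at <- function(cfg, modality, age) {
  s0 <- cfg$noise_sd[[modality]]
  pmax(s0 * (1 + cfg$sd_slope[[modality]] * (age - 30) / 40), 0.2 * s0)
}

rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Simulate a cohort with the statistical structure the analysis assumes
#'
#' Controls are drawn from the normative generative model (smooth ROI-specific
#' age trajectory + sex offset + Gaussian noise). Patients additionally
#' receive a subtle group effect — lower FA/FAt, higher FW — in a per-patient
#' random subset of tracts, implementing the premise that abnormalities occur
#' in spatially distinct regions across individuals. The 18th ROI, the
#' skeleton average, is the exact mean of the 17 tract values, so distributed
#' per-patient effects aggregate into it. Tract values are clipped to
#' (0.01, 0.99).
#'
#' @param config An [cohort_config()] object.
#' @return An object of class `nd_cohort`: a list with
#'   \describe{
#'     \item{subjects}{tibble `id`, `age`, `sex` (`"M"`/`"F"`), `group`
#'       (`"control"`/`"patient"`)}
#'     \item{measures}{named list, one tibble per modality: `id` plus one
#'       column per ROI}
#'   }
#'   The result is byte-identical across calls with the same configuration.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_controls = 40, n_patients = 40,
#'                                         seed = 7))
#' cohort$subjects
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "nd_cohort_config"))
  validate_cohort_config(config)
  cfg <- config
  withr::local_seed(cfg$seed)

  nC <- cfg$n_controls; nP <- cfg$n_patients
  lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
  age_c <- rtruncnorm_vec(nC, cfg$age_mean_sd_controls[1], cfg$age_mean_sd_controls[2], lo, hi)
  age_p <- rtruncnorm_vec(nP, cfg$age_mean_sd_patients[1], cfg$age_mean_sd_patients[2], lo, hi)

  n_male_c <- round(nC * cfg$male_fraction_controls)
  n_male_p <- round(nP * cfg$male_fraction_patients)
  sex_c <- sample(rep(c("M", "F"), c(n_male_c, nC - n_male_c)))
  sex_p <- sample(rep(c("M", "F"), c(n_male_p, nP - n_male_p)))

  subjects <- tibble::tibble(
    id = c(sprintf("C%04d", seq_len(nC)), sprintf("P%04d", seq_len(nP))),
    age = c(age_c, age_p),
    sex = c(sex_c, sex_p),
    group = rep(c("control", "patient"), c(nC, nP))
  )
  male <- subjects$sex == "M"
  is_pat <- subjects$group == "patient"
  n <- nC + nP

  # per-patient affected tract subsets, shared across modalities
  # (index into the count vector: sample() would misread a scalar count)
  k_aff <- cfg$affected_roi_counts[
    sample.int(length(cfg$affected_roi_counts), nP, replace = TRUE)]
  affected <- lapply(k_aff, function(k) {
    sample.int(17L, k, prob = cfg$affect_weights)
  })

  mods <- cohort_modalities(cfg)
  measures <- list()
  for (m in mods) {
    mu <- trajectory_matrix(cfg, m, subjects$age, male)
    sds <- noise_sd_at(cfg, m, subjects$age)
    vals <- mu + matrix(rnorm(n * 17L), n, 17L) * sds
    sign_m <- if (MODALITY_DIRECTION[[m]] == "less") -1 else 1
    rng <- cfg$effect_size_range[[m]]
    base_sd <- cfg$noise_sd[[m]]
    for (j in seq_len(nP)) {
      rois <- affected[[j]]
      d <- runif(length(rois), rng[1], rng[2])
      row <- nC + j
      vals[row, rois] <- vals[row, rois] + sign_m * d * base_sd
    }
    vals <- pmin(pmax(vals, 0.01), 0.99)
    skel <- rowMeans(vals)
    tab <- tibble::as_tibble(cbind(as.data.frame(vals), skel))
    names(tab) <- cfg$roi_names
    measures[[m]] <- dplyr::bind_cols(tibble::tibble(id = subjects$id), tab)
  }

  structure(
    list(subjects = subjects, measures = measures,
         roi_names = cfg$roi_names, config = cfg),
    class = "nd_cohort"
  )
}

#' Ground-truth normative curves of a synthetic configuration
#'
#' Returns the exact generative mean and SD used by [simulate_cohort()],
#' evaluable at any age, for parameter-recovery testing. The skeleton
#' average's mean is the mean of the tract means and its SD is
#' `noise_sd / sqrt(17)` (independent tract noise). Clipping to (0.01, 0.99)
#' is ignored; under the default trajectories it essentially never binds.
#'
#' @inheritParams simulate_cohort
#' @return An object of class `nd_oracle` with functions
#'   `mean(age, roi, modality, sex)` and `sd(age, roi, modality, sex)`,
#'   both vectorised over `age`.
#' @export
oracle_curves <- function(config) {
  stopifnot(inherits(config, "nd_cohort_config"))
  cfg <- config
  tracts <- utils::head(cfg$roi_names, -1L)
  skel <- cfg$roi_names[18L]

  mean_fun <- function(age, roi, modality, sex) {
    male <- sex == "M"
    if (roi == skel) {
      m <- trajectory_matrix(cfg, modality, age, rep(male, length(age)))
      rowMeans(m)
    } else {
      j <- match(roi, tracts)
      if (is.na(j)) abort(sprintf("unknown ROI `%s`", roi))
      tp <- cfg$trajectory_params[[modality]][j, ]
      a <- age - 30
      tp$base + tp$lin * a + tp$quad * a^2 +
        (if (male) cfg$sex_offset[[modality]][[j]] else 0)
    }
  }
  sd_fun <- function(age, roi, modality, sex) {
    s <- noise_sd_at(cfg, modality, age)
    if (roi == skel) s / sqrt(17) else s
  }
  structure(list(mean = mean_fun, sd = sd_fun, config = cfg),
            class = "nd_oracle")
}

#' @export
print.nd_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<nd_cohort> %d subjects (%d controls, %d patients), %d ROIs, modalities: %s\n",
              nrow(x$subjects), tab[["control"]], tab[["patient"]],
              length(x$roi_names), paste(names(x$measures), collapse = ", ")))
  invisible(x)
}

#' Long-format view of a cohort
#'
#' @param x An `nd_cohort`.
#' @param ... Unused.
#' @return Tibble with columns `id`, `age`, `sex`, `group`, `modality`,
#'   `roi`, `value`.
#' @export
as_tibble.nd_cohort <- function(x, ...) {
  purrr::imap_dfr(x$measures, function(tab, m) {
    tidyr::pivot_longer(tab, -"id", names_to = "roi", values_to = "value") |>
      dplyr::mutate(modality = m, .before = "roi")
  }) |>
    dplyr::left_join(x$subjects, by = "id") |>
    dplyr::select("id", "age", "sex", "group", "modality", "roi", "value")
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# measure values as a matrix with subject ids as rownames
measure_matrix <- function(cohort, modality) {
  tab <- cohort$measures[[modality]]
  if (is.null(tab)) abort(sprintf("modality `%s` not present in cohort", modality))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  m
}

# restrict a cohort to a set of subject ids (order preserved as in cohort)
filter_cohort <- function(cohort, ids) {
  keep <- cohort$subjects$id %in% ids
  structure(
    list(
      subjects = cohort$subjects[keep, ],
      measures = lapply(cohort$measures, function(tab) tab[keep, ]),
      roi_names = cohort$roi_names, config = cohort$config
    ),
    class = "nd_cohort"
  )
}

#' Write a cohort to tab-separated files
#'
#' Writes `subjects.tsv` (id, age, sex, group) and one `<modality>.tsv` per
#' modality (id + one column per ROI), headers included, `.` decimal.
#'
#' @param cohort An `nd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  purrr::iwalk(cohort$measures, function(tab, m) {
    readr::write_tsv(tab, file.path(dir, paste0(m, ".tsv")))
  })
  invisible(dir)
}

#' Read a cohort from tab-separated files
#'
#' Counterpart of [write_cohort()]; accepts any directory holding a
#' `subjects.tsv` and per-modality ROI tables in the same schema.
#'
#' @param dir Directory containing `subjects.tsv` and `<modality>.tsv` files.
#' @param modalities Modalities to read (default: those present).
#' @return An `nd_cohort`.
#' @export
read_cohort <- function(dir, modalities = NULL) {
  subjects <- readr::read_tsv(file.path(dir, "subjects.tsv"),
                              show_col_types = FALSE)
  if (is.null(modalities)) {
    present <- sub("\\.tsv$", "", basename(Sys.glob(file.path(dir, "*.tsv"))))
    modalities <- intersect(MODALITIES, present)
  }
  measures <- lapply(stats::setNames(modalities, modalities), function(m) {
    tab <- readr::read_tsv(file.path(dir, paste0(m, ".tsv")),
                           show_col_types = FALSE)
    if (!identical(tab$id, subjects$id)) {
      abort(sprintf("subject ids in %s.tsv do not match subjects.tsv", m))
    }
    tab
  })
  roi_names <- setdiff(names(measures[[1]]), "id")
  structure(list(subjects = subjects, measures = measures,
                 roi_names = roi_names, config = NULL),
            class = "nd_cohort")
}
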