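#' Configuration of a full pipeline run
#'
#' Collects every tunable of the analysis in one place, with explicit
#' defaults for each parameter the method leaves open (bandwidth grid, ridge
#' penalty, KDE regularisation, test tails, abnormality threshold).
#'
#' @param cohort An [cohort_config()] (a synthetic cohort is generated) or an
#'   existing `nd_cohort`.
#' @param modalities Modalities to analyse.
#' @param grid Bandwidth search grid.
#' @param alpha Significance level (abnormality threshold and per-bin tests).
#' @param z_threshold Abnormality threshold; `NULL` computes the two-sided
#'   Bonferroni quantile for 18 ROIs at `alpha` (2.9913 at alpha = 0.05);
#'   supply a number to override.
#' @param lambda Ridge penalty for the classifiers.
#' @param k Number of cross-validation folds.
#' @param feature_specs Feature sets for the classification stage; `NULL`
#'   uses, per modality, `raw:<m>:all` and `z:<m>:all`, plus `z:FAt+FW:all`
#'   when both free-water measures are present.
#' @param per_roi_auc Also run the 2 x 18 single-ROI classifiers per modality
#'   (needed by [report_run()]'s per-ROI AUC table).
#' @param by_sex Additionally repeat the classification per sex.
#' @param seed Seed for fold assignment (and cohort generation when `cohort`
#'   is a configuration; the cohort keeps its own seed if given one).
#' @return An object of class `nd_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       modalities = NULL,
                       grid = bandwidth_grid(),
                       alpha = 0.05,
                       z_threshold = NULL,
                       lambda = 1,
                       k = 10,
                       feature_specs = NULL,
                       per_roi_auc = FALSE,
                       by_sex = FALSE,
                       seed = 1L) {
  structure(
    list(cohort = cohort, modalities = modalities, grid = grid, alpha = alpha,
         z_threshold = z_threshold, lambda = lambda, k = k,
         feature_specs = feature_specs, per_roi_auc = per_roi_auc,
         by_sex = by_sex, seed = as.integer(seed)),
    class = "nd_run_config"
  )
}

default_feature_specs <- function(modalities) {
  specs <- c(sprintf("raw:%s:all", modalities), sprintf("z:%s:all", modalities))
  if (all(c("FAt", "FW") %in% modalities)) specs <- c(specs, "z:FAt+FW:all")
  specs
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> normative fitting -> z-scores ->
#' deviation summaries and significant ranges -> group statistics ->
#' cross-validated classification, writing every stage's tables to
#' `out_dir`:
#' `subjects.tsv` and `<modality>.tsv` (the cohort), `bandwidths.tsv`,
#' `zscores_<modality>.tsv`, `group_stats_<modality>_<kind>.tsv`,
#' `summary_measures_<modality>.tsv`, `summary_tests_<modality>.tsv`,
#' `sig_range_<modality>.json`, `cv_results.tsv`, `coefficients.tsv`, and a
#' `manifest.json` recording the seed and configuration hash. Rerunning with
#' the same configuration reproduces the deterministic stages bit for bit.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, an object of class `nd_run`: list with the cohort,
#'   curves, z-score tables, summaries, significant ranges, group
#'   statistics, CV results and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("ndrun")) {
  stopifnot(inherits(config, "nd_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            parent = e)
    })
    inform(sprintf("[%s] done in %.1fs", name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("cohort", {
    ch <- if (inherits(config$cohort, "nd_cohort_config")) {
      simulate_cohort(config$cohort)
    } else config$cohort
    write_cohort(ch, out_dir)
    ch
  })
  modalities <- config$modalities %||% names(cohort$measures)
  missing_mods <- setdiff(modalities, names(cohort$measures))
  if (length(missing_mods)) {
    abort(sprintf("pipeline stage `cohort` failed: modality `%s` not in cohort",
                  missing_mods[1]))
  }
  threshold <- config$z_threshold %||%
    bonferroni_z_threshold(length(cohort$roi_names), config$alpha)
  grp <- cohort$subjects$group

  zres <- stage("zscores", {
    out <- purrr::map(stats::setNames(modalities, modalities), function(m) {
      r <- compute_zscores(cohort, m, grid = config$grid)
      readr::write_tsv(tibble::as_tibble(r$zscores),
                       file.path(out_dir, sprintf("zscores_%s.tsv", m)))
      r
    })
    bw <- purrr::map_dfr(out, ~ tidy(.x$curves))
    readr::write_tsv(bw, file.path(out_dir, "bandwidths.tsv"))
    out
  })

  devres <- stage("deviation_features", {
    purrr::imap(zres, function(r, m) {
      z <- r$zscores
      sr <- significant_range(z_densities(z[grp == "control", ]),
                              z_densities(z[grp == "patient", ]),
                              alpha = config$alpha)
      sm <- summary_measures(z, threshold, sig_range = sr)
      readr::write_tsv(sm, file.path(out_dir, sprintf("summary_measures_%s.tsv", m)))
      jsonlite::write_json(
        list(modality = m, lower = sr$lower, upper = sr$upper,
             alpha = sr$alpha, p_values = sr$p_values),
        file.path(out_dir, sprintf("sig_range_%s.json", m)),
        auto_unbox = TRUE, digits = NA, na = "null")
      list(sig_range = sr, summaries = sm)
    })
  })

  gstats <- stage("group_stats", {
    purrr::imap(zres, function(r, m) {
      raw <- roi_group_comparison(cohort, m, "raw")
      zz <- roi_group_comparison(cohort, m, "z", zscores = r$zscores)
      readr::write_tsv(raw, file.path(out_dir, sprintf("group_stats_%s_raw.tsv", m)))
      readr::write_tsv(zz, file.path(out_dir, sprintf("group_stats_%s_z.tsv", m)))
      sm <- devres[[m]]$summaries
      st <- summary_group_comparison(sm[grp == "control", ],
                                     sm[grp == "patient", ], modality = m)
      readr::write_tsv(st, file.path(out_dir, sprintf("summary_tests_%s.tsv", m)))
      list(raw = raw, z = zz, summary_tests = st)
    })
  })

  cv <- stage("predict", {
    specs <- config$feature_specs %||% default_feature_specs(modalities)
    if (config$per_roi_auc) {
      roi_specs <- unlist(purrr::map(modalities, function(m) {
        c(sprintf("raw:%s:%s", m, cohort$roi_names),
          sprintf("z:%s:%s", m, cohort$roi_names))
      }))
      specs <- unique(c(specs, roi_specs))
    }
    res <- cross_validate(cohort, specs, k = config$k, lambda = config$lambda,
                          seed = config$seed, grid = config$grid,
                          threshold = threshold, alpha = config$alpha)
    coefs <- cv_coefficients(res)
    if (config$by_sex) {
      bysex <- sex_stratified_cv(cohort, config$feature_specs %||%
                                   default_feature_specs(modalities),
                                 k = config$k, lambda = config$lambda,
                                 seed = config$seed, grid = config$grid,
                                 threshold = threshold, alpha = config$alpha)
      res$sex <- "all"
      coefs$sex <- "all"
      coefs <- dplyr::bind_rows(coefs, cv_coefficients(bysex))
      res <- dplyr::bind_rows(tibble::as_tibble(res), tibble::as_tibble(bysex))
      attr(res, "coefficients") <- coefs
      attr(res, "k") <- config$k
      class(res) <- c("nd_cv", class(res))
    }
    cvtab <- tibble::as_tibble(res) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        intersect(c("feature_set", "sex"), names(res))))) |>
      dplyr::mutate(mean_auc = mean(.data$auc), seed = config$seed) |>
      dplyr::ungroup()
    readr::write_tsv(cvtab, file.path(out_dir, "cv_results.tsv"))
    readr::write_tsv(coefs, file.path(out_dir, "coefficients.tsv"))
    res
  })

  manifest <- list(
    package = "normdev",
    version = as.character(utils::packageVersion("normdev")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    modalities = modalities,
    n_subjects = nrow(cohort$subjects),
    z_threshold = threshold,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(
    list(cohort = cohort, zscores = zres, deviations = devres,
         group_stats = gstats, cv = cv, threshold = threshold,
         modalities = modalities, out_dir = out_dir, config = config),
    class = "nd_run"
  ))
}

#' Summaries of a completed pipeline run
#'
#' Reads a run directory produced by [run_pipeline()] and writes five CSV
#' summary tables: per-ROI effect sizes raw vs z, summary-measure effect
#' sizes, per-ROI AUC raw vs z, per-modality combined AUC, and the best
#' modality per ROI.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param out_dir Where to write the summaries (default: `run_dir`).
#' @return Invisibly, a named list of the five tibbles.
#' @export
report_run <- function(run_dir, out_dir = run_dir) {
  needed <- c("cv_results.tsv", "manifest.json")
  mods <- sub("^zscores_(.*)\\.tsv$", "\\1",
              basename(Sys.glob(file.path(run_dir, "zscores_*.tsv"))))
  if (length(mods)) {
    needed <- c(needed,
                sprintf("group_stats_%s_raw.tsv", mods),
                sprintf("group_stats_%s_z.tsv", mods),
                sprintf("summary_tests_%s.tsv", mods))
  }
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing) || !length(mods)) {
    abort(sprintf("incomplete run directory `%s`; missing: %s", run_dir,
                  paste(c(missing, if (!length(mods)) "zscores_*.tsv"),
                        collapse = ", ")))
  }
  rd <- function(f) readr::read_tsv(file.path(run_dir, f), show_col_types = FALSE)

  effect_raw_z <- purrr::map_dfr(mods, function(m) {
    raw <- rd(sprintf("group_stats_%s_raw.tsv", m))
    zz <- rd(sprintf("group_stats_%s_z.tsv", m))
    dplyr::inner_join(
      dplyr::select(raw, "roi", "modality", d_raw = "effect_size", p_raw = "p_value"),
      dplyr::select(zz, "roi", "modality", d_z = "effect_size", p_z = "p_value"),
      by = c("roi", "modality"))
  })
  summary_effects <- purrr::map_dfr(mods, function(m) {
    dplyr::mutate(rd(sprintf("summary_tests_%s.tsv", m)), modality = m)
  })
  cvtab <- rd("cv_results.tsv")
  if ("sex" %in% names(cvtab)) cvtab <- dplyr::filter(cvtab, .data$sex == "all")
  mean_auc <- cvtab |>
    dplyr::distinct(.data$feature_set, .data$mean_auc)
  per_roi <- mean_auc |>
    dplyr::filter(grepl("^(raw|z):[^:]+:", .data$feature_set) &
                    !grepl(":all", .data$feature_set)) |>
    tidyr::separate_wider_delim("feature_set", ":",
                                names = c("kind", "modality", "roi")) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "mean_auc",
                       names_prefix = "auc_")
  combined <- mean_auc |>
    dplyr::filter(grepl("^z:.*:all$", .data$feature_set)) |>
    dplyr::mutate(modality = sub("^z:(.*):all$", "\\1", .data$feature_set)) |>
    dplyr::select("modality", mean_auc = "mean_auc")
  best_per_roi <- if (nrow(per_roi) && "auc_z" %in% names(per_roi)) {
    per_roi |>
      dplyr::group_by(.data$roi) |>
      dplyr::slice_max(.data$auc_z, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("roi", best_modality = "modality", auc = "auc_z")
  } else {
    tibble::tibble(roi = character(), best_modality = character(),
                   auc = numeric())
  }

  out <- list(effectsizes_raw_vs_z = effect_raw_z,
              summary_measure_effects = summary_effects,
              per_roi_auc = per_roi,
              combined_auc = combined,
              best_modality_per_roi = best_per_roi)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(out, function(tab, nm) {
    readr::write_csv(tab, file.path(out_dir, paste0(nm, ".csv")))
  })
  invisible(out)
}
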