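# End-to-end orchestration: instrument derivation, harmonisation, the
# univariable and multivariable estimator suites, sensitivity reruns, and
# report writing.

#' Analysis configuration
#'
#' Thresholds and model definitions for the pipeline. The defaults are the
#' conventional ones for this analysis: genome-wide significance 5e-8, LD
#' clumping at r-squared 0.001, proxies at r-squared above 0.8, a two-sided
#' alpha of 0.01 (Bonferroni for five correlated lipid traits), and two
#' multivariable models — the atherogenic model (apoB, LDL, TG) and the
#' HDL-pathway model (apoB, HDL, apoA1).
#'
#' @param traits Traits to analyse.
#' @param p_threshold Genome-wide significance threshold.
#' @param clump_r2 LD-clumping r-squared threshold.
#' @param proxy_r2 Strict lower bound for proxy r-squared.
#' @param alpha Two-sided evidence-grading level.
#' @param models List of character vectors: exposure sets for multivariable
#'   MR (each needs at least 2 exposures).
#' @param estimators Univariable estimators to run.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Seed for all stochastic steps (bootstraps).
#' @param adjust_fasting Include the fasting-hours covariate in the exposure
#'   GWAS (needs individual-level data in the study object).
#' @param palindromic_window See [align_alleles()].
#' @return An `mr_analysis_config` list.
#' @export
mr_config <- function(traits = c("apoB", "LDL", "TG", "HDL", "apoA1"),
                      p_threshold = 5e-8, clump_r2 = 0.001, proxy_r2 = 0.8,
                      alpha = 0.01,
                      models = list(c("apoB", "LDL", "TG"),
                                    c("apoB", "HDL", "apoA1")),
                      estimators = c("ivw", "egger", "weighted_median",
                                     "weighted_mode"),
                      n_boot = 1000, seed = 1L, adjust_fasting = FALSE,
                      palindromic_window = c(0.42, 0.58)) {
  stopifnot(p_threshold > 0, p_threshold < 1, clump_r2 > 0, clump_r2 < 1,
            proxy_r2 > 0, proxy_r2 < 1, alpha > 0, alpha < 1)
  if (any(vapply(models, length, 1L) < 2)) {
    abort("each multivariable model needs at least 2 exposures")
  }
  structure(list(traits = traits, p_threshold = p_threshold,
                 clump_r2 = clump_r2, proxy_r2 = proxy_r2, alpha = alpha,
                 models = models, estimators = estimators, n_boot = n_boot,
                 seed = as.integer(seed), adjust_fasting = adjust_fasting,
                 palindromic_window = palindromic_window),
            class = "mr_analysis_config")
}

# exposure stats for the configured run: precomputed ones, or a re-run of the
# sample-1 GWAS with the fasting covariate added
.study_exposure_stats <- function(study, config) {
  if (!isTRUE(config$adjust_fasting)) return(study$exposure_stats)
  if (is.null(study$sample1)) {
    abort("adjust_fasting needs individual-level data in the study object")
  }
  covs <- as.matrix(study$sample1$covariates[, "fasting_hours", drop = FALSE])
  X <- study$sample1$exposures
  stats <- lapply(colnames(X), function(tr) {
    snp_association(study$sample1$panel, inverse_rank_normalise(X[, tr]),
                    covariates = covs, family = "linear", trait_name = tr)
  })
  setNames(stats, colnames(X))
}

# clumped instruments for one trait
.derive_instruments <- function(stats, ld, config) {
  stats |>
    filter_genome_wide(config$p_threshold) |>
    ld_clump(ld, config$clump_r2)
}

#' Univariable MR suite
#'
#' For each trait: derive instruments (genome-wide filter + LD clumping),
#' harmonise them to the outcome statistics (with proxy substitution),
#' run the configured estimators, and attach the mean F-statistic and an
#' evidence grade at the configured alpha.
#'
#' @param study An `mr_study` from [simulate_mr_study()], or any list with
#'   `exposure_stats` (named list of full summary-stat tibbles),
#'   `outcome_stats` and `ld`.
#' @param config An [mr_config()].
#' @return Tidy tibble: one row per trait x estimator, with odds-ratio scale
#'   columns, Egger intercept columns, `mean_f` and `evidence`.
#' @export
run_univariable_suite <- function(study, config = mr_config()) {
  exposure_stats <- .study_exposure_stats(study, config)
  traits <- intersect(config$traits, names(exposure_stats))
  if (!length(traits)) abort("no configured trait has summary statistics")
  rows <- purrr::map(traits, function(tr) {
    inst <- .derive_instruments(exposure_stats[[tr]], study$ld, config)
    H <- harmonise_mvmr(setNames(list(exposure_stats[[tr]]), tr),
                        inst$snp, study$outcome_stats, ld = study$ld,
                        proxy_r2 = config$proxy_r2,
                        palindromic_window = config$palindromic_window)
    inst_used <- inst[inst$snp %in% H$snp, ]
    fits <- purrr::map(config$estimators, function(m) {
      switch(m,
             ivw = mr_ivw(H, tr),
             egger = mr_egger(H, tr),
             weighted_median = mr_weighted_median(H, tr,
                                                  n_boot = config$n_boot,
                                                  seed = config$seed),
             weighted_mode = mr_weighted_mode(H, tr,
                                              n_boot = config$n_boot,
                                              seed = config$seed),
             abort(paste("unknown estimator:", m)))
    })
    dplyr::bind_rows(purrr::map(fits, function(f) {
      dplyr::bind_cols(tidy(f),
                       glance(f)[, c("residual_scale", "egger_intercept",
                                     "egger_intercept_se",
                                     "egger_intercept_p")])
    })) |>
      dplyr::mutate(mean_f = mean_f_statistic(inst_used),
                    retention = attr(H, "retention"))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(evidence = .data$p < config$alpha)
}

#' Multivariable MR suite
#'
#' For each configured model: instruments are derived per trait, their union
#' is harmonised against the full summary statistics of every model exposure
#' and the outcome, and multivariable IVW and MR-Egger are run together with
#' per-exposure conditional F-statistics.
#'
#' @inheritParams run_univariable_suite
#' @return Tidy tibble: model, method, exposure rows (the Egger intercept
#'   appears as exposure `"(intercept)"`), `n_snps` (the union actually
#'   used), `conditional_f`.
#' @export
run_multivariable_suite <- function(study, config = mr_config()) {
  exposure_stats <- .study_exposure_stats(study, config)
  rows <- purrr::map(config$models, function(model) {
    missing <- setdiff(model, names(exposure_stats))
    if (length(missing)) {
      abort(paste("model exposures without summary statistics:",
                  paste(missing, collapse = ", ")))
    }
    insts <- purrr::map(model, function(tr) {
      .derive_instruments(exposure_stats[[tr]], study$ld, config)
    })
    union_snps <- unique(unlist(purrr::map(insts, "snp")))
    H <- harmonise_mvmr(exposure_stats[model], union_snps,
                        study$outcome_stats, ld = study$ld,
                        proxy_r2 = config$proxy_r2,
                        palindromic_window = config$palindromic_window)
    model_id <- paste(model, collapse = "+")
    ivw <- mvmr_ivw(H, model)
    egg <- mvmr_egger(H, model)
    cf <- conditional_f_statistics(H, model)
    ivw_tbl <- tidy(ivw) |>
      dplyr::left_join(cf, by = "exposure")
    egg_tbl <- dplyr::bind_rows(
      tidy(egg),
      to_odds_ratio(
        dplyr::mutate(.estimate_row("(intercept)",
                                    egg$intercept$estimate,
                                    egg$intercept$se),
                      method = "mvmr_egger", n_snps = egg$n_snps,
                      .before = 1)))
    dplyr::bind_rows(ivw_tbl, egg_tbl) |>
      dplyr::mutate(model = model_id, .before = 1)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(evidence = .data$p < config$alpha)
}

#' Sensitivity suite
#'
#' Re-runs the analysis under the configured perturbations and reports
#' side-by-side deltas against the main run:
#' \itemize{
#'   \item `fasting`: exposure GWAS re-derived with the fasting-hours
#'     covariate (requires individual-level data);
#'   \item `no_apob`: multivariable models with the apoB-like exposure
#'     removed, exposing the residual HDL/LDL associations that mutual
#'     adjustment for apoB otherwise removes.
#' }
#'
#' @inheritParams run_univariable_suite
#' @param apob Name of the apoB-like trait to exclude (default `"apoB"`).
#' @return List: `main`, `main_mv`, `fasting`, `fasting_mv`, `no_apob_mv`,
#'   `delta` (per trait x method, change in beta and in units of the joint
#'   SE between the main and fasting-adjusted univariable runs).
#' @export
run_sensitivity_suite <- function(study, config = mr_config(),
                                  apob = "apoB") {
  main <- run_univariable_suite(study, config)
  main_mv <- run_multivariable_suite(study, config)

  fasting <- fasting_mv <- NULL
  if (!is.null(study$sample1)) {
    cfg_f <- config; cfg_f$adjust_fasting <- TRUE
    fasting <- run_univariable_suite(study, cfg_f)
    fasting_mv <- run_multivariable_suite(study, cfg_f)
  }

  reduced <- purrr::map(config$models, setdiff, y = apob)
  reduced <- unique(reduced[vapply(reduced, length, 1L) >= 2])
  no_apob_mv <- NULL
  if (length(reduced)) {
    cfg_r <- config; cfg_r$models <- reduced
    no_apob_mv <- run_multivariable_suite(study, cfg_r)
  }

  delta <- NULL
  if (!is.null(fasting)) {
    delta <- dplyr::inner_join(
      dplyr::select(main, "exposure", "method", beta_main = "beta",
                    se_main = "se"),
      dplyr::select(fasting, "exposure", "method", beta_fast = "beta",
                    se_fast = "se"),
      by = c("exposure", "method")) |>
      dplyr::mutate(delta_beta = .data$beta_fast - .data$beta_main,
                    joint_se = sqrt(.data$se_main^2 + .data$se_fast^2),
                    delta_in_se = .data$delta_beta / .data$joint_se)
  }
  list(main = main, main_mv = main_mv, fasting = fasting,
       fasting_mv = fasting_mv, no_apob_mv = no_apob_mv, delta = delta)
}

#' Write a results report
#'
#' Writes the results table as TSV and as versioned JSON (schema 1.0:
#' `{schema_version, created_with, results}`), plus an optional forest plot.
#' Output is deterministic for a fixed table (the plot file is excluded from
#' any determinism guarantee).
#'
#' @param results Nonempty tidy results tibble.
#' @param dir Output directory (created if needed).
#' @param name File stem (default `"mr_results"`).
#' @param plot Also write a forest plot PDF (default `FALSE`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir, name = "mr_results", plot = FALSE) {
  if (is.null(results) || nrow(results) == 0) abort("results are empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  json <- file.path(dir, paste0(name, ".json"))
  readr::write_tsv(results, tsv)
  jsonlite::write_json(list(schema_version = "1.0",
                            created_with = "lipidmr",
                            results = results),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(tsv = tsv, json = json)
  if (plot) {
    pdf_path <- file.path(dir, paste0(name, ".pdf"))
    ggplot2::ggsave(pdf_path, plot_forest(results), width = 7, height = 5)
    paths <- c(paths, pdf = pdf_path)
  }
  invisible(paths)
}

#' Check a written report against the shipped schema
#'
#' Lightweight structural validation of the JSON written by [write_report()]:
#' required top-level keys, schema version, and required per-row fields.
#'
#' @param path Path to the JSON file.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("schema_version", "created_with", "results")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste("report JSON missing keys:", paste(missing, collapse = ", ")))
  }
  if (!identical(x$schema_version, "1.0")) {
    abort(paste("unsupported schema version:", x$schema_version))
  }
  fields <- c("method", "exposure", "beta", "se", "p", "or")
  missing <- setdiff(fields, names(x$results))
  if (length(missing)) {
    abort(paste("result rows missing fields:",
                paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
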