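# Replicate-level simulation studies: parameter recovery under the lipid
# preset and frequentist calibration of the estimators under the null.
# These are the package's own evaluation harnesses; the methods vignette
# discusses the study conditions they encode.

#' Parameter-recovery benchmark for multivariable MR
#'
#' Repeatedly simulates the three-trait atherogenic preset (apoB-like, LDL-
#' like, TG-like exposures with true direct effects 0.65, 0 and 0.10 log-odds
#' per SD and an apoB-LDL correlation of 0.96), runs the full pipeline
#' (association scans, genome-wide filter, LD clumping, harmonisation) and
#' records the MVMR-IVW direct-effect estimates, the univariable IVW estimate
#' for the fully mediated LDL-like trait, and the conditional F-statistics.
#'
#' @param n_reps Number of replicate studies.
#' @param n_per_sample Individuals per (disjoint) sample.
#' @param m_snps Variants per study.
#' @param n_causal Causal variants per study.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return Tibble, one row per replicate: `theta_hat_apoB/ LDL/ TG`, their
#'   SEs, `ldl_uni_beta`, `ldl_uni_se`, `cond_f_*`, `n_union`.
#' @export
benchmark_recovery <- function(n_reps = 100, n_per_sample = 20000,
                               m_snps = 300, n_causal = 40, seed = 1L) {
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1, n_reps))
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- lipid_preset(traits = c("apoB", "LDL", "TG"),
                        n_exposure_sample = n_per_sample,
                        n_outcome_sample = n_per_sample,
                        m_snps = m_snps, n_causal = n_causal,
                        seed = seeds[r])
    st <- simulate_mr_study(cfg, keep_individual = FALSE)
    insts <- lapply(st$exposure_stats, function(s) {
      ld_clump(filter_genome_wide(s), st$ld)
    })
    union_snps <- unique(unlist(lapply(insts, function(x) x$snp)))
    H <- harmonise_mvmr(st$exposure_stats, union_snps, st$outcome_stats,
                        ld = st$ld)
    fit <- mvmr_ivw(H)
    cf <- conditional_f_statistics(H)
    Hl <- harmonise_mvmr(st$exposure_stats["LDL"], insts$LDL$snp,
                         st$outcome_stats, ld = st$ld)
    ul <- mr_ivw(Hl, "LDL")
    tibble::tibble(
      rep = r,
      theta_hat_apoB = fit$estimates$beta[1],
      theta_hat_LDL = fit$estimates$beta[2],
      theta_hat_TG = fit$estimates$beta[3],
      se_apoB = fit$estimates$se[1],
      se_LDL = fit$estimates$se[2],
      se_TG = fit$estimates$se[3],
      ldl_uni_beta = ul$estimates$beta,
      ldl_uni_se = ul$estimates$se,
      cond_f_apoB = cf$conditional_f[1],
      cond_f_LDL = cf$conditional_f[2],
      cond_f_TG = cf$conditional_f[3],
      mean_f_LDL = mean_f_statistic(insts$LDL),
      n_union = nrow(H))
  })
}

#' Null-calibration benchmark for the univariable estimators
#'
#' Simulates a single strongly instrumented exposure with *no* effect on the
#' outcome (and a confounder, which leaves the SNPs null), runs the pipeline,
#' and records whether each estimator's 95% interval covers zero. With
#' `pleiotropy = "balanced"` the exposure is given a real effect (0.3) plus
#' balanced horizontal pleiotropy, and the recorded indicator is whether the
#' MR-Egger intercept interval covers zero (its truth under the InSIDE
#' assumption).
#'
#' @param n_reps Replicates.
#' @param n_per_sample,m_snps,n_causal Study dimensions (defaults keep a
#'   replicate around 0.5 s).
#' @param pleiotropy `"none"` (null coverage of all estimators) or
#'   `"balanced"` (Egger intercept coverage).
#' @param n_boot Bootstrap replicates behind the median/mode SEs.
#' @param seed Master seed.
#' @return Tibble of logical coverage indicators, one row per replicate.
#' @export
benchmark_calibration <- function(n_reps = 500, n_per_sample = 4000,
                                  m_snps = 60, n_causal = 30,
                                  pleiotropy = c("none", "balanced"),
                                  n_boot = 500, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1, n_reps))
  theta <- if (pleiotropy == "none") 0 else 0.3
  pspec <- if (pleiotropy == "none") {
    list(mode = "none", sd = 0, mean = 0)
  } else {
    list(mode = "balanced", sd = 0.02, mean = 0)
  }
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_exposure_sample = n_per_sample,
                      n_outcome_sample = n_per_sample,
                      m_snps = m_snps, k_traits = 1,
                      trait_names = "X", n_causal = n_causal,
                      genetic_cov = matrix(0.4),
                      confounder_loadings = 0.3,
                      confounder_outcome_loading = 0.3,
                      true_direct_effects = theta,
                      pleiotropy_spec = pspec,
                      seed = seeds[r])
    st <- simulate_mr_study(cfg, keep_individual = FALSE)
    inst <- ld_clump(filter_genome_wide(st$exposure_stats$X), st$ld)
    H <- harmonise_mvmr(st$exposure_stats, inst$snp, st$outcome_stats,
                        ld = st$ld)
    covers0 <- function(est) {
      est$estimates$ci_lo <= 0 && est$estimates$ci_hi >= 0
    }
    if (pleiotropy == "none") {
      wm <- mr_weighted_median(H, n_boot = n_boot, seed = seeds[r])
      wo <- mr_weighted_mode(H, n_boot = n_boot, seed = seeds[r])
      tibble::tibble(rep = r, n_snps = nrow(H),
                     ivw = covers0(mr_ivw(H)),
                     egger = covers0(mr_egger(H)),
                     weighted_median = covers0(wm),
                     weighted_mode = covers0(wo))
    } else {
      eg <- mr_egger(H)
      lo <- eg$intercept$estimate - Z975 * eg$intercept$se
      hi <- eg$intercept$estimate + Z975 * eg$intercept$se
      tibble::tibble(rep = r, n_snps = nrow(H),
                     egger_intercept = lo <= 0 && hi >= 0)
    }
  })
}
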