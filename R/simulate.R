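#' Simulation configuration for a two-sample MR study
#'
#' Bundles everything the synthetic-data generator needs: sample sizes for the
#' (disjoint) exposure and outcome samples, the variant map, per-allele SNP
#' effects on the latent traits, the factor structure inducing trait
#' correlations, the true direct effects on the binary outcome, and a
#' pleiotropy specification.
#'
#' The generative model is
#' \deqn{X = G_c A + U \lambda_c' + F \lambda_s' + E,\qquad
#'       \mathrm{logit}\,P(Y=1) = \alpha + X\theta + \gamma U + G_c \delta,}
#' where \eqn{G_c} is the mean-centred dosage matrix, \eqn{U} a standard-normal
#' confounder shared between traits and outcome, \eqn{F} an inert shared
#' factor, \eqn{E} multivariate-normal residuals with covariance
#' `resid_cov`, and \eqn{\delta} the per-SNP pleiotropic effects. Columns of
#' \eqn{X} are standardised to mean 0, SD 1, so `true_direct_effects` are
#' log-odds per 1-SD of trait. The intercept \eqn{\alpha} is solved
#' numerically so the expected case fraction matches `outcome_prevalence`.
#'
#' @param n_exposure_sample,n_outcome_sample Individuals in sample 1 (exposure
#'   GWAS) and sample 2 (outcome GWAS). The samples are disjoint by
#'   construction: each is an independent draw from the same SNP map.
#' @param m_snps Number of variants.
#' @param k_traits Number of exposures.
#' @param trait_names Character vector of length `k_traits`.
#' @param allele_freq_range Effect-allele frequencies are drawn uniformly from
#'   this open interval; both ends must lie in (0, 1).
#' @param snp_effect_matrix `m_snps x k_traits` per-allele effects on the
#'   latent (pre-standardisation) traits, or `NULL` to draw a sparse matrix at
#'   simulation time (see `n_causal`, `genetic_cov`).
#' @param n_causal When `snp_effect_matrix` is `NULL`, the number of SNPs with
#'   nonzero effects.
#' @param genetic_cov Target genetic covariance matrix (`k x k`). When
#'   supplied together with a drawn effect matrix, effects are exactly
#'   normalised so that `t(A) %*% diag(2f(1-f)) %*% A == genetic_cov`.
#' @param shared_factor_loadings,confounder_loadings Numeric k-vectors.
#' @param confounder_outcome_loading Log-odds effect of the confounder on the
#'   outcome (this is what makes `U` a confounder rather than noise).
#' @param resid_cov Residual covariance of `E` (`k x k`), or `NULL` for a
#'   diagonal matrix topping each trait variance up to 1.
#' @param covariate_loadings Optional `k x 3` matrix of effects of the
#'   generated covariates (age, sex, fasting hours; each used standardised) on
#'   the traits. Default all zero: covariates are carried for pipeline
#'   fidelity without disturbing the calibrated correlation structure.
#' @param true_direct_effects Numeric k-vector \eqn{\theta} of direct log-odds
#'   effects per 1-SD trait; the recovery target of multivariable MR.
#' @param pleiotropy_spec List with elements `mode` (one of `"none"`,
#'   `"balanced"`, `"directional"`, `"inside_violating"`), `sd` and `mean`.
#'   Balanced: direct SNP-outcome effects drawn N(0, sd^2) on causal SNPs.
#'   Directional: N(mean, sd^2). Inside-violating: effects proportional to the
#'   SNP's effect on the first trait (breaks the InSIDE assumption).
#' @param outcome_prevalence Target case fraction in sample 2.
#' @param n_chroms Number of chromosomes the SNP map is laid out over
#'   (default 22; use 1 to force all SNPs onto one chromosome in small test
#'   panels).
#' @param ld_blocks Optional list `(n_blocks, block_size, swap_frac)`. Each
#'   block copies a template SNP's dosages and independently resamples a
#'   fraction `swap_frac` of individuals, giving pairwise correlation of about
#'   `1 - swap_frac` within the block (tunable r-squared for clumping and
#'   proxy tests).
#' @param seed Integer seed; identical configurations give bit-identical
#'   output from every generator.
#'
#' @return An object of class `sim_config` (a list).
#' @seealso [lipid_preset()] for the calibrated five-trait and three-trait
#'   lipid presets, [simulate_mr_study()] to run the generator end to end.
#' @export
sim_config <- function(n_exposure_sample = 10000,
                       n_outcome_sample = 10000,
                       m_snps = 100,
                       k_traits = 1,
                       trait_names = paste0("trait", seq_len(k_traits)),
                       allele_freq_range = c(0.05, 0.95),
                       snp_effect_matrix = NULL,
                       n_causal = min(20L, m_snps),
                       genetic_cov = NULL,
                       shared_factor_loadings = rep(0, k_traits),
                       confounder_loadings = rep(0, k_traits),
                       confounder_outcome_loading = 0,
                       resid_cov = NULL,
                       covariate_loadings = NULL,
                       true_direct_effects = rep(0, k_traits),
                       pleiotropy_spec = list(mode = "none", sd = 0, mean = 0),
                       outcome_prevalence = 0.33,
                       n_chroms = 22L,
                       ld_blocks = NULL,
                       seed = 1L) {
  if (m_snps < 0 || n_exposure_sample < 0 || n_outcome_sample < 0) {
    abort("sample sizes and m_snps must be non-negative",
          class = "lipidmr_config_error")
  }
  if (length(allele_freq_range) != 2 ||
      allele_freq_range[1] <= 0 || allele_freq_range[2] >= 1 ||
      allele_freq_range[1] >= allele_freq_range[2]) {
    abort("allele_freq_range must satisfy 0 < low < high < 1",
          class = "lipidmr_config_error")
  }
  if (length(true_direct_effects) != k_traits ||
      length(trait_names) != k_traits) {
    abort("trait_names and true_direct_effects must have length k_traits",
          class = "lipidmr_config_error")
  }
  if (!is.null(snp_effect_matrix) &&
      !identical(dim(snp_effect_matrix), c(m_snps, k_traits))) {
    abort("snp_effect_matrix must be m_snps x k_traits",
          class = "lipidmr_config_error")
  }
  pleiotropy_spec$mode <- match.arg(pleiotropy_spec$mode,
                                    c("none", "balanced", "directional",
                                      "inside_violating"))
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1) {
    abort("outcome_prevalence must be in (0, 1)",
          class = "lipidmr_config_error")
  }
  structure(
    list(n_exposure_sample = as.integer(n_exposure_sample),
         n_outcome_sample = as.integer(n_outcome_sample),
         m_snps = as.integer(m_snps), k_traits = as.integer(k_traits),
         trait_names = trait_names, allele_freq_range = allele_freq_range,
         snp_effect_matrix = snp_effect_matrix,
         n_causal = as.integer(n_causal), genetic_cov = genetic_cov,
         shared_factor_loadings = shared_factor_loadings,
         confounder_loadings = confounder_loadings,
         confounder_outcome_loading = confounder_outcome_loading,
         resid_cov = resid_cov, covariate_loadings = covariate_loadings,
         true_direct_effects = true_direct_effects,
         pleiotropy_spec = pleiotropy_spec,
         outcome_prevalence = outcome_prevalence,
         n_chroms = as.integer(n_chroms),
         ld_blocks = ld_blocks, seed = as.integer(seed)),
    class = "sim_config")
}

# Calibrated constants for the lipid presets. Trait order is
# (apoB, LDL, TG, HDL, apoA1). The two anchor correlations are apoB-LDL 0.96
# and TG-HDL -0.49; remaining phenotypic and genetic correlations are chosen
# to be lipid-realistic while keeping the residual covariance
# Psi = R - Cg - lc lc' positive semi-definite.
.lipid_traits <- c("apoB", "LDL", "TG", "HDL", "apoA1")

.lipid_corr <- local({
  R <- diag(5)
  dimnames(R) <- list(.lipid_traits, .lipid_traits)
  R["apoB", "LDL"] <- 0.96; R["apoB", "TG"] <- 0.45
  R["apoB", "HDL"] <- -0.05; R["apoB", "apoA1"] <- -0.05
  R["LDL", "TG"] <- 0.35; R["LDL", "HDL"] <- 0; R["LDL", "apoA1"] <- 0
  R["TG", "HDL"] <- -0.49; R["TG", "apoA1"] <- -0.30
  R["HDL", "apoA1"] <- 0.92
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
})

.lipid_genetic_corr <- local({
  R <- diag(5)
  dimnames(R) <- list(.lipid_traits, .lipid_traits)
  R["apoB", "LDL"] <- 0.945; R["apoB", "TG"] <- 0.45
  R["apoB", "HDL"] <- -0.10; R["apoB", "apoA1"] <- -0.10
  R["LDL", "TG"] <- 0.25; R["LDL", "HDL"] <- -0.05
  R["LDL", "apoA1"] <- -0.05
  R["TG", "HDL"] <- -0.55; R["TG", "apoA1"] <- -0.35
  R["HDL", "apoA1"] <- 0.90
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
})

.lipid_h2 <- c(apoB = 0.55, LDL = 0.55, TG = 0.45, HDL = 0.50, apoA1 = 0.50)
.lipid_conf <- c(apoB = 0.15, LDL = 0.10, TG = 0.25, HDL = -0.20,
                 apoA1 = -0.15)
.lipid_theta <- c(apoB = 0.65, LDL = 0, TG = 0.10, HDL = 0, apoA1 = 0)

#' Calibrated lipid-trait simulation presets
#'
#' Returns a [sim_config()] emulating the statistical structure of a large
#' lipid GWAS feeding a two-sample MR of coronary heart disease: five highly
#' correlated standardised exposures (apolipoprotein B, LDL cholesterol,
#' triglycerides, HDL cholesterol, apolipoprotein A-I), a shared confounder,
#' and a binary outcome whose only direct lipid causes are the apoB-like trait
#' (log-odds 0.65 per SD) and, weakly, the TG-like trait (0.10); the LDL-like
#' effect is fully mediated by apoB. Phenotypic correlations are calibrated so
#' that corr(LDL, apoB) is 0.96 and corr(HDL, TG) is -0.49.
#'
#' @param traits Which traits to include, a subset of
#'   `c("apoB", "LDL", "TG", "HDL", "apoA1")`. The three-trait preset
#'   `c("apoB", "LDL", "TG")` is the atherogenic-model recovery benchmark.
#' @param n_exposure_sample,n_outcome_sample,m_snps,seed See [sim_config()].
#' @param n_causal Number of SNPs with nonzero trait effects (default 40):
#'   a sparse architecture of strong loci, keeping single-SNP F-statistics in
#'   the range reported for real lipid instruments.
#' @param outcome_prevalence Case fraction (default 0.33, the case/control
#'   composition of the outcome consortium data the design emulates).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
lipid_preset <- function(traits = .lipid_traits,
                         n_exposure_sample = 20000,
                         n_outcome_sample = 20000,
                         m_snps = 300, n_causal = 40,
                         outcome_prevalence = 0.33, seed = 1L, ...) {
  traits <- match.arg(traits, .lipid_traits, several.ok = TRUE)
  k <- length(traits)
  R <- .lipid_corr[traits, traits, drop = FALSE]
  Rg <- .lipid_genetic_corr[traits, traits, drop = FALSE]
  h2 <- .lipid_h2[traits]
  lc <- .lipid_conf[traits]
  Cg <- (sqrt(h2) %o% sqrt(h2)) * Rg
  Psi <- R - Cg - lc %o% lc
  ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("preset residual covariance is not positive semi-definite")
  }
  sim_config(n_exposure_sample = n_exposure_sample,
             n_outcome_sample = n_outcome_sample,
             m_snps = m_snps, k_traits = k, trait_names = traits,
             n_causal = n_causal, genetic_cov = Cg,
             confounder_loadings = lc, confounder_outcome_loading = 0.25,
             resid_cov = Psi, true_direct_effects = unname(.lipid_theta[traits]),
             outcome_prevalence = outcome_prevalence, seed = seed, ...)
}

# symmetric positive semi-definite square root
.msqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

.ACGT <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# SNP map shared by both samples: ids, chromosome/position layout, alleles,
# frequencies, the realised effect matrix and the causal index set.
.simulate_snp_map <- function(config) {
  m <- config$m_snps
  k <- config$k_traits
  f <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
  # 250 kb spacing so novelty windows contain neighbours
  nc <- config$n_chroms %||% 22L
  chrom <- rep(seq_len(nc), each = ceiling(m / nc), length.out = m)
  pos <- integer(m)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    pos[idx] <- 100000L + (seq_along(idx) - 1L) * 250000L
  }
  ea <- character(m); oa <- character(m)
  for (j in seq_len(m)) {
    al <- sample(.ACGT, 2)
    ea[j] <- al[1]; oa[j] <- al[2]
  }
  A <- config$snp_effect_matrix
  causal <- integer(0)
  if (is.null(A)) {
    A <- matrix(0, m, k)
    if (config$n_causal > 0 && m > 0) {
      causal <- sort(sample.int(m, min(config$n_causal, m)))
      A[causal, ] <- matrix(rnorm(length(causal) * k), length(causal), k)
      if (!is.null(config$genetic_cov)) {
        vG <- 2 * f * (1 - f)
        M <- crossprod(A, A * vG)
        A <- A %*% solve(.msqrt(M)) %*% .msqrt(config$genetic_cov)
      }
    }
  } else {
    causal <- which(rowSums(abs(A)) > 0)
  }
  list(snp = if (m > 0) paste0("rs", seq_len(m)) else character(0),
       chr = chrom, bp = pos,
       ea = ea, oa = oa, freq = f, A = A, causal = causal)
}

#' Simulate a genotype dosage panel
#'
#' Dosages are drawn i.i.d. Binomial(2, f_j) per SNP with frequencies drawn
#' uniformly from the configured range (or taken from a supplied SNP map).
#' Optional LD blocks copy a template SNP's dosages and resample a fraction of
#' individuals, giving tunable within-block correlation.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals (defaults to `config$n_exposure_sample`).
#' @param map Internal: a pre-drawn SNP map so that two samples share variants.
#' @param seed Seed; `NULL` continues the current RNG stream (used internally
#'   by [simulate_mr_study()]), otherwise defaults to `config$seed`.
#' @return A `geno_panel`: list with `dosages` (n x m integer matrix) and
#'   `snps` (tibble: snp, chr, bp, ea, oa, freq).
#' @export
simulate_genotypes <- function(config, n = config$n_exposure_sample,
                               map = NULL, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- .simulate_snp_map(config)
  m <- config$m_snps
  G <- matrix(rbinom(n * m, 2L, rep(map$freq, each = n)), n, m)
  if (!is.null(config$ld_blocks) && m > 0) {
    lb <- config$ld_blocks
    stopifnot(lb$n_blocks * lb$block_size <= m)
    for (b in seq_len(lb$n_blocks)) {
      first <- (b - 1L) * lb$block_size + 1L
      for (j in seq_len(lb$block_size - 1L)) {
        col <- first + j
        G[, col] <- G[, first]
        swap <- runif(n) < lb$swap_frac
        if (any(swap)) {
          G[swap, col] <- rbinom(sum(swap), 2L, map$freq[first])
        }
        map$freq[col] <- map$freq[first]
      }
    }
  }
  colnames(G) <- map$snp
  structure(list(dosages = G,
                 snps = tibble::tibble(snp = map$snp, chr = map$chr,
                                       bp = map$bp, ea = map$ea, oa = map$oa,
                                       freq = map$freq),
                 map = map),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat("<geno_panel> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " SNPs\n", sep = "")
  print(head(x$snps, 5))
  invisible(x)
}

.simulate_covariates <- function(n) {
  tibble::tibble(age = rnorm(n, 57, 8),
                 sex = rbinom(n, 1L, 0.54),
                 fasting_hours = pmax(rnorm(n, 4, 3), 0))
}

#' Simulate correlated standardised exposures
#'
#' Builds traits as genetic effects plus confounder, shared factor, covariate
#' and residual components (see [sim_config()]), then standardises each column
#' to mean 0, SD 1 exactly.
#'
#' @param panel A `geno_panel` from [simulate_genotypes()].
#' @param config The matching [sim_config()].
#' @param covariates Optional covariate tibble (defaults to a fresh draw).
#' @return An n x k numeric matrix of class `trait_matrix` with attributes
#'   `confounder` (the n-vector U), `covariates`, and `standardized = TRUE`.
#' @export
simulate_exposures <- function(panel, config, covariates = NULL) {
  A <- panel$map$A
  k <- config$k_traits
  if (!identical(dim(A), c(config$m_snps, k))) {
    abort("snp_effect_matrix dimensions do not match panel and k_traits")
  }
  n <- nrow(panel$dosages)
  Gc <- sweep(panel$dosages, 2, 2 * panel$map$freq)
  U <- rnorm(n)
  Fs <- rnorm(n)
  if (is.null(covariates)) covariates <- .simulate_covariates(n)
  X <- Gc %*% A + U %o% config$confounder_loadings +
    Fs %o% config$shared_factor_loadings
  if (!is.null(config$covariate_loadings)) {
    Cm <- scale(as.matrix(covariates))
    X <- X + Cm %*% t(config$covariate_loadings)
  }
  Psi <- config$resid_cov
  if (is.null(Psi)) {
    base_var <- diag(crossprod(X) / n)
    Psi <- diag(pmax(1 - base_var, 0.01), k)
  }
  X <- X + matrix(rnorm(n * k), n, k) %*% t(.msqrt(Psi))
  X <- scale(X)
  # scale() leaves mean ~1e-17; enforce the exact contract
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, apply(X, 2, sd), "/")
  colnames(X) <- config$trait_names
  structure(X, confounder = U, covariates = covariates,
            standardized = TRUE, class = c("trait_matrix", "matrix", "array"))
}

.pleiotropy_vector <- function(config, map) {
  m <- config$m_snps
  spec <- config$pleiotropy_spec
  delta <- numeric(m)
  idx <- if (length(map$causal)) map$causal else seq_len(m)
  if (spec$mode == "balanced") {
    delta[idx] <- rnorm(length(idx), 0, spec$sd)
  } else if (spec$mode == "directional") {
    delta[idx] <- rnorm(length(idx), spec$mean, spec$sd)
  } else if (spec$mode == "inside_violating") {
    a1 <- map$A[idx, 1]
    s <- sd(a1); if (!is.finite(s) || s == 0) s <- 1
    delta[idx] <- spec$mean + spec$sd * a1 / s
  }
  delta
}

#' Simulate a binary outcome with known causal structure
#'
#' Case status follows a logistic model in the standardised exposures (direct
#' effects `theta`), the shared confounder, and any direct SNP effects
#' (horizontal pleiotropy). The intercept is solved numerically so the
#' expected case fraction matches `config$outcome_prevalence`.
#'
#' @param panel,config As in [simulate_exposures()].
#' @param exposures The `trait_matrix` simulated from `panel`.
#' @return List with `status` (integer 0/1 n-vector) and `truth`, a
#'   `sim_truth` list carrying `theta`, `pleiotropy_vector` and the implied
#'   `total_effects` (genetic regression of the linear predictor on each
#'   single genetically predicted trait — the univariable MR estimand on the
#'   linear-predictor scale).
#' @export
simulate_outcome <- function(panel, exposures, config) {
  n <- nrow(panel$dosages)
  if (nrow(exposures) != n) abort("exposures do not match panel")
  theta <- config$true_direct_effects
  U <- attr(exposures, "confounder")
  delta <- .pleiotropy_vector(config, panel$map)
  Gc <- sweep(panel$dosages, 2, 2 * panel$map$freq)
  lp <- drop(exposures %*% theta) + config$confounder_outcome_loading * U +
    drop(Gc %*% delta)
  fr <- function(a) mean(plogis(a + lp)) - config$outcome_prevalence
  sol <- tryCatch(uniroot(fr, c(-30, 30), tol = 1e-10),
                  error = function(e) {
                    abort(paste0("target prevalence ",
                                 config$outcome_prevalence,
                                 " unreachable: ", conditionMessage(e)),
                          class = "lipidmr_config_error")
                  })
  status <- rbinom(n, 1L, plogis(sol$root + lp))
  Cg <- crossprod(panel$map$A, panel$map$A * (2 * panel$map$freq *
                                                (1 - panel$map$freq)))
  total <- if (all(diag(Cg) > 0)) drop(Cg %*% theta) / diag(Cg) else theta
  truth <- structure(list(theta = setNames(theta, config$trait_names),
                          pleiotropy_vector = delta,
                          total_effects = setNames(total, config$trait_names),
                          alpha = sol$root),
                     class = "sim_truth")
  list(status = status, truth = truth)
}

#' Simulate a complete two-sample MR study
#'
#' Draws a shared SNP map, two disjoint samples (sample 1: exposures; sample
#' 2: binary outcome), runs the per-SNP association scans (linear for each
#' inverse-rank-normalised trait in sample 1, logistic for case status in
#' sample 2), and returns full summary statistics for every trait together
#' with the LD matrix of the exposure panel and the generative truth.
#'
#' @param config A [sim_config()], e.g. from [lipid_preset()].
#' @param keep_individual Keep the individual-level data (needed by
#'   [run_sensitivity_suite()] to re-derive instruments with extra GWAS
#'   covariates). Default `TRUE`.
#' @param rank_normalise Inverse-rank-normalise traits before the exposure
#'   GWAS (the convention for lipid GWAS). Default `TRUE`.
#' @return An `mr_study` list: `exposure_stats` (named list of summary-stat
#'   tibbles over all SNPs), `outcome_stats`, `ld` (signed correlation matrix
#'   from sample 1), `truth`, `config`, and optionally `sample1`, `sample2`.
#' @export
simulate_mr_study <- function(config, keep_individual = TRUE,
                              rank_normalise = TRUE) {
  set.seed(config$seed)
  map <- .simulate_snp_map(config)
  p1 <- simulate_genotypes(config, n = config$n_exposure_sample,
                           map = map, seed = NULL)
  X <- simulate_exposures(p1, config)
  p2 <- simulate_genotypes(config, n = config$n_outcome_sample,
                           map = map, seed = NULL)
  X2 <- simulate_exposures(p2, config)
  out <- simulate_outcome(p2, X2, config)

  exposure_stats <- lapply(seq_len(config$k_traits), function(k) {
    y <- X[, k]
    if (rank_normalise) y <- inverse_rank_normalise(y)
    snp_association(p1, y, family = "linear",
                    trait_name = config$trait_names[k])
  })
  names(exposure_stats) <- config$trait_names
  outcome_stats <- snp_association(p2, out$status, family = "logistic",
                                   trait_name = "outcome")
  ld <- ld_matrix(p1)
  structure(list(exposure_stats = exposure_stats,
                 outcome_stats = outcome_stats,
                 ld = ld, truth = out$truth, config = config,
                 sample1 = if (keep_individual) {
                   list(panel = p1, exposures = X,
                        covariates = attr(X, "covariates"))
                 },
                 sample2 = if (keep_individual) {
                   list(panel = p2, status = out$status,
                        covariates = attr(X2, "covariates"))
                 }),
            class = "mr_study")
}

#' @export
print.mr_study <- function(x, ...) {
  cat("<mr_study> ", x$config$k_traits, " traits (",
      paste(x$config$trait_names, collapse = ", "), "), ",
      x$config$m_snps, " SNPs\n",
      "  sample 1 (exposures): n = ", x$config$n_exposure_sample, "\n",
      "  sample 2 (outcome):   n = ", x$config$n_outcome_sample,
      ", target case fraction ", x$config$outcome_prevalence, "\n",
      sep = "")
  invisible(x)
}
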