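#' Inverse rank-normalisation
#'
#' Maps values to normal quantiles via the Blom offset,
#' \eqn{\Phi^{-1}((r_i - 3/8)/(n + 1/4))}, with average ranks under ties, so
#' the transformed trait has mean ~0 and SD ~1 regardless of its original
#' distribution. Order is preserved; `NA`s stay `NA`.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' inverse_rank_normalise(c(3, 1, 2))
inverse_rank_normalise <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) abort("need at least 2 finite values")
  if (length(unique(x[ok])) < 2) {
    abort("all values identical: rank normalisation undefined")
  }
  r <- rank(x[ok], ties.method = "average")
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

.new_summary_stats <- function(snps, eaf, beta, se, log_p, n, trait,
                               info = 1) {
  p <- exp(pmax(log_p, log(.Machine$double.xmin)))
  tibble::tibble(snp = snps$snp, chr = snps$chr, bp = snps$bp,
                 ea = snps$ea, oa = snps$oa, eaf = unname(eaf),
                 beta = unname(beta), se = unname(se), p = unname(p),
                 log10_p = unname(log_p) / log(10),
                 n = as.integer(n), info = info, trait = trait)
}

#' Per-SNP association scan
#'
#' Regresses a trait on each SNP's dosage plus covariates and an intercept:
#' ordinary least squares for quantitative traits, maximum-likelihood
#' logistic regression for binary traits. The linear scan uses the
#' Frisch-Waugh-Lovell closed form (trait and dosages residualised on the
#' covariates), the logistic scan an IRLS loop in compiled code.
#'
#' Monomorphic SNPs are emitted with `beta = 0`, `se = Inf`, `p = 1` so that
#' downstream significance filters exclude them without aborting a pipeline;
#' non-convergent logistic fits are dropped with a warning.
#'
#' P-values are also carried as `log10_p` so that genome-wide-scale values
#' that underflow `p` still order correctly in clumping.
#'
#' @param panel A `geno_panel`.
#' @param trait Numeric vector (binary 0/1 for `family = "logistic"`) of
#'   length `nrow(panel$dosages)`.
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (an intercept is always added; must be full rank).
#' @param family `"linear"` or `"logistic"`.
#' @param trait_name Stored in the `trait` column.
#' @return A summary-statistics tibble: snp, chr, bp, ea, oa, eaf, beta, se,
#'   p, log10_p, n, info, trait. `eaf` is the column mean dosage / 2 exactly.
#' @export
snp_association <- function(panel, trait, covariates = NULL,
                            family = c("linear", "logistic"),
                            trait_name = "trait") {
  family <- match.arg(family)
  G <- panel$dosages
  n <- nrow(G)
  if (length(trait) != n) abort("trait length must equal panel n")
  C <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    C <- cbind(C, as.matrix(covariates))
  }
  qrC <- qr(C)
  # redundant (rank-deficient) covariate columns are harmless for the dosage
  # coefficient; project on the column space only
  eaf <- colMeans(G) / 2
  mono <- apply(G, 2, function(g) all(g == g[1]))

  if (family == "linear") {
    yr <- qr.resid(qrC, trait)
    Gr <- qr.resid(qrC, G)
    sxx <- colSums(Gr^2)
    df <- n - qrC$rank - 1L
    beta <- ifelse(sxx > 0, colSums(Gr * yr) / ifelse(sxx > 0, sxx, 1), 0)
    rss <- sum(yr^2) - beta^2 * sxx
    se <- ifelse(sxx > 0, sqrt(pmax(rss, 0) / df / ifelse(sxx > 0, sxx, 1)),
                 Inf)
    tval <- ifelse(is.finite(se) & se > 0, beta / se, 0)
    log_p <- log(2) + pt(-abs(tval), df, log.p = TRUE)
    log_p[mono] <- 0
    beta[mono] <- 0; se[mono] <- Inf
    out <- .new_summary_stats(panel$snps, eaf, beta, se, log_p, n, trait_name)
  } else {
    if (!all(trait %in% c(0, 1))) abort("logistic family needs a 0/1 trait")
    fit <- .logistic_scan_cpp(G, as.numeric(trait), C)
    beta <- fit[, 1]; se <- fit[, 2]
    conv <- fit[, 4] > 0 & !mono
    log_p <- log(2) + pnorm(-abs(fit[, 3]), log.p = TRUE)
    beta[mono] <- 0; se[mono] <- Inf; log_p[mono] <- 0
    out <- .new_summary_stats(panel$snps, eaf, beta, se, log_p, n, trait_name)
    bad <- !conv & !mono
    if (any(bad)) {
      warn(paste0("dropping ", sum(bad),
                  " SNP(s) with non-convergent logistic fit: ",
                  paste(head(out$snp[bad], 5), collapse = ", ")))
      out <- out[!bad, ]
    }
  }
  out
}

#' Genome-wide significance filter
#'
#' Keeps rows with p-value strictly below the threshold (the conventional
#' genome-wide level 5e-8 by default), preserving input order. Comparison is
#' done on the log scale so underflowed p-values filter correctly.
#'
#' @param stats Summary-statistics tibble.
#' @param threshold Strict upper bound on p.
#' @return Filtered tibble.
#' @export
filter_genome_wide <- function(stats, threshold = 5e-8) {
  lp <- .log10p(stats)
  stats[lp < log10(threshold), , drop = FALSE]
}

# log10 p, recomputed from beta/se (normal approximation) when the column is
# absent, e.g. after file round-trips
.log10p <- function(stats) {
  if ("log10_p" %in% names(stats)) return(stats$log10_p)
  (log(2) + pnorm(-abs(stats$beta / stats$se), log.p = TRUE)) / log(10)
}
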