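# Causal estimators on harmonised summary statistics: IVW, MR-Egger,
# weighted median, weighted mode, multivariable IVW / MR-Egger, and the
# instrument-strength diagnostics (mean F, conditional F).
#
# All Wald-type methods use multiplicative random-effects standard errors:
# the classical (fixed-effect) covariance is scaled by the weighted residual
# mean square, clipped at 1 so over-precision is never reported. P-values use
# the normal reference distribution.

new_mr_fit <- function(method, exposures, estimates, n_snps,
                       intercept = NULL, sigma = NA_real_, orient = NULL) {
  structure(list(method = method, exposures = exposures,
                 estimates = estimates, n_snps = n_snps,
                 intercept = intercept, sigma = sigma, orient = orient),
            class = "mr_fit")
}

.estimate_row <- function(exposure, beta, se) {
  tibble::tibble(exposure = exposure, beta = beta, se = se,
                 ci_lo = beta - Z975 * se, ci_hi = beta + Z975 * se,
                 p = 2 * pnorm(-abs(beta / ifelse(se > 0, se, Inf))))
}

.pick_exposure <- function(inp, exposure) {
  if (is.null(exposure)) return(1L)
  if (is.character(exposure)) {
    i <- match(exposure, inp$exposures)
    if (is.na(i)) abort(paste("unknown exposure:", exposure))
    return(i)
  }
  as.integer(exposure)
}

#' Per-SNP Wald ratio estimates
#'
#' The building block of the median and mode estimators: for SNP j,
#' `ratio = beta_outcome / beta_exposure` with first-order standard error
#' `se_outcome / abs(beta_exposure)`.
#'
#' @param dat An `mr_harmonised` tibble (or any data frame with
#'   `beta_<exposure>`, `se_<exposure>`, `beta_outcome`, `se_outcome`).
#' @param exposure Exposure name or index (default: first).
#' @return Tibble: snp, ratio, se.
#' @export
mr_ratio <- function(dat, exposure = NULL) {
  inp <- .mr_inputs(dat)
  k <- .pick_exposure(inp, exposure)
  bx <- inp$B[, k]
  if (any(bx == 0)) {
    abort(paste("zero exposure beta for SNP(s):",
                paste(inp$snps[bx == 0], collapse = ", ")))
  }
  tibble::tibble(snp = inp$snps, ratio = inp$b / bx,
                 se = inp$s / abs(bx))
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of the SNP-outcome associations on the SNP-exposure
#' associations with the intercept constrained at the origin and weights
#' equal to the inverse squared outcome standard errors:
#' \deqn{\hat\beta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} /
#'       \sum_j w_j \hat\beta_{Xj}^2,\quad w_j = s_{Yj}^{-2}.}
#' The standard error is the fixed-effect one inflated by the residual scale
#' when it exceeds 1 (multiplicative random effects). Equivalent to the
#' inverse-variance-weighted mean of Wald ratios with weights
#' `beta_x^2 / s_y^2`.
#'
#' @inheritParams mr_ratio
#' @return An `mr_fit`; see [tidy.mr_fit()].
#' @export
mr_ivw <- function(dat, exposure = NULL) {
  inp <- .mr_inputs(dat)
  k <- .pick_exposure(inp, exposure)
  bx <- inp$B[, k]; by <- inp$b; sy <- inp$s
  J <- length(bx)
  if (J < 1) abort("IVW requires at least 1 SNP")
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  sigma <- if (J > 1) {
    sqrt(max(1, sum(w * (by - beta * bx)^2) / (J - 1)))
  } else 1
  se <- sqrt(1 / sxx) * sigma
  new_mr_fit("ivw", inp$exposures[k], .estimate_row(inp$exposures[k],
                                                    beta, se),
             n_snps = J, sigma = sigma)
}

#' MR-Egger regression
#'
#' SNPs are first oriented so every exposure beta is non-negative (negating
#' both betas of a SNP leaves the Wald ratio unchanged, so this is a
#' canonicalisation, and it makes the intercept interpretable). A weighted
#' linear regression of outcome on exposure betas with a free intercept then
#' gives the causal slope and an intercept estimating average directional
#' pleiotropy; a nonzero intercept flags violation of the exclusion
#' restriction (under the InSIDE assumption).
#'
#' @inheritParams mr_ratio
#' @return An `mr_fit` with an `intercept` element
#'   (`estimate`, `se`, `p`).
#' @export
mr_egger <- function(dat, exposure = NULL) {
  inp <- .mr_inputs(dat)
  k <- .pick_exposure(inp, exposure)
  bx <- inp$B[, k]; by <- inp$b; sy <- inp$s
  J <- length(bx)
  if (J < 3) abort("MR-Egger requires at least 3 SNPs")
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, X * w)
  est <- solve(XtWX, crossprod(X, by * w))
  res <- by - X %*% est
  sigma <- sqrt(max(1, sum(w * res^2) / (J - 2)))
  V <- solve(XtWX) * sigma^2
  se <- sqrt(diag(V))
  new_mr_fit("egger", inp$exposures[k],
             .estimate_row(inp$exposures[k], est[2], se[2]),
             n_snps = J,
             intercept = list(estimate = est[1], se = se[1],
                              p = 2 * pnorm(-abs(est[1] / se[1]))),
             sigma = sigma)
}

# step-by-step weighted median of `x` with weights `w` (normalised):
# sort, take cumulative weight midpoints, interpolate x against them at 0.5
.weighted_median_est <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  pmid <- cumsum(w) - w / 2
  if (0.5 <= pmid[1]) return(x[1])
  if (0.5 >= pmid[length(pmid)]) return(x[length(x)])
  approx(pmid, x, xout = 0.5, ties = "ordered")$y
}

.parametric_boot <- function(inp, k, n_boot, seed, estimator) {
  ord <- order(inp$snps)  # canonical order: row permutations do not change draws
  bx <- inp$B[ord, k]; sx <- inp$S[ord, k]
  by <- inp$b[ord]; sy <- inp$s[ord]
  J <- length(bx)
  withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bxs <- rnorm(J, bx, sx)
      bys <- rnorm(J, by, sy)
      estimator(bxs, bys, sy)
    }, numeric(1))
  })
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance-weighted
#' median (weights `beta_x^2 / s_y^2`, the first-order inverse ratio
#' variance) by linear interpolation of ratio against cumulative weight
#' midpoints at 0.5. Consistent when at least half the weight comes from
#' valid instruments. The standard error is the SD of the estimate over
#' `n_boot` parametric resamples of the summary statistics, so it is
#' reproducible under `seed`.
#'
#' @inheritParams mr_ratio
#' @param n_boot Parametric bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (local; does not touch the session RNG).
#' @return An `mr_fit`.
#' @export
mr_weighted_median <- function(dat, exposure = NULL, n_boot = 1000,
                               seed = 1L) {
  inp <- .mr_inputs(dat)
  k <- .pick_exposure(inp, exposure)
  bx <- inp$B[, k]
  J <- length(bx)
  if (J < 3) abort("weighted median requires at least 3 SNPs")
  est_fun <- function(bx, by, sy) {
    ok <- bx != 0  # a resample can push a weak beta through zero
    .weighted_median_est(by[ok] / bx[ok], bx[ok]^2 / sy[ok]^2)
  }
  beta <- est_fun(bx, inp$b, inp$s)
  se <- sd(.parametric_boot(inp, k, n_boot, seed, est_fun))
  new_mr_fit("weighted_median", inp$exposures[k],
             .estimate_row(inp$exposures[k], beta, se), n_snps = J)
}

# mode of a weighted normal-kernel density over ratios, argmax on a fixed
# 512-point grid spanning [min - 3h, max + 3h]
.weighted_mode_est <- function(ratio, w, phi = 1, grid_n = 512L) {
  s <- sd(ratio)
  h <- phi * 0.9 * min(s, IQR(ratio) / 1.349) * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratio[1])  # all ratios identical
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- exp(-(outer(grid, ratio, "-") / h)^2 / 2) %*% w
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' Estimates the causal effect as the mode of the weighted kernel density of
#' per-SNP Wald ratios (normal kernel, modified Silverman bandwidth
#' `phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`, argmax on a fixed 512-point
#' grid). Consistent when the largest group of SNPs sharing a ratio value
#' are valid instruments (zero modal pleiotropy). Bootstrap SE as in
#' [mr_weighted_median()]. When all ratios coincide the estimate is the
#' common ratio with SE 0.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @return An `mr_fit`.
#' @export
mr_weighted_mode <- function(dat, exposure = NULL, phi = 1, n_boot = 1000,
                             seed = 1L) {
  inp <- .mr_inputs(dat)
  k <- .pick_exposure(inp, exposure)
  bx <- inp$B[, k]
  J <- length(bx)
  if (J < 3) abort("weighted mode requires at least 3 SNPs")
  ratio <- inp$b / bx
  w <- bx^2 / inp$s^2
  w <- w / sum(w)
  if (length(unique(ratio)) == 1) {
    return(new_mr_fit("weighted_mode", inp$exposures[k],
                      .estimate_row(inp$exposures[k], ratio[1], 0),
                      n_snps = J))
  }
  beta <- .weighted_mode_est(ratio, w, phi)
  est_fun <- function(bx, by, sy) {
    ok <- bx != 0
    wi <- bx[ok]^2 / sy[ok]^2
    .weighted_mode_est(by[ok] / bx[ok], wi / sum(wi), phi)
  }
  se <- sd(.parametric_boot(inp, k, n_boot, seed, est_fun))
  new_mr_fit("weighted_mode", inp$exposures[k],
             .estimate_row(inp$exposures[k], beta, se), n_snps = J)
}

#' Multivariable IVW estimator
#'
#' Weighted multiple regression (no intercept) of the SNP-outcome betas on
#' the matrix of SNP-exposure betas, weights `1/s_y^2`. Each coefficient is
#' the *direct* effect of that exposure: the effect not mediated or
#' confounded by the other exposures in the model. Requires more SNPs than
#' exposures and a full-column-rank exposure matrix.
#'
#' @param dat An `mr_harmonised` tibble.
#' @param exposures Character vector (default: all exposures in `dat`).
#' @return An `mr_fit` with one estimate row per exposure.
#' @export
mvmr_ivw <- function(dat, exposures = NULL) {
  inp <- .mr_inputs(dat, exposures)
  B <- inp$B; b <- inp$b; w <- 1 / inp$s^2
  J <- nrow(B); K <- ncol(B)
  if (J < K + 1) abort("multivariable IVW requires J >= K + 1 SNPs")
  if (qr(B)$rank < K) {
    abort(paste("exposure beta matrix is rank deficient; collinear",
                "exposures:", paste(inp$exposures, collapse = ", ")))
  }
  XtWX <- crossprod(B, B * w)
  est <- unname(drop(solve(XtWX, crossprod(B, b * w))))
  res <- b - drop(B %*% est)
  sigma <- sqrt(max(1, sum(w * res^2) / (J - K)))
  se <- unname(sqrt(diag(solve(XtWX)))) * sigma
  new_mr_fit("mvmr_ivw", inp$exposures,
             .estimate_row(inp$exposures, est, se), n_snps = J,
             sigma = sigma)
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] but with a free intercept estimating directional
#' pleiotropy. SNPs are first oriented so the chosen exposure's betas are
#' non-negative, negating the SNP's entire row (all exposure betas and the
#' outcome beta together), which leaves every slope invariant and
#' canonicalises the intercept.
#'
#' @inheritParams mvmr_ivw
#' @param orient Exposure (name or index) whose betas define the row
#'   orientation; default the first exposure in the model.
#' @return An `mr_fit` with per-exposure slopes and an `intercept` element.
#' @export
mvmr_egger <- function(dat, exposures = NULL, orient = NULL) {
  inp <- .mr_inputs(dat, exposures)
  B <- inp$B; b <- inp$b; w <- 1 / inp$s^2
  J <- nrow(B); K <- ncol(B)
  if (J < K + 2) abort("multivariable MR-Egger requires J >= K + 2 SNPs")
  ko <- .pick_exposure(inp, orient)
  flip <- B[, ko] < 0
  B[flip, ] <- -B[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  X <- cbind(`(intercept)` = 1, B)
  if (qr(X)$rank < K + 1) {
    abort(paste("exposure beta matrix is rank deficient; collinear",
                "exposures:", paste(inp$exposures, collapse = ", ")))
  }
  XtWX <- crossprod(X, X * w)
  est <- unname(drop(solve(XtWX, crossprod(X, b * w))))
  res <- b - drop(X %*% est)
  sigma <- sqrt(max(1, sum(w * res^2) / (J - K - 1)))
  se <- unname(sqrt(diag(solve(XtWX)))) * sigma
  new_mr_fit("mvmr_egger", inp$exposures,
             .estimate_row(inp$exposures, est[-1], se[-1]), n_snps = J,
             intercept = list(estimate = est[1], se = se[1],
                              p = 2 * pnorm(-abs(est[1] / se[1]))),
             sigma = sigma, orient = inp$exposures[ko])
}

#' Mean F-statistic of a genetic instrument
#'
#' The Bowden approximation from summary statistics: the mean of the squared
#' per-SNP z-statistics, `mean((beta/se)^2)`, over the instrument SNPs.
#' Values well above 10 indicate that weak-instrument bias is unlikely to be
#' material.
#'
#' @param stats Summary-statistics tibble (the clumped instrument rows).
#' @return A single number.
#' @export
mean_f_statistic <- function(stats) {
  if (nrow(stats) == 0) abort("no SNPs: mean F undefined")
  if (any(stats$se <= 0)) abort("standard errors must be positive")
  mean((stats$beta / stats$se)^2)
}

#' Conditional F-statistics for multivariable MR
#'
#' Instrument strength for each exposure given the others, from summary data:
#' for exposure k, regress its betas on the other exposures' betas (weights
#' `1/se_k^2`, no intercept), accumulate the weighted residual sum of squares
#' `Q_k`, and report `Q_k / (L - K + 1)` (the Sanderson-Windmeijer Q form).
#' Low values (roughly below 10) signal that the exposure's instruments carry
#' little signal independent of the other exposures.
#'
#' @inheritParams mvmr_ivw
#' @return Tibble: exposure, conditional_f; attributes `L` (SNPs) and `K`.
#' @export
conditional_f_statistics <- function(dat, exposures = NULL) {
  inp <- .mr_inputs(dat, exposures)
  B <- inp$B; S <- inp$S
  L <- nrow(B); K <- ncol(B)
  if (K < 2) abort("conditional F requires at least 2 exposures")
  if (L <= K) abort("conditional F requires more SNPs than exposures")
  cf <- vapply(seq_len(K), function(k) {
    wk <- 1 / S[, k]^2
    # weighted projection via QR so degenerate predictor sets (e.g. all-zero
    # betas for the other exposures) reduce to fitted values of zero
    Bw <- B[, -k, drop = FALSE] * sqrt(wk)
    yw <- B[, k] * sqrt(wk)
    qq <- qr(Bw)
    fitted <- if (qq$rank == 0) 0 else qr.fitted(qq, yw, k = qq$rank)
    Q <- sum((yw - fitted)^2)
    Q / (L - K + 1)
  }, numeric(1))
  out <- tibble::tibble(exposure = inp$exposures, conditional_f = cf)
  attr(out, "L") <- L; attr(out, "K") <- K
  out
}
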