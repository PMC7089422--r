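# broom-style accessors and plots for mr_fit objects and results tables.

#' Tidy an MR fit
#'
#' One row per exposure with the estimate on the log-odds scale, its 95%
#' Wald interval, p-value and the odds-ratio scale columns.
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return Tibble: method, exposure, n_snps, beta, se, ci_lo, ci_hi, p,
#'   or, or_lo, or_hi.
#' @export
tidy.mr_fit <- function(x, ...) {
  out <- dplyr::mutate(x$estimates, method = x$method,
                       n_snps = x$n_snps, .before = 1)
  to_odds_ratio(out)
}

#' Method-level summary of an MR fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return One-row tibble: method, n_snps, residual_scale (the multiplicative
#'   overdispersion factor actually applied, `NA` for bootstrap-based
#'   methods), egger_intercept, egger_intercept_se, egger_intercept_p.
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n_snps = x$n_snps,
                 residual_scale = x$sigma,
                 egger_intercept = x$intercept$estimate %||% NA_real_,
                 egger_intercept_se = x$intercept$se %||% NA_real_,
                 egger_intercept_p = x$intercept$p %||% NA_real_)
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("<mr_fit> ", x$method, " (", x$n_snps, " SNPs)\n", sep = "")
  print(tidy(x))
  if (!is.null(x$intercept)) {
    cat(sprintf("intercept %.4g (se %.3g, p %.3g)\n",
                x$intercept$estimate, x$intercept$se, x$intercept$p))
  }
  invisible(x)
}

#' Add odds-ratio scale columns
#'
#' For any table with `beta` and `se` columns (log-odds per 1-SD exposure)
#' adds `or = exp(beta)` and the 95% interval
#' `exp(beta -/+ 1.959964 * se)`. A zero SE gives a degenerate interval equal
#' to the point estimate.
#'
#' @param x A data frame with `beta` and `se`, or an `mr_fit`.
#' @return The input with `or`, `or_lo`, `or_hi` columns (an `mr_fit` is
#'   tidied first).
#' @export
to_odds_ratio <- function(x) {
  if (inherits(x, "mr_fit")) return(tidy(x))
  dplyr::mutate(x, or = exp(.data$beta),
                or_lo = exp(.data$beta - Z975 * .data$se),
                or_hi = exp(.data$beta + Z975 * .data$se))
}

#' Scatter plot of an MR fit
#'
#' SNP-outcome against SNP-exposure associations with the fitted line
#' (through the origin for IVW; with intercept for Egger, after orientation).
#'
#' @param object An `mr_fit` from a univariable estimator.
#' @param dat The harmonised data the fit was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_fit <- function(object, dat, ...) {
  inp <- .mr_inputs(dat)
  k <- match(object$exposures[1], inp$exposures)
  df <- tibble::tibble(bx = inp$B[, k], by = inp$b, sy = inp$s)
  if (object$method %in% c("egger", "mvmr_egger")) {
    flip <- df$bx < 0
    df$bx[flip] <- -df$bx[flip]; df$by[flip] <- -df$by[flip]
  }
  icpt <- object$intercept$estimate %||% 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - Z975 * .data$sy,
                                        ymax = .data$by + Z975 * .data$sy),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(intercept = icpt,
                         slope = object$estimates$beta[1],
                         colour = "firebrick") +
    ggplot2::labs(x = paste("SNP effect on", object$exposures[1]),
                  y = "SNP effect on outcome (log-odds)",
                  title = paste0(object$method, " (", object$n_snps,
                                 " SNPs)")) +
    ggplot2::theme_minimal()
}

#' Forest plot of MR results
#'
#' Odds ratios per 1-SD higher genetically instrumented trait, one row per
#' exposure-method estimate, on a log x-scale.
#'
#' @param results A tidy results table (e.g. from [run_univariable_suite()]
#'   or [tidy.mr_fit()]) with columns exposure, method, or, or_lo, or_hi.
#' @return A ggplot.
#' @export
plot_forest <- function(results) {
  stopifnot(all(c("exposure", "method", "or", "or_lo", "or_hi") %in%
                  names(results)))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$or, y = .data$exposure,
                               colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_lo,
                                          xmax = .data$or_hi),
                             position = ggplot2::position_dodge(width = 0.5),
                             fatten = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR of outcome per 1-SD higher trait", y = NULL) +
    ggplot2::theme_minimal()
}
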