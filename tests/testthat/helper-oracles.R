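# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different machinery than the implementation
# (lm/glm fits, literal step-by-step simulations of stated rules).

# weighted least squares through the origin via lm
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  fit <- lm(by ~ 0 + bx, weights = w)
  s2 <- sum(w * residuals(fit)^2) / (length(bx) - 1)
  se_fe <- sqrt(1 / sum(w * bx^2))
  list(beta = unname(coef(fit)), se = se_fe * sqrt(max(1, s2)))
}

oracle_mvmr <- function(B, by, sy) {
  w <- 1 / sy^2
  fit <- lm(by ~ 0 + B, weights = w)
  s2 <- sum(w * residuals(fit)^2) / (nrow(B) - ncol(B))
  V <- solve(t(B) %*% (B * w))
  list(beta = unname(coef(fit)), se = sqrt(diag(V) * max(1, s2)))
}

oracle_egger <- function(bx, by, sy) {
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  w <- 1 / sy^2
  fit <- lm(by ~ bx, weights = w)
  s2 <- sum(w * residuals(fit)^2) / (length(bx) - 2)
  X <- cbind(1, bx)
  V <- solve(t(X) %*% (X * w)) * max(1, s2)
  list(intercept = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
       se = sqrt(diag(V)))
}

# literal reading of the weighted-median definition
oracle_weighted_median <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(ratio[1])
  if (0.5 >= p[length(p)]) return(ratio[length(ratio)])
  below <- max(which(p < 0.5)); above <- below + 1
  ratio[below] + (ratio[above] - ratio[below]) *
    (0.5 - p[below]) / (p[above] - p[below])
}

# grid argmax of the weighted normal-kernel density, written independently
oracle_weighted_mode <- function(ratio, w, phi = 1) {
  w <- w / sum(w)
  h <- phi * 0.9 * min(sd(ratio), IQR(ratio) / 1.349) * length(ratio)^(-0.2)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, ratio, h) * h), 0)
  grid[which.max(dens)]
}

# step-by-step simulation of the stated greedy clumping rule
oracle_clump <- function(snp, chr, log10_p, beta, ld, r2) {
  remaining <- order(log10_p, -abs(beta), snp)
  keep <- integer(0)
  while (length(remaining)) {
    best <- remaining[1]
    keep <- c(keep, best)
    remaining <- remaining[-1]
    if (length(remaining)) {
      kill <- vapply(remaining, function(j) {
        chr[j] == chr[best] && ld[snp[best], snp[j]]^2 >= r2
      }, TRUE)
      remaining <- remaining[!kill]
    }
  }
  snp[keep]
}

# minimal summary-stats tibble for hand-built instances
make_stats <- function(snp, beta, se, chr = 1L, bp = seq_along(snp) * 1e5,
                       ea = "A", oa = "G", eaf = 0.3, n = 1000,
                       trait = "x", p = NULL) {
  p <- p %||% (2 * pnorm(-abs(beta / se)))
  tibble::tibble(snp = snp, chr = chr, bp = as.integer(bp), ea = ea, oa = oa,
                 eaf = eaf, beta = beta, se = se, p = p,
                 log10_p = log10(p), n = as.integer(n), info = 1,
                 trait = trait)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built harmonised tibble for estimator tests
make_harmonised <- function(B, S, b, s, snps = paste0("rs", seq_len(nrow(B))),
                            exposures = paste0("X", seq_len(ncol(B)))) {
  out <- tibble::tibble(snp = snps)
  for (k in seq_len(ncol(B))) {
    out[[paste0("beta_", exposures[k])]] <- B[, k]
    out[[paste0("se_", exposures[k])]] <- S[, k]
  }
  out$beta_outcome <- b
  out$se_outcome <- s
  structure(out, exposures = exposures,
            class = c("mr_harmonised", class(out)))
}

# small lipid-preset study used by several files (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- lipid_preset(traits = c("apoB", "LDL", "TG"),
                          n_exposure_sample = 4000, n_outcome_sample = 4000,
                          m_snps = 60, n_causal = 20, seed = 11)
      cache <<- simulate_mr_study(cfg)
    }
    cache
  }
})
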