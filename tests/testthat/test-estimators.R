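# Causal estimators and instrument-strength diagnostics.

test_that("Wald ratios follow the first-order formulas", {
  H <- make_harmonised(B = cbind(c(0.2, -0.2)), S = cbind(c(0.02, 0.02)),
                       b = c(0.1, 0.1), s = c(0.05, 0.05))
  r <- mr_ratio(H)
  expect_equal(r$ratio, c(0.5, -0.5))  # negating beta_x flips the sign
  expect_equal(r$se, c(0.25, 0.25))

  H0 <- make_harmonised(B = cbind(c(0.2, 0)), S = cbind(c(0.02, 0.02)),
                        b = c(0.1, 0.1), s = c(0.05, 0.05))
  expect_error(mr_ratio(H0), "rs2")
})

test_that("IVW reduces to the Wald ratio for one SNP and fits exact lines", {
  H1 <- make_harmonised(B = cbind(0.2), S = cbind(0.02), b = 0.1, s = 0.05)
  f1 <- mr_ivw(H1)
  expect_equal(f1$estimates$beta, 0.5)
  expect_equal(f1$estimates$se, 0.25)

  bx <- c(0.1, 0.2, 0.3)
  Hline <- make_harmonised(B = cbind(bx), S = cbind(rep(0.01, 3)),
                           b = 0.4 * bx, s = c(0.01, 0.02, 0.015))
  fl <- mr_ivw(Hline)
  expect_equal(fl$estimates$beta, 0.4, tolerance = 1e-12)
  expect_equal(fl$sigma, 1)  # dispersion clipped at the fixed-effect floor
  expect_equal(fl$estimates$se, sqrt(1 / sum(bx^2 / c(0.01, 0.02, 0.015)^2)))
})

test_that("IVW and MVMR-IVW match weighted-least-squares oracles", {
  # the fixed 3-SNP instance
  H3 <- make_harmonised(B = cbind(c(0.10, 0.20, 0.15)),
                        S = cbind(rep(0.01, 3)),
                        b = c(0.06, 0.11, 0.09), s = c(0.01, 0.02, 0.015))
  got <- mr_ivw(H3)
  want <- oracle_ivw(c(0.10, 0.20, 0.15), c(0.06, 0.11, 0.09),
                     c(0.01, 0.02, 0.015))
  expect_equal(got$estimates$beta, want$beta, tolerance = 1e-10)
  expect_equal(got$estimates$se, want$se, tolerance = 1e-10)

  # random instances, univariable and multivariable
  set.seed(67)
  for (i in 1:30) {
    J <- sample(5:15, 1); K <- sample(1:3, 1)
    B <- matrix(rnorm(J * K, 0, 0.1), J, K)
    S <- matrix(runif(J * K, 0.005, 0.02), J, K)
    b <- rnorm(J, 0, 0.05); s <- runif(J, 0.01, 0.08)
    H <- make_harmonised(B, S, b, s)
    gm <- mvmr_ivw(H)
    wm <- oracle_mvmr(B, b, s)
    expect_equal(gm$estimates$beta, wm$beta, tolerance = 1e-10)
    expect_equal(gm$estimates$se, wm$se, tolerance = 1e-10)
    gu <- mr_ivw(H, 1)
    wu <- oracle_ivw(B[, 1], b, s)
    expect_equal(gu$estimates$beta, wu$beta, tolerance = 1e-10)
    # algebraic identity: IVW is the weighted mean of Wald ratios
    wr <- B[, 1]^2 / s^2
    expect_equal(gu$estimates$beta, sum(wr * (b / B[, 1])) / sum(wr),
                 tolerance = 1e-10)
  }
  expect_error(mvmr_ivw(make_harmonised(cbind(c(1, 2), c(2, 4)),
                                        matrix(0.01, 2, 2),
                                        c(1, 2), c(0.1, 0.1))),
               "J >= K")
  Bc <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(mvmr_ivw(make_harmonised(Bc, matrix(0.01, 4, 2),
                                        rnorm(4), rep(0.1, 4))),
               "rank deficient")
})

test_that("MVMR-IVW with one exposure equals univariable IVW", {
  set.seed(71)
  H <- make_harmonised(B = cbind(rnorm(8, 0, 0.1)),
                       S = cbind(runif(8, 0.005, 0.02)),
                       b = rnorm(8, 0, 0.05), s = runif(8, 0.01, 0.05))
  expect_equal(mvmr_ivw(H)$estimates$beta, mr_ivw(H)$estimates$beta,
               tolerance = 1e-12)
  expect_equal(mvmr_ivw(H)$estimates$se, mr_ivw(H)$estimates$se,
               tolerance = 1e-12)
})

test_that("MR-Egger recovers exact affine structure and canonicalises", {
  bx <- c(0.1, 0.2, 0.3, 0.15)
  H <- make_harmonised(B = cbind(bx), S = cbind(rep(0.01, 4)),
                       b = 0.02 + 0.5 * bx, s = rep(0.02, 4))
  f <- mr_egger(H)
  expect_equal(f$intercept$estimate, 0.02, tolerance = 1e-10)
  expect_equal(f$estimates$beta, 0.5, tolerance = 1e-10)

  # negating both betas of one SNP is absorbed by orientation
  H2 <- make_harmonised(B = cbind(c(-0.1, 0.2, 0.3, 0.15)),
                        S = cbind(rep(0.01, 4)),
                        b = c(-(0.02 + 0.05), 0.02 + 0.5 * c(0.2, 0.3, 0.15)),
                        s = rep(0.02, 4))
  f2 <- mr_egger(H2)
  expect_equal(f2$estimates$beta, f$estimates$beta, tolerance = 1e-12)
  expect_equal(f2$intercept$estimate, f$intercept$estimate,
               tolerance = 1e-12)

  # oracle agreement on a random instance
  set.seed(73)
  bx <- rnorm(10, 0, 0.1); by <- rnorm(10, 0, 0.05); sy <- runif(10, 0.01, 0.05)
  g <- mr_egger(make_harmonised(cbind(bx), cbind(rep(0.01, 10)), by, sy))
  w <- oracle_egger(bx, by, sy)
  expect_equal(g$estimates$beta, w$beta, tolerance = 1e-10)
  expect_equal(g$intercept$estimate, w$intercept, tolerance = 1e-10)
  expect_equal(unname(c(g$intercept$se, g$estimates$se)), unname(w$se),
               tolerance = 1e-10)

  expect_error(mr_egger(make_harmonised(cbind(c(1, 2)), cbind(c(0.1, 0.1)),
                                        c(1, 2), c(0.1, 0.1))),
               "at least 3")
})

test_that("weighted median interpolates cumulative weight midpoints", {
  # equal weights, ratios {0.1, 0.5, 0.9}: the middle ratio
  H <- make_harmonised(B = cbind(rep(1, 3)), S = cbind(rep(0.01, 3)),
                       b = c(0.1, 0.5, 0.9), s = rep(1, 3))
  expect_equal(mr_weighted_median(H, n_boot = 10)$estimates$beta, 0.5)

  # an overwhelmingly weighted SNP dominates (deviation ~ half its
  # complementary weight times the ratio gap)
  Hd <- make_harmonised(B = cbind(c(1, 1, 1)), S = cbind(rep(0.01, 3)),
                        b = c(0.3, 0.8, 0.9), s = c(0.001, 1, 1))
  expect_lt(abs(mr_weighted_median(Hd, n_boot = 10)$estimates$beta - 0.3),
            1e-5)

  # 5-SNP instance against the step-by-step oracle
  set.seed(79)
  for (i in 1:20) {
    bx <- runif(5, 0.05, 0.3); by <- rnorm(5, 0.1, 0.1)
    sy <- runif(5, 0.02, 0.2)
    H5 <- make_harmonised(cbind(bx), cbind(rep(0.01, 5)), by, sy)
    got <- mr_weighted_median(H5, n_boot = 2)$estimates$beta
    want <- oracle_weighted_median(by / bx, bx^2 / sy^2)
    expect_equal(got, want, tolerance = 1e-12)
    # always inside the ratio range
    expect_gte(got, min(by / bx)); expect_lte(got, max(by / bx))
  }

  # bootstrap SE reproducible under a fixed seed
  se1 <- mr_weighted_median(H, n_boot = 50, seed = 5)$estimates$se
  se2 <- mr_weighted_median(H, n_boot = 50, seed = 5)$estimates$se
  expect_identical(se1, se2)
})

test_that("weighted mode finds the dominant ratio cluster", {
  # degenerate: all ratios equal
  H0 <- make_harmonised(B = cbind(rep(2, 3)), S = cbind(rep(0.01, 3)),
                        b = rep(0.6, 3), s = rep(0.05, 3))
  f0 <- mr_weighted_mode(H0, n_boot = 5)
  expect_equal(f0$estimates$beta, 0.3)
  expect_identical(f0$estimates$se, 0)

  # bimodal: 7 high-weight SNPs near 0.5, 3 near 1.5
  set.seed(83)
  ratios <- c(rnorm(7, 0.5, 0.02), rnorm(3, 1.5, 0.02))
  bx <- rep(1, 10)
  sy <- c(rep(0.05, 7), rep(0.2, 3))  # weight = 1/sy^2
  Hb <- make_harmonised(cbind(bx), cbind(rep(0.01, 10)), ratios, sy)
  fb <- mr_weighted_mode(Hb, n_boot = 5)
  expect_lt(abs(fb$estimates$beta - 0.5), 0.1)
  w <- bx^2 / sy^2
  expect_equal(fb$estimates$beta,
               oracle_weighted_mode(ratios, w / sum(w)), tolerance = 1e-12)

  # a dominant-weight SNP pins the mode near its ratio
  Hd <- make_harmonised(cbind(rep(1, 4)), cbind(rep(0.01, 4)),
                        c(0.3, 1, 1.4, 2), c(0.005, 1, 1, 1))
  expect_lt(abs(mr_weighted_mode(Hd, n_boot = 5)$estimates$beta - 0.3), 0.05)
})

test_that("MVMR-Egger recovers affine structure and ignores row signs", {
  set.seed(89)
  B <- matrix(rnorm(12 * 2, 0, 0.2), 12, 2)
  B[, 1] <- abs(B[, 1])  # oriented
  b <- 0.02 + 0.6 * B[, 1] - 0.1 * B[, 2]
  H <- make_harmonised(B, matrix(0.01, 12, 2), b, rep(0.03, 12))
  f <- mvmr_egger(H)
  expect_equal(f$intercept$estimate, 0.02, tolerance = 1e-10)
  expect_equal(f$estimates$beta, c(0.6, -0.1), tolerance = 1e-10)

  # arbitrary row negations are undone by orientation
  flip <- c(1, 3, 5, 8)
  B2 <- B; B2[flip, ] <- -B2[flip, ]
  b2 <- b; b2[flip] <- -b2[flip]
  f2 <- mvmr_egger(make_harmonised(B2, matrix(0.01, 12, 2), b2,
                                   rep(0.03, 12)))
  expect_equal(f2$estimates$beta, f$estimates$beta, tolerance = 1e-12)
  expect_equal(f2$intercept$estimate, f$intercept$estimate,
               tolerance = 1e-12)

  expect_error(mvmr_egger(make_harmonised(B[1:3, ], matrix(0.01, 3, 2),
                                          b[1:3], rep(0.03, 3))),
               "J >= K")
})

test_that("mean F and conditional F follow their defining formulas", {
  st1 <- make_stats("rs1", beta = 1, se = 0.1)   # z = 10
  expect_equal(mean_f_statistic(st1), 100)
  st2 <- make_stats(c("rs1", "rs2"), beta = c(1, 2), se = c(0.1, 0.1))
  expect_equal(mean_f_statistic(st2), 250)
  expect_error(mean_f_statistic(st2[0, ]), "no SNPs")

  # other exposures' betas all zero: conditional F = mean F * L / (L - K + 1)
  set.seed(97)
  L <- 10
  b1 <- rnorm(L, 0, 0.2); s1 <- runif(L, 0.01, 0.05)
  H <- make_harmonised(cbind(b1, rep(0, L)),
                       cbind(s1, runif(L, 0.01, 0.05)),
                       rnorm(L), runif(L, 0.02, 0.08))
  cf <- conditional_f_statistics(H)
  mf <- mean((b1 / s1)^2)
  expect_equal(cf$conditional_f[1], mf * L / (L - 2 + 1), tolerance = 1e-10)

  # exact linear dependence: conditional F collapses to zero
  B <- cbind(b1, 0.5 * b1)
  Hc <- make_harmonised(B, cbind(s1, s1), rnorm(L), runif(L, 0.02, 0.08))
  cfc <- conditional_f_statistics(Hc)
  expect_lt(cfc$conditional_f[1], 1e-16)
  expect_lt(cfc$conditional_f[2], 1e-16)

  expect_error(conditional_f_statistics(
    make_harmonised(B[1:2, ], cbind(s1, s1)[1:2, ], rnorm(2), rep(0.1, 2))),
    "more SNPs")
})

test_that("estimators are permutation-invariant and scale-equivariant", {
  set.seed(101)
  J <- 9
  B <- matrix(rnorm(J * 2, 0, 0.15), J, 2)
  S <- matrix(runif(J * 2, 0.005, 0.02), J, 2)
  b <- rnorm(J, 0, 0.05); s <- runif(J, 0.02, 0.06)
  H <- make_harmonised(B, S, b, s)
  perm <- sample(J)
  Hp <- make_harmonised(B[perm, ], S[perm, ], b[perm], s[perm],
                        snps = paste0("rs", seq_len(J))[perm])
  for (fit in list(mr_ivw, mr_egger,
                   function(d) mr_weighted_median(d, n_boot = 30, seed = 2),
                   function(d) mr_weighted_mode(d, n_boot = 30, seed = 2),
                   mvmr_ivw, mvmr_egger)) {
    expect_equal(fit(H)$estimates$beta, fit(Hp)$estimates$beta,
                 tolerance = 1e-12)
  }
  # bootstrap SEs are also invariant thanks to canonical draw order
  expect_equal(mr_weighted_median(H, n_boot = 30, seed = 2)$estimates$se,
               mr_weighted_median(Hp, n_boot = 30, seed = 2)$estimates$se,
               tolerance = 1e-12)

  cc <- 2.5  # rescale exposure betas: estimates divide by the same factor
  Hs <- make_harmonised(B * cc, S * cc, b, s)
  expect_equal(mvmr_ivw(Hs)$estimates$beta, mvmr_ivw(H)$estimates$beta / cc,
               tolerance = 1e-10)
  expect_equal(mr_ivw(Hs)$estimates$beta, mr_ivw(H)$estimates$beta / cc,
               tolerance = 1e-10)
  expect_equal(mr_weighted_mode(Hs, n_boot = 2)$estimates$beta,
               mr_weighted_mode(H, n_boot = 2)$estimates$beta / cc,
               tolerance = 1e-10)
})

test_that("odds-ratio conversion and tidiers expose the fit", {
  H <- make_harmonised(B = cbind(c(0.1, 0.2, 0.15)),
                       S = cbind(rep(0.01, 3)),
                       b = c(0.06, 0.11, 0.09), s = c(0.01, 0.02, 0.015))
  f <- mr_ivw(H)
  td <- tidy(f)
  expect_equal(td$or, exp(td$beta))
  expect_equal(td$or_lo, exp(td$beta - 1.959964 * td$se))
  expect_equal(td$ci_hi, td$beta + 1.959964 * td$se)

  zero <- to_odds_ratio(tibble::tibble(beta = 0, se = 0.1))
  expect_equal(zero$or, 1)
  ln166 <- to_odds_ratio(tibble::tibble(beta = log(1.66), se = 0.1))
  expect_equal(ln166$or, 1.66)
  deg <- to_odds_ratio(tibble::tibble(beta = 0.5, se = 0))
  expect_equal(deg$or_lo, deg$or)
  expect_equal(deg$or_hi, deg$or)

  g <- glance(f)
  expect_identical(g$n_snps, 3L)
  expect_true(is.na(g$egger_intercept))
  ge <- glance(mr_egger(H))
  expect_false(is.na(ge$egger_intercept))
})
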