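# Allele alignment, proxy substitution and multivariable harmonisation.

row_of <- function(ea, oa, beta = 0.1, eaf = 0.3, se = 0.01, snp = "rs1") {
  tibble::tibble(snp = snp, ea = ea, oa = oa, beta = beta, eaf = eaf,
                 se = se)
}

test_that("allele alignment covers direct, swapped, strand and drops", {
  ex <- row_of("A", "G", beta = 0.2, eaf = 0.3)

  al <- align_alleles(ex, row_of("A", "G", beta = 0.15, eaf = 0.31))
  expect_identical(al$action, "direct")
  expect_equal(al$outcome_row$beta, 0.15)

  al <- align_alleles(ex, row_of("G", "A", beta = 0.15, eaf = 0.69))
  expect_identical(al$action, "flipped")
  expect_equal(al$outcome_row$beta, -0.15)
  expect_equal(al$outcome_row$eaf, 0.31)

  # strand complement: T/C reported, complement is A/G
  al <- align_alleles(ex, row_of("T", "C", beta = 0.15, eaf = 0.3))
  expect_identical(al$action, "strand_flipped")
  expect_equal(al$outcome_row$beta, 0.15)

  # complement then swap
  al <- align_alleles(ex, row_of("C", "T", beta = 0.15, eaf = 0.7))
  expect_identical(al$action, "strand_flipped_swapped")
  expect_equal(al$outcome_row$beta, -0.15)

  al <- align_alleles(ex, row_of("A", "C", beta = 0.15))
  expect_identical(al$action, "dropped:incompatible_alleles")
  expect_null(al$outcome_row)

  expect_error(align_alleles(row_of("A", "N"), row_of("A", "G")),
               "malformed")
})

test_that("palindromic SNPs orient by frequency or drop when ambiguous", {
  ex <- row_of("A", "T", beta = 0.2, eaf = 0.2)

  # both frequencies on the same side: accept as aligned
  al <- align_alleles(ex, row_of("A", "T", beta = 0.1, eaf = 0.25))
  expect_identical(al$action, "direct")
  expect_equal(al$outcome_row$beta, 0.1)

  # opposite sides: the outcome row is reported on the other strand; flip
  al <- align_alleles(ex, row_of("A", "T", beta = 0.1, eaf = 0.75))
  expect_identical(al$action, "flipped")
  expect_equal(al$outcome_row$beta, -0.1)

  # intermediate frequency: cannot orient
  al <- align_alleles(ex, row_of("T", "A", beta = 0.1, eaf = 0.50))
  expect_identical(al$action, "dropped:palindromic_ambiguous")

  # exposure frequency in the window is just as ambiguous
  ex2 <- row_of("C", "G", beta = 0.2, eaf = 0.45)
  al <- align_alleles(ex2, row_of("C", "G", beta = 0.1, eaf = 0.2))
  expect_identical(al$action, "dropped:palindromic_ambiguous")
})

test_that("alignment is a no-op on already-aligned rows (idempotence)", {
  ex <- row_of("A", "G", beta = 0.2, eaf = 0.3)
  ou <- row_of("G", "A", beta = 0.15, eaf = 0.69)
  once <- align_alleles(ex, ou)
  twice <- align_alleles(ex, once$outcome_row)
  expect_identical(twice$action, "direct")
  expect_equal(twice$outcome_row$beta, once$outcome_row$beta)
  expect_equal(twice$outcome_row$eaf, once$outcome_row$eaf)
})

test_that("swapping allele roles in the input leaves harmonised data fixed", {
  # negating ea/oa, beta and eaf of an outcome row encodes the same signal
  ex <- row_of("A", "G", beta = 0.2, eaf = 0.3)
  ou <- row_of("A", "G", beta = 0.15, eaf = 0.31)
  ou_swapped <- row_of("G", "A", beta = -0.15, eaf = 0.69)
  a1 <- align_alleles(ex, ou)
  a2 <- align_alleles(ex, ou_swapped)
  expect_equal(a1$outcome_row$beta, a2$outcome_row$beta)
  expect_equal(a1$outcome_row$eaf, a2$outcome_row$eaf)
})

test_that("proxy search obeys the strict r^2 bound and tie rules", {
  cfg <- sim_config(m_snps = 6, n_exposure_sample = 2000, n_chroms = 1,
                    seed = 53)
  p <- simulate_genotypes(cfg)
  # rs2 is a strong proxy of rs1; rs3 a weak one
  p$dosages[, 2] <- p$dosages[, 1]
  swap <- seq_len(500)
  p$dosages[swap, 2] <- rbinom(500, 2, p$snps$freq[1])
  ld <- ld_matrix(p)

  out_stats <- make_stats(p$snps$snp[2:6], beta = rnorm(5), se = 0.05,
                          chr = p$snps$chr[2:6], bp = p$snps$bp[2:6])
  px <- find_proxy("rs1", out_stats, ld, r2_min = 0.5)
  expect_identical(px$snp, "rs2")
  expect_gt(px$r2, 0.5)

  # the target itself present in the outcome wins with r^2 = 1
  out_all <- make_stats(p$snps$snp, beta = rnorm(6), se = 0.05,
                        chr = p$snps$chr, bp = p$snps$bp)
  expect_identical(find_proxy("rs1", out_all, ld, r2_min = 0.8)$snp, "rs1")

  # strict inequality at the bound
  expect_null(find_proxy("rs1", out_stats, ld, r2_min = 1))
  expect_null(find_proxy("rs1", out_stats, ld,
                         r2_min = px$r2))  # candidates at the bound excluded

  # absent from the reference: no proxy, message
  expect_message(expect_null(find_proxy("zz1", out_stats, ld)), "absent")
})

test_that("multivariable harmonisation assembles, drops and accounts", {
  ex1 <- make_stats(paste0("rs", 1:10), beta = rnorm(10), se = 0.02,
                    ea = "A", oa = "G", eaf = 0.3, trait = "X1")
  ex2 <- make_stats(paste0("rs", 1:10), beta = rnorm(10), se = 0.02,
                    ea = "A", oa = "G", eaf = 0.3, trait = "X2")
  ou <- make_stats(paste0("rs", 1:10), beta = rnorm(10), se = 0.05,
                   ea = "A", oa = "G", eaf = 0.3, trait = "Y")
  # one palindromic, intermediate-frequency SNP in the union
  ex1$ea[5] <- "A"; ex1$oa[5] <- "T"; ex1$eaf[5] <- 0.5
  ex2$ea[5] <- "A"; ex2$oa[5] <- "T"; ex2$eaf[5] <- 0.5
  ou$ea[5] <- "A"; ou$oa[5] <- "T"; ou$eaf[5] <- 0.5

  H <- harmonise_mvmr(list(X1 = ex1, X2 = ex2), paste0("rs", 1:10), ou)
  expect_identical(nrow(H), 9L)
  dropped <- attr(H, "dropped")
  expect_identical(dropped$snp, "rs5")
  expect_identical(dropped$reason, "palindromic_ambiguous")
  expect_identical(nrow(H) + nrow(dropped), 10L)
  expect_equal(attr(H, "retention"), 0.9)
  expect_true(all(H$provenance == "direct"))

  # a union SNP missing from one trait's full stats is a hard error
  expect_error(harmonise_mvmr(list(X1 = ex1[-2, ], X2 = ex2),
                              paste0("rs", 1:10), ou),
               "X1")
})

test_that("strand flips and proxies match a hand-aligned oracle", {
  cfg <- sim_config(m_snps = 5, n_exposure_sample = 3000, n_chroms = 1,
                    seed = 59)
  p <- simulate_genotypes(cfg)
  p$dosages[, 5] <- p$dosages[, 3]  # rs5 proxies rs3
  ld <- ld_matrix(p)

  ex <- make_stats(paste0("rs", 1:3), beta = c(0.2, -0.1, 0.3), se = 0.02,
                   ea = "A", oa = "G", eaf = 0.3, trait = "X1",
                   chr = p$snps$chr[1:3], bp = p$snps$bp[1:3])
  # outcome: rs1 reported on the other strand (T/C == complement of A/G),
  # rs2 strand-flipped AND swapped, rs3 absent but rs5 present
  ou <- make_stats(c("rs1", "rs2", "rs5"), beta = c(0.11, 0.07, -0.25),
                   se = 0.05, eaf = c(0.3, 0.7, 0.3),
                   chr = p$snps$chr[c(1, 2, 5)], bp = p$snps$bp[c(1, 2, 5)],
                   trait = "Y")
  ou$ea <- c("T", "C", "A"); ou$oa <- c("C", "T", "G")
  # make the alleles non-palindromic and consistent with the panel
  H <- harmonise_mvmr(list(X1 = ex), c("rs1", "rs2", "rs3"), ou, ld = ld,
                      proxy_r2 = 0.8)
  expect_identical(nrow(H), 3L)
  # hand-aligned: rs1 beta unchanged (strand flip only), rs2 negated
  expect_equal(H$beta_outcome[H$snp == "rs1"], 0.11)
  expect_equal(H$beta_outcome[H$snp == "rs2"], -0.07)
  expect_identical(H$provenance[H$snp == "rs1"], "strand_flipped")
  expect_identical(H$provenance[H$snp == "rs2"], "strand_flipped_swapped")
  # rs3 resolved through its perfect proxy rs5; signed r is positive here
  expect_identical(H$provenance[H$snp == "rs3"], "proxy:rs5")
  expect_equal(H$beta_outcome[H$snp == "rs3"], -0.25)
})

test_that("a negatively correlated proxy is sign-oriented", {
  cfg <- sim_config(m_snps = 4, n_exposure_sample = 3000, n_chroms = 1,
                    seed = 61)
  p <- simulate_genotypes(cfg)
  p$dosages[, 4] <- 2L - p$dosages[, 2]  # rs4 = mirrored rs2, r = -1
  ld <- ld_matrix(p)
  ex <- make_stats("rs2", beta = 0.2, se = 0.02, ea = "A", oa = "G",
                   chr = p$snps$chr[2], bp = p$snps$bp[2], trait = "X1")
  ou <- make_stats("rs4", beta = 0.4, se = 0.05, ea = "A", oa = "G",
                   chr = p$snps$chr[4], bp = p$snps$bp[4], trait = "Y")
  H <- harmonise_mvmr(list(X1 = ex), "rs2", ou, ld = ld)
  expect_identical(H$provenance, "proxy:rs4")
  expect_equal(H$beta_outcome, -0.4)  # flipped to the target's effect allele
})
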