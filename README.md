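# lipidmr

Two-sample and multivariable Mendelian randomisation (MR) for highly
correlated lipoprotein lipid exposures on a binary disease outcome.

## The problem this package addresses

LDL cholesterol, triglycerides, HDL cholesterol, apolipoprotein B (apoB)
and apolipoprotein A-I travel together: LDL cholesterol and apoB are
correlated at Pearson r ≈ 0.96. Univariable MR — using genome-wide
significant SNPs as instruments and regressing SNP–outcome on SNP–exposure
associations — therefore makes *every* lipid trait look causal for coronary
heart disease, because an instrument for one trait instruments its
companions too. Multivariable MR (MVMR) fits all exposures jointly and
estimates each trait's **direct** effect conditional on the others; under a
particle-number model of atherosclerosis, only apoB should survive that
adjustment. `lipidmr` is built for exactly this analysis, for
epidemiologists and statistical geneticists who want the full pipeline —
and a matching synthetic-data generator — in one tested package.

## What it implements

* **Synthetic two-sample studies** (`lipid_preset()`, `simulate_mr_study()`):
  genotypes, five correlated standardised lipid-like exposures
  (corr(LDL, apoB) calibrated to 0.96; corr(HDL, TG) to −0.49), a shared
  confounder, optional horizontal pleiotropy, and a logistic outcome in an
  independent sample whose only direct lipid causes are the apoB-like trait
  (log-odds θ = 0.65 per SD) and, weakly, triglycerides (0.10).
* **Association scans** (`snp_association()`): inverse-rank-normalised
  traits, covariate-adjusted per-SNP OLS, compiled per-SNP logistic
  regression for case status.
* **Instruments** (`filter_genome_wide()`, `ld_clump()`,
  `annotate_novelty()`, `cross_trait_overlap()`): strict p < 5×10⁻⁸ filter,
  greedy LD clumping at r² < 0.001, novelty against a reported-SNP
  catalogue (±1 Mb, r² < 0.001), Venn-style cross-trait locus cells.
* **Harmonisation** (`harmonise_mvmr()`, `align_alleles()`, `find_proxy()`):
  common effect allele across all traits and the outcome, strand
  resolution, frequency-oriented palindromic SNPs (ambiguous ones dropped),
  signed-LD proxies at r² > 0.8.
* **Estimators** (`mr_ivw()`, `mr_egger()`, `mr_weighted_median()`,
  `mr_weighted_mode()`, `mvmr_ivw()`, `mvmr_egger()`): for J SNPs,

  βᵢᵥᵥ = Σⱼ wⱼ β̂ₓⱼ β̂ᵧⱼ / Σⱼ wⱼ β̂ₓⱼ², wⱼ = 1/s²ᵧⱼ,

  with multiplicative random-effects SEs (residual scale clipped at 1);
  Egger adds a free intercept after orienting exposure betas non-negative;
  median/mode work on Wald ratios β̂ᵧⱼ/β̂ₓⱼ with seeded parametric-bootstrap
  SEs; MVMR is the weighted multiple regression of outcome betas on the
  J×K exposure beta matrix. Diagnostics: mean F = mean(β̂ₓ/sₓ)² and the
  conditional F (Q-statistic form) per exposure.
* **Orchestration** (`mr_config()`, `run_univariable_suite()`,
  `run_multivariable_suite()`, `run_sensitivity_suite()`,
  `write_report()`): conventional defaults (alpha 0.01; models
  apoB+LDL+TG and apoB+HDL+apoA1), fasting-covariate and apoB-excluded
  reruns, deterministic TSV/JSON reports, forest plots, broom-style
  `tidy()`/`glance()` and `autoplot()`.

## Worked example

Simulate a three-trait study at the calibrated preset (20,000 individuals
per sample, 300 SNPs, 40 causal) and run both suites:

```r
library(lipidmr)

cfg <- lipid_preset(traits = c("apoB", "LDL", "TG"), seed = 42)
st  <- simulate_mr_study(cfg)

cfg_a <- mr_config(traits = c("apoB", "LDL", "TG"),
                   models = list(c("apoB", "LDL", "TG")))
uni <- run_univariable_suite(st, cfg_a)
mv  <- run_multivariable_suite(st, cfg_a)

dplyr::filter(uni, method == "ivw")
#>   exposure n_snps   or or_lo or_hi         p mean_f
#> 1     apoB     29 1.82  1.75  1.89 1.93e-181    386
#> 2      LDL     31 1.73  1.60  1.87  1.12e-42    365
#> 3       TG     27 1.42  1.18  1.71  2.60e-04    338

dplyr::filter(mv, method == "mvmr_ivw")
#>   exposure n_snps   or or_lo or_hi        p conditional_f
#> 1     apoB     39 1.66 1.409  1.95 1.13e-09            18
#> 2      LDL     39 1.06 0.915  1.24 4.23e-01            21
#> 3       TG     39 1.08 1.013  1.15 1.69e-02           133
```

Read: univariable MR declares all three traits strongly "causal"
(odds ratios 1.42–1.82 per 1-SD higher trait, huge mean F). In the joint
model only the apoB-like trait keeps a robust direct effect (OR 1.66,
p ≈ 1e-9); the LDL-like estimate collapses to the null (OR 1.06, p = 0.42)
because in the generating model its entire effect is mediated by apoB, and
the TG estimate shrinks to its small direct share (OR 1.08). The
conditional F-statistics (18 and 21 for the collinear apoB/LDL pair versus
133 for TG) quantify how little independent instrument signal the 0.96
correlation leaves. `plot_forest(dplyr::bind_rows(uni, mv))` draws the
comparison; `write_report()` saves it.

The estimates are population-averaged log-odds ratios: odds-ratio
non-collapsibility and finite conditional F attenuate the apoB estimate
below exp(0.65) ≈ 1.92 by design-knowable amounts — the methods vignette
(`vignettes/lipidmr-methods.Rmd`) walks through the arithmetic.

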