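---
title: "Separating apolipoprotein B from its correlated lipid companions: methods behind lipidmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating apolipoprotein B from its correlated lipid companions: methods behind lipidmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Circulating lipid measures — LDL cholesterol, triglycerides, HDL
cholesterol, apolipoprotein B (apoB) and apolipoprotein A-I — are so highly
correlated (LDL cholesterol and apoB at Pearson r ≈ 0.96) that observational
or single-exposure genetic analyses cannot say *which* of them drives
coronary heart disease (CHD). Two-sample Mendelian randomisation (MR) treats
genome-wide significant SNPs as instrumental variables: the SNP–exposure
associations come from one cohort, the SNP–outcome associations from a
second, non-overlapping case-control sample, and a weighted regression of
one on the other estimates the causal log-odds of disease per 1-SD higher
exposure. Univariable MR applied to each lipid trait in turn makes *all* of
them look causal, because an instrument for LDL cholesterol is almost
inevitably an instrument for apoB too. Multivariable MR (MVMR) — regressing
the SNP–outcome associations jointly on every exposure's SNP associations —
estimates each trait's *direct* effect, conditional on the others, and is
the analysis this package is built around: under a data-generating process
in which only apoB (strongly) and triglycerides (weakly) act on the outcome,
MVMR should recover that structure while univariable MR shows the familiar,
misleading positive effect of LDL cholesterol.

`lipidmr` implements the whole pipeline — per-SNP association scans,
genome-wide filtering, LD clumping, novelty annotation, cross-trait locus
overlap, summary-statistic harmonisation with proxy substitution, the
estimators (IVW, MR-Egger, weighted median, weighted mode, MVMR-IVW,
MVMR-Egger), instrument-strength diagnostics (mean and conditional
F-statistics), and a synthetic-data generator that reproduces the
statistical structure of the real design so every stage is testable without
access to cohort data.

## The synthetic-data generator

The generator is first-class code, not a test fixture. One call to
`simulate_mr_study()` draws a shared SNP map (ids, chromosomes, positions,
alleles, frequencies uniform on (0.05, 0.95) by default) and two disjoint
samples of individuals. Traits are built as

$$X = G_c A + U\lambda_c' + F\lambda_s' + E,$$

with $G_c$ the centred dosages (Binomial(2, f) per SNP), $U$ a standard
normal confounder, $F$ an inert shared factor, and $E$ multivariate normal.
Columns are standardised to mean 0, SD 1 exactly. Case status follows

$$\mathrm{logit}\,P(Y=1) = \alpha + X\theta + \gamma U + G_c\,\delta,$$

where $\theta$ holds the true direct effects, $\delta$ optional horizontal
pleiotropy (balanced, directional, or InSIDE-violating), and $\alpha$ is
solved numerically so the expected case fraction matches the target
prevalence (0.33 by default, matching the case/control composition of the
large CHD consortium data the design emulates).

### The calibrated lipid presets

`lipid_preset()` encodes the study conditions. Trait order is (apoB, LDL,
TG, HDL, apoA1); the three-trait subset (apoB, LDL, TG) is the atherogenic
recovery benchmark. The key constants, fixed once during design:

* **Phenotypic correlations.** Anchored at corr(apoB, LDL) = 0.96 and
  corr(TG, HDL) = −0.49; the remaining entries (apoB–TG 0.45, LDL–TG 0.35,
  HDL–apoA1 0.92, …) are chosen to be realistic for non-fasted lipid panels.
* **Decomposition.** Each trait has heritability $h^2$ (0.55, 0.55, 0.45,
  0.50, 0.50), a confounder loading $\lambda_c$ (0.15, 0.10, 0.25, −0.20,
  −0.15) with outcome log-odds loading 0.25, and a genetic correlation
  matrix (apoB–LDL 0.945) chosen so the residual covariance
  $\Psi = R - C_g - \lambda_c\lambda_c'$ is positive semi-definite. An
  empirical check at n = 50,000 reproduces every entry of $R$ to within
  0.007.
* **Exact genetic normalisation.** Per-allele effects are drawn for a
  sparse set of causal SNPs (40 of 300 by default) and then linearly
  transformed so that $A'\,\mathrm{diag}(2f(1-f))\,A$ equals the target
  genetic covariance exactly. This removes Monte-Carlo slack from the
  correlation targets and pins the instrument-strength regime: with 40
  strong loci the single-SNP F-statistics land in the 100–300 range
  reported for real lipid instruments, and the union instrument set is
  desk-scale.
* **True effects.** $\theta$ = 0.65 for apoB, 0.10 for TG, 0 elsewhere: the
  LDL effect is fully mediated by apoB, mirroring the conclusion the MVMR
  analysis is designed to expose.
* **LD.** SNPs are independent by default; optional blocks copy a template
  SNP and resample a configurable fraction of genotypes, giving tunable
  within-block r² for clumping and proxy tests. Realistic human LD maps,
  imputation error and relatedness are deliberately out of scope, so
  passing tests say nothing about mixed-model GWAS machinery on real
  cohorts.

Covariates (age, sex, fasting hours) are generated and accepted by the
association scan but carry zero trait loadings by default, so the
correlation calibration stays exact; the fasting-time sensitivity rerun
exercises the covariate path itself.

## Association scans and instrument selection

Traits are inverse-rank-normalised before the exposure GWAS,
$\Phi^{-1}((r_i - 3/8)/(n + 1/4))$ with average ranks under ties. The Blom
offset is a convention choice; the transform is standard for lipid GWAS but
its exact offset is rarely reported. The per-SNP scan is plain OLS
(Frisch–Waugh–Lovell closed form) for quantitative traits and IRLS logistic
regression in compiled code for case status — linear mixed models are
unnecessary for synthetic panels without structure or relatedness, and this
is an explicit simplification relative to biobank-scale practice.
Monomorphic SNPs are emitted with `se = Inf` rather than erroring, so
extreme-frequency simulations never abort a pipeline; p-values are carried
in log10 form so genome-wide signals that underflow double precision still
order correctly.

Instruments are SNPs with p strictly below 5e-8, greedily clumped at
r² < 0.001: sort by p (ties: larger |beta|, then SNP id), keep the best,
discard everything correlated with it on the same chromosome, repeat. No
distance window is applied — the r² rule alone is stricter than windowed
clumping and affordable at desk scale. Novelty annotation flags an
instrument as novel when every catalogue SNP within 1 Mb on the same
chromosome has r² < 0.001 with it; we read the "within 1 Mb and r² < 0.001"
rule as independence from *all* in-window reported SNPs, which is the
conservative reading of an ambiguous convention. Cross-trait overlap
re-clumps the union of instruments and labels each locus with the set of
traits its index SNP is significant for — the cells of the instrument
specificity Venn diagram.

## Harmonisation

Exposure and outcome summary statistics are aligned to a single effect
allele per SNP: direct match; swapped alleles (negate beta, complement the
frequency); strand complement; or both. Palindromic A/T and C/G SNPs cannot
be resolved from labels, so they are oriented by allele-frequency agreement
when both frequencies lie outside [0.42, 0.58] and dropped as ambiguous
otherwise; the window is configurable, and when the outcome file lacks
frequencies palindromic SNPs are always dropped. Exposure traits measured
in one study are assumed strand-consistent with each other, so
cross-exposure alignment uses labels only — the frequency rule applies to
the outcome study. A SNP missing from the outcome statistics is replaced by
its best LD proxy at r² strictly above 0.8, oriented by the *signed* LD r
from the reference panel; when only unsigned r² is available proxies are
disabled rather than risking silent sign errors. Every dropped SNP carries
exactly one reason, and retained + dropped reconciles to the union size.

## Estimators

All Wald-type methods use multiplicative random-effects standard errors:
the fixed-effect covariance scaled by the weighted residual mean square,
clipped at 1 so over-precision is never reported, with normal-reference
p-values (instrument counts are large in the target use).

* **IVW**: weighted regression of outcome on exposure betas through the
  origin, weights $1/s_Y^2$; algebraically the inverse-variance-weighted
  mean of per-SNP Wald ratios.
* **MR-Egger**: SNPs oriented so exposure betas are non-negative, then the
  same regression with a free intercept estimating directional pleiotropy.
* **Weighted median**: ratios sorted, weights $\beta_X^2/s_Y^2$, linear
  interpolation of the cumulative weight midpoints at 0.5; SE from a seeded
  parametric bootstrap (1000 resamples by default) drawn in canonical SNP
  order so results are invariant to row permutations.
* **Weighted mode**: argmax on a fixed 512-point grid of the
  normal-kernel density of ratios, bandwidth
  $\varphi\, 0.9 \min(\mathrm{sd}, \mathrm{IQR}/1.349) J^{-1/5}$; identical
  ratios short-circuit to that ratio with SE 0.
* **MVMR-IVW / MVMR-Egger**: weighted multiple regression of outcome betas
  on the exposure beta matrix without/with an intercept; Egger orientation
  negates whole SNP rows by the sign of a chosen exposure (the first in the
  model by default, recorded in the output).
* **Diagnostics**: mean F is the summary-data approximation
  $\tfrac1L\sum_j (\hat\beta_{Xj}/s_{Xj})^2$; the conditional F for exposure
  k regresses its betas on the other exposures' betas (weights
  $1/s_{Xjk}^2$, no intercept, rank-deficient predictor sets handled by QR
  projection) and reports $Q_k/(L-K+1)$, the summary-data Q form. The exact
  equation used by the original study's supplement was not inspectable, so
  this documented form is the default.

## What the evaluation harness shows — and does not

`benchmark_recovery()` runs 100 replicate three-trait studies at n = 20,000
per sample and m = 300 SNPs. Expectations worth stating plainly: the
population quantity summary-data MVMR estimates on a logistic outcome is
*not* exactly $\theta$. Odds-ratio non-collapsibility attenuates the
per-SNP outcome log-odds by roughly $1/\sqrt{1 + 0.35\,\sigma^2}$ (σ² ≈ 0.5
here, a ~7% shrink), and weak-instrument error in the exposure betas
shrinks the poorly identified apoB-minus-LDL contrast by about
$F_{cond}/(F_{cond}+1)$ — the replicate conditional F for apoB and LDL sits
near 20, close to the mid-30s the original study reported at twenty times
the sample size. The recovery check therefore asks that the mean estimate
sit within two replicate-level SDs of $\theta$, which it does
(apoB ≈ 0.57 with replicate SD ≈ 0.08 against 0.65; LDL ≈ 0.00; TG ≈ 0.09), while the
univariable IVW for the fully mediated LDL-like trait excludes zero at the
99% level in essentially every replicate — the qualitative
univariable-versus-MVMR reversal that motivates the whole design.

`benchmark_calibration()` runs 500 null replicates (one strongly
instrumented trait, $\theta = 0$, a confounder but no pleiotropy; n = 4,000
per sample, 60 SNPs, 30 causal) and 500 balanced-pleiotropy replicates for
the Egger intercept. IVW, MR-Egger, the weighted median and the Egger
intercept all cover zero at rates inside the exact binomial 99% band around
0.95. The **weighted mode overcovers** (≈ 0.978, just above the band): the
parametric-bootstrap SD overestimates the sampling variability of a kernel
density argmax at modest instrument counts. This is a known conservative
property of the method as defined, not an implementation artefact — the
oracle tests pin the point estimate to an independent grid-argmax to
1e-12 — and we report it rather than retuning the scenario. Mode intervals
should be read as conservative.

Problem sizes throughout (n per sample, SNP counts, replicate counts) are
the package's own choices: large enough that binomial bands and oracle
comparisons are meaningful, small enough that the full evaluation reruns in
minutes on a laptop core.

## Interface choices

Every user-facing function takes a data frame first and returns a tibble,
so pipelines compose with the pipe; fitted estimators are `mr_fit` objects
with `tidy()`/`glance()` methods and `autoplot()`; `run_univariable_suite()`,
`run_multivariable_suite()` and `run_sensitivity_suite()` orchestrate the
full analysis from an `mr_study` (or any list of summary-stat tibbles plus
an LD matrix) under an `mr_config()` whose defaults are the conventional
thresholds: p < 5e-8, clump r² < 0.001, proxy r² > 0.8, two-sided alpha
0.01 (a Bonferroni-style allowance for five correlated traits), and the two
standard multivariable models (apoB + LDL + TG; apoB + HDL + apoA1).
`write_report()` emits deterministic TSV and schema-versioned JSON; file
readers accept external column dialects through a column map. The package
is operated from R — the suite functions, the IO layer and `write_report()`
are the pipeline surface, and `scripts/acceptance.R` shows a complete
scripted run; no shell subcommand wrapper is shipped.

## Known limitations

* Odds-ratio non-collapsibility means all summary-data estimates are
  population-averaged log-ORs, mildly attenuated relative to the
  conditional $\theta$; this is inherent to logistic outcomes, shared with
  every two-sample MR implementation, and quantified above.
* Weighted-mode bootstrap intervals are conservative (see calibration).
* The generator's LD model (exchangeable blocks) and covariate model are
  deliberately simple; clumping, proxy search and novelty annotation are
  exercised mechanically but not against realistic human LD.
* Cross-exposure strand consistency is assumed (one-study exposures);
  harmonising exposures from different genotyping platforms would need the
  frequency rule extended to exposure pairs.
* Real-data retention fractions depend on the outcome file's SNP coverage;
  on synthetic data retention reflects only palindromic drops (~94%), so it
  is reported, not asserted.
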