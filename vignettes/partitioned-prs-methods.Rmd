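---
title: "Partitioned polygenic risk scores for liver fat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned polygenic risk scores for liver fat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partprs)
```

## The scientific problem

Excess liver triglyceride (steatotic liver disease) has at least two
genetic routes. Variants in genes that hamper hepatic lipoprotein (VLDL)
secretion retain triglycerides in the liver while *lowering* circulating
triglycerides: more liver fat, fewer circulating lipoproteins, and —
because circulating lipoproteins drive atherosclerosis — *lower*
cardiovascular risk. Other variants raise liver fat through systemic
routes (uptake, de novo synthesis, reduced oxidation) and raise
circulating triglycerides alongside, carrying cardiometabolic risk with
them.

`partprs` operationalizes this distinction. Genome-wide significant loci
for MRI-derived liver fat (PDFF) are split by the *sign* of their effect
on circulating triglycerides (TG), oriented to the PDFF-increasing
allele:

* **discordant** (TG effect negative): liver-retention pathway;
* **concordant** (TG effect positive): systemic pathway;
* loci with no TG association are excluded.

Each group becomes a partitioned polygenic risk score (pPRS)
`score_i = sum_v w_v g_iv`, with `w_v` the oriented PDFF effect of the
strongest association at the locus. The two scores are then associated
with disease outcomes (logistic for case-control status, Cox for
incident events), compared per outcome by the Wald statistic
`W = (b1 - b2) / sqrt(se1^2 + se2^2)`, `W^2 ~ chi2(1)`, and by AIC
differences. A hypothesis-free alternative partition is obtained by
Bayesian non-negative matrix factorization of the variant-trait z-score
matrix.

## The synthetic world

Real cohort data of this kind are access-restricted, so the package
carries a first-class generator (`sim_config()`, `simulate_cohort()`)
whose defaults state the world every downstream test assumes:

* **Cohort**: 20,000 samples; age uniform 40–70, sex balanced.
* **Causal architecture**: 10 discordant and 13 concordant loci. Per-allele
  PDFF effects are drawn uniformly from |0.03–0.29| SD/allele (the span of
  reported genome-wide significant liver-fat effects); MAF uniform on
  0.10–0.50; 500 null variants.
* **Pathway coupling**: each variant's TG effect magnitude equals its PDFF
  effect magnitude times Unif(0.95, 1.05), clipped to the same range, with
  the sign set by its group. One underlying pathway activity per variant
  drives both traits. This matters for the factorization: if the two
  effect sizes were drawn independently, the variant-trait signal matrix
  would have non-negative rank about four (each pathway block would span a
  PDFF-driven and an unrelated TG-driven pattern) and *no* correct
  factorization could report the two-cluster structure the analysis is
  meant to recover.
* **Adiposity**: BMI, whole-body fat mass, VAT and waist-hip ratio are
  correlated Gaussians (pairwise correlations 0.45–0.85) with mild age/sex
  structure.
* **Mediation**: a fraction `f = 0.2` of each *concordant* variant's PDFF
  effect is routed through VAT (the designated mediator; effect
  `gamma = 0.3` SD PDFF per SD VAT), so the direct path is `(1 - f) b` by
  construction. Discordant (liver-retention) effects are fully direct.
* **Secondary traits**: cT1 tracks the discordant pathway (liver damage),
  ALT tracks PDFF, LDL *falls* with the discordant pathway (lipoprotein
  retention) and rises mildly with the concordant one, glucose tracks the
  concordant pathway. Residual noise SD is 1 on every quantitative trait,
  so planted betas are approximately SD units.
* **Outcomes**: liver disease (prevalence 0.05), cardiovascular disease
  (0.10), hypertension (0.25), diabetes (0.08). Case-control status is a
  logistic draw on the standardized true pathway scores with log-odds
  (discordant, concordant) = (+0.35, +0.20), (−0.15, +0.25), (0, +0.20),
  (+0.10, +0.25) respectively — liver risk loads on the liver-retention
  score, cardiovascular risk dissociates. Incident events for
  non-prevalent samples follow an exponential proportional-hazards model
  with the same log-effects, baseline hazard `prevalence / 14.5` per year
  and uniform censoring on 0.7–1.0 of the 14.5-year follow-up.
* **LD tags**: optional tag variants copy the causal haplotypes with
  per-allele fidelity `sqrt(r2)`, hitting the target dosage r² in
  expectation.

What the generator does **not** emulate: population structure and
relatedness (no PCs, no mixed models), imputation uncertainty,
rare-variant effects, X-chromosome dosages, and real LD beyond the simple
tag mechanism. A green test therefore establishes that the *analysis
machinery* is correct under its stated assumptions, not that those
assumptions hold in any particular biobank.

## Association machinery

Quantitative traits are rank-based inverse-normal transformed before
scanning: `qnorm((r - 3/8) / (n + 1 - 3/4))` with average ranks for ties
(the Blom offset 3/8 is a convention choice; the source analyses do not
state one). Scans fit one variant at a time with the standard covariate
set (age, sex, age², age×sex, age²×sex, plus at most one adiposity
index); with complete dosages the linear scan uses Frisch–Waugh
residualization for speed and is exactly equal to per-variant OLS.
Whole-genome-regression machinery (REGENIE-style LOCO ridge, its step-1
polygenic covariate, saddle-point corrections for rare binary outcomes)
is deliberately absent: the synthetic world has no relatedness or
polygenic background, so the per-variant GLM estimands coincide.

Gene–adiposity interaction tests use HC3 sandwich standard errors
(hand-rolled: `(X'X)^-1 X' diag(e²/(1-h)²) X (X'X)^-1`) and optionally
log-transform the phenotype. Independent loci come from PLINK-style
greedy clumping (`p1 = 5e-8`, `r2 = 0.01`, `kb = 1000`; members claimed
at `r2 >=` threshold per PLINK convention) followed by forward-backward
stepwise conditional selection on individual-level data (threshold
`5e-8`, 10 Mb conditioning window) — exact where the original used
summary-statistic approximations, since genotypes are in hand. Leads
within 1 Mb and `r2 > 0.2` (strict, per the stated rule) merge into
pleiotropic loci; ids are assigned by genomic position, and per-trait
locus leads are the lowest-P members with ties broken by trait name,
position, then id (the tie rule is not stated in the source; this one is
deterministic and logged).

The TG-association threshold that decides exclusion from the partition is
not printed anywhere; `alpha_tg = 0.05` is the default and is exposed as
configuration. Scores standardize to unit SD before outcome regression so
effects are per SD and the Wald comparison is scale-free. Missing dosages
mean-impute to `2 x EAF` with a hard 10% ceiling per variant.

## bNMF soft clustering

The variant-trait matrix holds `z = beta / se` per variant and trait,
scaled by `sqrt(median N / N_trait)` to equalize sample-size differences,
aligned so the PDFF z of every variant is positive, and split into
non-negative positive/negative trait columns. One trait of each pair with
absolute *phenotypic* correlation above 0.85 is dropped (first by input
order wins). Using z-column correlations instead would spuriously
collapse the panel whenever effect sizes are pathway-coupled, which is
why the pipeline passes phenotypic correlations explicitly.

The factorization minimizes

```
||V - WH||^2 / (2 phi)
  + sum_k [ (||W_k||^2 + ||H_k||^2) / 2 + b0 ] / lambda_k
  + ((N + M)/2 + a0 + 1) sum_k log lambda_k
```

by multiplicative updates for `W` and `H` (majorization steps, so the
objective never increases within a restart) and a closed-form update for
the relevance scales `lambda_k`. Hyperparameters: `a0 = 10`,
`b0 = sqrt((a0-1)(a0-2) mean(V) / K)`, `phi = var(V)` (the conservative
ARD convention; exposed as `noise_var`). The input is normalized by its
mean internally so the selected K and memberships are invariant to
rescaling. A component is effective when its scale exceeds the prior
floor `b0 / C` by 5%; the modal effective K over random restarts (1,000
in a full run) is selected and the best-posterior restart at that K
returned. On the default synthetic world 80–98% of restarts converge to
two clusters.

Cluster membership uses each variant's weights normalized across clusters
(relative affinity; raw weights when K = 1, where affinity is undefined),
with a cutoff chosen to maximize Otsu's between-class variance
`n_lo n_hi (mean_hi - mean_lo)^2` on the pooled values. Two simpler
rules were rejected: maximizing mean-above/mean-below is always won by
the smallest candidate cutoff (removing the minimum shrinks the
denominator fastest), and Fisher-style `(mu_hi - mu_lo)/(sd_hi + sd_lo)`
truncates genuinely weak-effect members because absolute weights scale
with effect size. The realized mean-above/mean-below ratio at the chosen
cutoff is reported as `snr`. Because membership is per-cluster, a variant
can join both clusters — the soft-clustering behavior the method is
chosen for.

## Mediation

`mediate()` fits `mediator ~ exposure + covariates` and
`outcome ~ exposure + mediator (+ exposure:mediator) + covariates` and
computes ACME/ADE by counterfactual prediction, averaging over treatment
levels when the interaction is present. For linear models the
potential-outcomes estimator is available in closed form, so point
estimates carry no simulation noise; without interaction the ACME equals
the product of the fitted path coefficients exactly. The exposure
contrast defaults to 0 vs 1 allele (the per-unit convention, under which
ACME = a·b); the homozygote contrast 0 vs 2 is available via
`treat_levels`. Intervals are percentile bootstrap (minimal assumptions,
matching a nonparametric-bootstrap description; BCa was deliberately not
used), with both models refit per resample.

Sensitivity to unobserved mediator-outcome confounding uses the linear
closed form: with `rho*` the observed correlation between the residuals
of the mediator model and of an outcome model *without* the mediator,

```
ACME(rho) = a (sd_y / sd_m) (rho* - rho sqrt((1 - rho*^2)/(1 - rho^2)))
```

so `ACME(0)` reproduces the primary estimate and the estimate crosses
zero exactly at `rho = rho*`. `rho_zero` is the smallest `|rho|` on the
grid (default −0.9…0.9 by 0.05) whose bootstrap interval covers zero.
Classification: `none` if the ACME interval covers 0; `complete` if the
ADE interval covers 0 but the ACME's does not; `inconsistent` if ACME and
total effect have opposite signs with both intervals excluding 0 (partial
mediation in the opposite direction); otherwise `consistent-partial`.

## Penalized predictor selection

`nested_cv_penalized()` ranks adiposity indices as independent predictors
of a liver trait. Lasso, ridge and elastic net (alpha grid 0–1 by 0.1,
lambda by glmnet's path) compete in a nested CV: 80/20 train/test split,
outer 10-fold CV scores each family while inner 10-fold CV tunes
(alpha, lambda) by minimum MSE; the winner is re-tuned on the full
training set, evaluated once on the held-out 20%, and refit on all data.
Predictors are standardized, the response is inverse-normal transformed,
and covariates enter unpenalized. Note that a minimum-MSE lambda does not
guarantee that every pure-noise coefficient is exactly zero under the
lasso — sparsity holds for most, and the coefficients agree with a direct
glmnet solve at the selected penalty; tests assert exactly that.

## Numerical and degenerate-input conventions

* Coordinates are 1-based (VCF convention); intervals closed; A1 is the
  effect allele and all betas are per A1 copy.
* Constant dosages are flagged (`constant_dosage`), never silently
  dropped; logistic separation and non-convergence likewise.
* Clump P ties break by position then id; locus ids by (chrom, min pos).
* `glmnet` convergence threshold is tightened to `1e-10` so results are
  reproducible across predictor orderings to ~1e-6.
* Every stochastic function takes a seed, restores the caller's RNG
  state, and derives sub-seeds deterministically; identical configuration
  implies bit-identical output, which the pipeline tests assert on the
  written TSVs.
* Tag-variant fidelity uses per-allele copy probability `sqrt(r2)`, which
  hits the target dosage r² in expectation only; tests allow the
  Monte-Carlo band.

## Known limitations

* All LD comes from the in-run genotype matrix; there is no reference
  panel, no long-range-LD or MHC masking.
* The proxy-variant rule breaks ties by LD, distance and id — the
  functional-consequence criterion would need external annotation.
* Mediation is implemented for continuous outcomes and a single mediator.
* The bNMF prior hyperparameters are documented defaults, not re-derived;
  small matrices (fewer than ~15 variants or ~6 trait columns) give the
  prior more influence over the selected K.
* Sex-stratified and covariate-sensitivity analyses are configurations
  (subsets and covariate lists), not separate code paths.
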