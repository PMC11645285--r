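# partprs

Partitioned polygenic risk scores (pPRS) for the genetics of liver fat.

## The problem

Liver triglyceride accumulation (steatotic liver disease, MASLD) has at
least two genetic routes with opposite systemic consequences. Variants
that hamper hepatic lipoprotein (VLDL) secretion *retain* triglycerides
in the liver: liver fat goes up while circulating triglycerides go down,
and with them cardiovascular risk. Variants acting through systemic
routes (uptake, de novo lipogenesis, reduced oxidation) push liver fat
and circulating triglycerides up together, carrying cardiometabolic risk
along. A single genome-wide polygenic score averages over these two
mechanisms and blurs exactly the distinction that matters clinically.

`partprs` implements the partitioned alternative end to end. Loci
associated with MRI-derived liver fat (PDFF, proton density fat
fraction) are oriented to their PDFF-increasing allele and split by the
sign of their effect on circulating triglycerides (TG):

* **discordant** (`beta_TG < 0`): liver-retention pathway,
* **concordant** (`beta_TG > 0`): systemic pathway,
* no TG association: excluded.

Each group becomes a weighted allele score
`score_i = sum_v w_v g_iv` (weights `w_v` = oriented PDFF effect of the
strongest association at the locus), the scores are tested against
disease outcomes with logistic and Cox models, and their effects are
compared per outcome with the Wald statistic

    W = (b_1 - b_2) / sqrt(se_1^2 + se_2^2),   W^2 ~ chi-square(1)

and by AIC differences. The package also provides the surrounding
machinery: rank-based inverse-normal transforms, per-variant association
scans under multiple adiposity adjustments, HC3-robust gene-adiposity
interaction tests, PLINK-style LD clumping plus stepwise conditional
selection, pleiotropic locus merging, inverse-variance fixed-effect
meta-analysis with LD-proxy lookup, causal mediation analysis with a
rho-sensitivity curve, ARD Bayesian non-negative matrix factorization
for hypothesis-free variant clustering, and penalized
(lasso/ridge/elastic-net) adiposity-predictor selection under nested
cross-validation.

Individual-level biobank data cannot ship with a package, so `partprs`
includes a first-class synthetic-cohort generator with a planted
two-pathway architecture (10 discordant + 13 concordant loci, effect
sizes spanning 0.03–0.29 SD/allele, correlated adiposity indices,
partial mediation through VAT, and outcomes whose risks dissociate by
pathway). Every analysis stage is tested against that stated world; see
`vignettes/partitioned-prs-methods.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(partprs)

cfg <- run_config(
  sim = sim_config(n_samples = 10000, n_null_variants = 100, seed = 42),
  out_dir = "demo_run", bnmf_restarts = 100)
res <- run_pipeline(cfg, quiet = TRUE)

print(res$partition)
#> partition_result: 10 discordant, 9 concordant, 0 excluded

print(res$effects[["discordant.masld.logistic"]])
#> masld ~ discordant [logistic]: OR = 1.439 (95% CI 1.348-1.536), P = 1.27e-27, 997/10000 cases
print(res$effects[["discordant.cardiovascular.logistic"]])
#> cardiovascular ~ discordant [logistic]: OR = 0.885 (95% CI 0.840-0.933), P = 5.46e-06, 1710/10000 cases
print(res$effects[["concordant.cardiovascular.logistic"]])
#> cardiovascular ~ concordant [logistic]: OR = 1.296 (95% CI 1.231-1.365), P = 1.27e-22, 1710/10000 cases

print(res$wald)
#>          outcome          w            p
#> 1          masld   3.734311 1.882296e-04
#> 2 cardiovascular -10.114078 4.785019e-24
#> 3   hypertension  -7.454463 9.023450e-14
#> 4       diabetes  -5.600273 2.140151e-08

print(res$bnmf)
#> bnmf_result: modal K = 2 (87% of 100 restarts), objective -189
```

Reading this: at n = 10,000 the pipeline recovers 19 of the 23 planted
loci at genome-wide significance and assigns all of them to their true
pathway. The liver-retention (discordant) score raises liver-disease
risk (OR 1.44 per SD) while *lowering* cardiovascular risk (OR 0.89);
the systemic (concordant) score raises cardiovascular risk (OR 1.30).
The per-outcome Wald tests confirm the two scores carry significantly
different risks for every outcome, and the hypothesis-free bNMF
clustering independently converges to the same two-cluster structure in
87% of restarts. Every stage also lands on disk in `demo_run/` as
schema-tagged TSVs plus a run log.

The same workflow is scriptable stage by stage:

```sh
Rscript inst/scripts/partprs simulate --seed 42 --out demo_run
Rscript inst/scripts/partprs scan     --out demo_run
Rscript inst/scripts/partprs clump    --out demo_run
Rscript inst/scripts/partprs partition --out demo_run
# ... score, assoc, bnmf, mediate, meta, select-adiposity, run-all
```

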