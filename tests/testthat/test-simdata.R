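test_that("sim_config enforces the planted-architecture invariants", {
  cfg <- sim_config(seed = 101)
  expect_length(cfg$discordant_loci, 10)
  expect_length(cfg$concordant_loci, 13)
  betas <- vapply(c(cfg$discordant_loci, cfg$concordant_loci),
                  function(p) abs(p$beta_pdff), numeric(1))
  expect_true(all(betas >= 0.03 & betas <= 0.29))
  # sign rules are structural
  expect_error(sim_config(discordant_loci = list(
    planted_variant("x", 0.3, 0.1, 0.1))), "opposite")
  expect_error(sim_config(concordant_loci = list(
    planted_variant("x", 0.3, 0.1, -0.1))), "equal PDFF/TG signs")
  expect_error(planted_variant("x", 1.2, 0.1, -0.1))
  expect_error(planted_variant("x", 0.3, 0, -0.1))
  badR <- matrix(1, 4, 4)
  dimnames(badR) <- dimnames(default_adiposity_corr())
  expect_error(sim_config(adiposity_corr = badR), "positive-definite")
  bad_out <- default_outcome_spec()
  bad_out$prevalence[1] <- 1.2
  expect_error(sim_config(outcome_spec = bad_out), "prevalence")
})

test_that("planted_truth returns the generative labels and weights", {
  cfg <- sim_config(seed = 102)
  tr <- planted_truth(cfg)
  expect_length(tr$discordant, 10)
  expect_length(tr$concordant, 13)
  expect_true(all(tr$discordant > 0))
  # labels agree with the sign rule applied to the planted betas
  with(tr$table, {
    expect_true(all(sign(beta_pdff[group == "discordant"]) !=
                    sign(beta_tg[group == "discordant"])))
    expect_true(all(sign(beta_pdff[group == "concordant"]) ==
                    sign(beta_tg[group == "concordant"])))
  })
  cfg0 <- sim_config(concordant_loci = list(), seed = 103)
  expect_length(planted_truth(cfg0)$concordant, 0)
})

test_that("simulate_cohort is bit-reproducible and leaves the RNG alone", {
  cfg <- sim_config(n_samples = 500, n_null_variants = 10, seed = 104)
  set.seed(9); before <- rnorm(1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  set.seed(9)
  expect_identical(rnorm(1), before)  # global RNG state restored
})

test_that("simulated moments match the configuration", {
  # empirical allele frequency 0.25 +/- 0.01 at n = 50,000
  cfg <- sim_config(
    n_samples = 50000, n_null_variants = 0,
    discordant_loci = list(planted_variant("d1", 0.25, 0.2, -0.15)),
    concordant_loci = list(planted_variant("c1", 0.25, 0.1, 0.1)),
    seed = 105)
  coh <- simulate_cohort(cfg)
  expect_lt(abs(mean(dosage(coh$genotypes, "d1")) / 2 - 0.25), 0.01)
  ph <- coh$phenotypes
  # adiposity correlations within Monte-Carlo tolerance
  R <- default_adiposity_corr()
  emp <- cor(as.matrix(ph[, c("BMI", "WFM", "VAT", "WHR")]))
  expect_lt(max(abs(emp - R)), 0.03)
  expect_lt(abs(sd(ph$BMI) - 4.5), 0.15)
})

test_that("planted effects propagate to the phenotypes as configured", {
  cc <- default_cohort()
  coh <- cc$coh; cfg <- cc$cfg
  ph <- coh$phenotypes
  # total PDFF effect of a discordant variant ~ beta_pdff
  pv <- cfg$discordant_loci[[9]]  # largest drawn effects are easiest to see
  fit <- lm(ph$pdff ~ dosage(coh$genotypes, pv$variant_id))
  expect_lt(abs(coef(fit)[2] - pv$beta_pdff),
            3 * summary(fit)$coefficients[2, 2])
  # for a mediated concordant variant, adjusting for the mediated index
  # leaves the direct path (1 - f) * beta
  cv <- cfg$concordant_loci[[which.max(vapply(cfg$concordant_loci, `[[`,
                                              numeric(1), "beta_pdff"))]]
  fit2 <- lm(ph$pdff ~ dosage(coh$genotypes, cv$variant_id) + ph$VAT)
  expect_lt(abs(coef(fit2)[2] - (1 - cfg$mediation_fraction) * cv$beta_pdff),
            3 * summary(fit2)$coefficients[2, 2])
  # downstream scan recovers the negative TG effect of a discordant variant
  dv <- cfg$discordant_loci[[which.max(vapply(cfg$discordant_loci, function(p)
    abs(p$beta_tg), numeric(1)))]]
  rec <- assoc_scan(subset_variants(coh$genotypes, dv$variant_id),
                    rank_inverse_normal(ph$tg),
                    standard_covariates(ph, "WHR"))
  expect_lt(rec$beta, 0)
  expect_lt(rec$p, 1e-4)
})

test_that("LD tags hit their target r2 in expectation", {
  cfg <- sim_config(
    n_samples = 20000, n_null_variants = 0,
    discordant_loci = list(planted_variant("d1", 0.3, 0.2, -0.15,
                                           n_tags = 2, tag_r2 = 0.8)),
    concordant_loci = list(planted_variant("c1", 0.3, 0.1, 0.1)),
    seed = 106)
  coh <- simulate_cohort(cfg)
  expect_true(all(c("d1_tag1", "d1_tag2") %in%
                  coh$genotypes$variants$variant_id))
  r2 <- c(ld_r2(coh$genotypes, "d1", "d1_tag1"),
          ld_r2(coh$genotypes, "d1", "d1_tag2"))
  expect_lt(max(abs(r2 - 0.8)), 0.05)
})

test_that("outcome generators respect prevalence and pathway loadings", {
  cc <- default_cohort()
  ph <- cc$coh$phenotypes
  spec <- cc$cfg$outcome_spec
  for (k in seq_len(nrow(spec))) {
    os <- spec$outcome[k]
    expect_lt(abs(mean(ph[[paste0(os, "_prev")]]) - spec$prevalence[k]),
              0.05)
    tm <- ph[[paste0(os, "_time")]]
    expect_true(all(is.na(tm) | tm >= 0))
    expect_true(all(is.na(tm[ph[[paste0(os, "_prev")]] == 1])))
  }
  # true discordant score raises masld risk, lowers cardiovascular risk
  tr <- planted_truth(cc$cfg)
  s_disc <- compute_score(cc$coh$genotypes, tr$discordant)
  fit <- glm(ph$masld ~ scale(s_disc), family = binomial())
  expect_gt(coef(fit)[2], 0)
  fit2 <- glm(ph$cardiovascular ~ scale(s_disc), family = binomial())
  expect_lt(coef(fit2)[2], 0)
})
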