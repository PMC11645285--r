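mk_rec <- function(id, beta, p, ea = "A", oa = "G") {
  data.frame(variant_id = id, effect_allele = ea, other_allele = oa,
             beta = beta, se = abs(beta) / 3, p = p,
             stringsAsFactors = FALSE)
}

test_that("partition_by_concordance applies the sign/threshold rule", {
  pdff <- rbind(mk_rec("v1", 0.24, 1e-30), mk_rec("v2", 0.05, 1e-9),
                mk_rec("v3", 0.10, 1e-12))
  tg <- rbind(mk_rec("v1", -0.10, 1e-6), mk_rec("v2", 0.08, 1e-4),
              mk_rec("v3", 0.02, 0.5))
  part <- partition_by_concordance(pdff, tg)
  expect_identical(names(part$discordant), "v1")
  expect_identical(names(part$concordant), "v2")
  expect_identical(part$excluded$variant_id, "v3")
  expect_identical(part$excluded$reason, "no TG association")
  expect_true(all(c(part$discordant, part$concordant) > 0))
})

test_that("partition is invariant to reported-allele flips", {
  pdff <- rbind(mk_rec("v1", 0.24, 1e-30), mk_rec("v2", -0.07, 1e-9))
  tg <- rbind(mk_rec("v1", -0.10, 1e-6), mk_rec("v2", 0.05, 1e-4))
  base <- partition_by_concordance(pdff, tg)
  # flip the TG record of v1 onto the other allele
  tg2 <- tg
  tg2[1, c("effect_allele", "other_allele")] <- c("G", "A")
  tg2$beta[1] <- 0.10
  flip <- partition_by_concordance(pdff, tg2)
  expect_identical(flip$discordant, base$discordant)
  expect_identical(flip$concordant, base$concordant)
  # v2 has a negative PDFF beta: oriented to the PDFF-increasing allele,
  # its TG effect flips sign -> discordant, weight positive
  expect_identical(names(base$discordant), c("v1", "v2"))
  expect_identical(base$orientation$effect_allele[2], "G")
  # irreconcilable alleles error with the variant named
  tg3 <- tg
  tg3[1, c("effect_allele", "other_allele")] <- c("T", "C")
  expect_error(partition_by_concordance(pdff, tg3), "v1")
})

test_that("compute_score is the oriented weighted dosage sum", {
  D <- matrix(c(0, 0, 0, 2, 1, 0), 3, 2,
              dimnames = list(NULL, c("z", "w")))
  gm <- make_gm(D)
  expect_equal(unname(compute_score(gm, c(z = 0.5))), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(compute_score(gm, c(w = 0.3))), c(0.6, 0.3, 0),
               ignore_attr = TRUE)
  # orientation on the other allele flips to 2 - dosage
  ori <- data.frame(variant_id = "w", effect_allele = "G")
  expect_equal(unname(compute_score(gm, c(w = 0.3), ori)), c(0, 0.3, 0.6),
               ignore_attr = TRUE)

  set.seed(51)
  D2 <- matrix(rbinom(100 * 8, 2, 0.3), 100, 8,
               dimnames = list(NULL, sprintf("m%02d", 1:8)))
  gm2 <- make_gm(D2)
  w1 <- setNames(runif(8, -0.2, 0.4), colnames(D2))
  expect_equal(unname(compute_score(gm2, w1)), drop(D2 %*% w1),
               tolerance = 1e-12, ignore_attr = TRUE)
  # linearity in the weights
  w2 <- setNames(rnorm(8), colnames(D2))
  expect_equal(compute_score(gm2, w1 + w2),
               compute_score(gm2, w1) + compute_score(gm2, w2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("compute_score imputes sparse missingness and rejects heavy missingness", {
  set.seed(52)
  D <- matrix(rbinom(200, 2, 0.4), 100, 2,
              dimnames = list(NULL, c("a", "b")))
  D[1:5, 1] <- NA
  gm <- make_gm(D)
  sc <- compute_score(gm, c(a = 1))
  expect_identical(attr(sc, "n_imputed"), 5L)
  expect_equal(unname(sc[1]), 2 * mean(D[-(1:5), 1]) / 2)
  D[1:20, 2] <- NA  # 20% missing
  expect_error(compute_score(make_gm(D), c(b = 1)), ">10% missing")
})

test_that("outcome_assoc recovers planted logistic and Cox effects", {
  set.seed(53)
  n <- 20000
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.3 * s))
  e1 <- outcome_assoc(s, y, model = "logistic")
  expect_lt(abs(e1$beta - 0.3), 3 * e1$se)
  expect_true(e1$ci95[1] < e1$beta & e1$beta < e1$ci95[2])
  expect_identical(e1$n_cases, sum(y))

  # exponential proportional hazards with log-HR 0.2 per SD
  tt <- rexp(n, 0.02 * exp(0.2 * s))
  cens <- runif(n, 5, 15)
  e2 <- outcome_assoc(s, covariates = NULL, model = "cox",
                      time = pmin(tt, cens), event = as.integer(tt <= cens))
  expect_lt(abs(e2$beta - 0.2), 3 * e2$se)
  expect_true(is.finite(e2$ph_p))
})

test_that("logistic CI for a null score has close-to-nominal coverage", {
  set.seed(54)
  n_sim <- 300
  covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    s <- rnorm(400)
    y <- rbinom(400, 1, 0.3)
    e <- outcome_assoc(s, y, model = "logistic")
    covered[i] <- e$ci95[1] <= 0 && 0 <= e$ci95[2]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.985)
})

test_that("wald_compare matches the closed form", {
  e <- function(b, s) list(beta = b, se = s)
  w0 <- wald_compare(e(0.2, 0.1), e(0.2, 0.15))
  expect_equal(w0$w, 0)
  expect_equal(w0$p, 1)
  w1 <- wald_compare(e(0.2, 0.1), e(-0.1, 0.1))
  expect_equal(round(w1$w, 4), 2.1213)
  expect_equal(round(w1$p, 4), 0.0339)
  expect_equal(w1$w2, w1$w^2)
  expect_error(wald_compare(e(0.2, 0), e(0.1, 0.1)), "positive")
})

test_that("aic_compare penalizes pure-noise predictors", {
  set.seed(55)
  # identical fits tie exactly
  y <- rnorm(200); x <- rnorm(200)
  f1 <- lm(y ~ x)
  cmp <- aic_compare(list(a = f1, b = f1))
  expect_equal(cmp$delta["a", "b"], 0)
  # E[AIC_big - AIC_small] = 2 - E[chisq_1] = 1 for one noise predictor
  n_sim <- 400
  d <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    x1 <- rnorm(150); noise <- rnorm(150)
    yy <- 0.5 * x1 + rnorm(150)
    d[i] <- AIC(lm(yy ~ x1 + noise)) - AIC(lm(yy ~ x1))
  }
  expect_gt(mean(d), 0.4)
  expect_lt(mean(d), 1.7)
  # the planted model is preferred in >= 90% of replicates
  pref <- 0
  for (i in 1:200) {
    x1 <- rnorm(300); x2 <- rnorm(300)
    yy <- 0.5 * x1 + rnorm(300)
    cmpi <- aic_compare(list(true = lm(yy ~ x1), wrong = lm(yy ~ x2)))
    pref <- pref + (cmpi$delta["true", "wrong"] < 0)
  }
  expect_gte(pref / 200, 0.9)
  expect_error(aic_compare(list(lm(y ~ x), lm(y[1:100] ~ x[1:100]))),
               "different sample sizes")
})

test_that("quartile_contrast compares extreme score quartiles", {
  # n = 8 distinct scores -> exactly 2 per extreme quartile
  sc <- 1:8
  bio <- data.frame(b = c(1, 1, 2, 2, 3, 3, 10, 11))
  out <- quartile_contrast(sc, bio)
  expect_identical(out$n_top, 2L)
  expect_identical(out$n_bottom, 2L)
  expect_equal(out$difference, mean(c(10, 11)) - mean(c(1, 1)))

  set.seed(56)
  sc2 <- rnorm(400)
  bio2 <- data.frame(signal = sc2 + rnorm(400, 0, 0.5),
                     flat = rnorm(400))
  out2 <- quartile_contrast(sc2, bio2)
  expect_gt(out2$difference[1], 0)
  expect_lt(out2$p[1], 1e-6)
  expect_gt(out2$p[2], 0.001)
  expect_error(quartile_contrast(rep(1, 10), bio2[1:10, , drop = FALSE]),
               "constant")
})

test_that("variance explained tracks the stronger planted score", {
  set.seed(57)
  n <- 6000
  s_strong <- rnorm(n); s_weak <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.5 * s_strong + 0.15 * s_weak))
  r2_strong <- score_r2(s_strong, y, family = "logistic")
  r2_weak <- score_r2(s_weak, y, family = "logistic")
  expect_gt(r2_strong, r2_weak)
})
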