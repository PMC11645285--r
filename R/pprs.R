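#' Partition loci by PDFF-triglyceride sign concordance
#'
#' The hypothesis-driven split at the heart of the package. Each locus lead
#' is oriented to its PDFF-increasing allele; loci whose triglyceride
#' association is significant (`p < alpha_tg`) are assigned to the
#' discordant score when the oriented TG beta is negative (liver
#' triglyceride retention: more liver fat, fewer circulating lipoproteins)
#' and to the concordant score when positive (systemic pathway). Loci that
#' do not associate with triglycerides are excluded. Score weights are the
#' oriented PDFF betas, all positive.
#'
#' @param pdff_assoc data.frame of association records for the locus leads
#'   against PDFF (one row per locus; columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`).
#' @param tg_assoc matching records against circulating triglycerides.
#' @param alpha_tg TG significance threshold for inclusion; default 0.05
#'   (the paper does not print this threshold; exposed as configuration).
#' @return list of class `partition_result`: `discordant` and `concordant`
#'   named weight vectors, `excluded` data.frame (`variant_id`, `reason`),
#'   `orientation` data.frame (`variant_id`, `effect_allele` =
#'   PDFF-increasing allele), and `table` with the oriented betas.
#' @export
partition_by_concordance <- function(pdff_assoc, tg_assoc, alpha_tg = 0.05) {
  stopifnot(alpha_tg > 0, alpha_tg < 1)
  ids <- pdff_assoc$variant_id
  j <- match(ids, tg_assoc$variant_id)
  if (anyNA(j))
    stop("variants missing from TG records: ",
         paste(ids[is.na(j)], collapse = ", "))
  tg <- tg_assoc[j, , drop = FALSE]
  # re-orient TG records onto the PDFF effect allele
  same <- tg$effect_allele == pdff_assoc$effect_allele &
    tg$other_allele == pdff_assoc$other_allele
  flipped <- tg$effect_allele == pdff_assoc$other_allele &
    tg$other_allele == pdff_assoc$effect_allele
  if (any(!same & !flipped))
    stop("allele mismatch that cannot be resolved by swapping: ",
         paste(ids[!same & !flipped], collapse = ", "))
  tg_beta <- ifelse(flipped, -tg$beta, tg$beta)
  # orient every variant to its PDFF-increasing allele
  flip_pdff <- pdff_assoc$beta < 0
  w_pdff <- abs(pdff_assoc$beta)
  tg_beta <- ifelse(flip_pdff, -tg_beta, tg_beta)
  eff <- ifelse(flip_pdff, pdff_assoc$other_allele, pdff_assoc$effect_allele)
  oth <- ifelse(flip_pdff, pdff_assoc$effect_allele, pdff_assoc$other_allele)

  group <- ifelse(tg$p < alpha_tg & tg_beta < 0, "discordant",
           ifelse(tg$p < alpha_tg & tg_beta > 0, "concordant", "excluded"))
  tab <- data.frame(variant_id = ids, group = group,
                    effect_allele = eff, other_allele = oth,
                    weight = w_pdff, tg_beta = tg_beta, tg_p = tg$p,
                    stringsAsFactors = FALSE)
  pick <- function(g) {
    s <- tab[tab$group == g, , drop = FALSE]
    stats::setNames(s$weight, s$variant_id)
  }
  structure(list(
    discordant = pick("discordant"),
    concordant = pick("concordant"),
    excluded = data.frame(
      variant_id = ids[group == "excluded"],
      reason = rep("no TG association", sum(group == "excluded")),
      stringsAsFactors = FALSE),
    orientation = data.frame(variant_id = ids, effect_allele = eff,
                             stringsAsFactors = FALSE),
    table = tab), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition_result:", length(x$discordant), "discordant,",
      length(x$concordant), "concordant,", nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Weighted-sum polygenic score
#'
#' `score_i = sum_v w_v * dosage_iv`, dosages counted on the oriented effect
#' allele. A variant stored in the matrix on the opposite allele contributes
#' `2 - dosage`. Missing dosages are mean-imputed to `2 * EAF` (count
#' reported via attribute `"n_imputed"`); any variant missing in more than
#' 10% of samples is an error.
#'
#' @param gm genotype_matrix.
#' @param weights named numeric vector, variant id -> weight.
#' @param orientation optional data.frame (`variant_id`, `effect_allele`)
#'   giving the allele each weight refers to; default: the matrix's own
#'   effect alleles.
#' @return numeric score per sample (named by sample id).
#' @export
compute_score <- function(gm, weights, orientation = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- names(weights)
  if (is.null(ids) || any(!nzchar(ids))) stop("weights must be named by variant id")
  miss <- setdiff(ids, gm$variants$variant_id)
  if (length(miss)) stop("weighted variants absent: ", paste(miss, collapse = ", "))
  D <- gm$dosages[, ids, drop = FALSE]
  vi <- match(ids, gm$variants$variant_id)
  if (!is.null(orientation)) {
    oi <- match(ids, orientation$variant_id)
    if (anyNA(oi)) stop("orientation missing for: ",
                        paste(ids[is.na(oi)], collapse = ", "))
    want <- orientation$effect_allele[oi]
    have_eff <- gm$variants$effect_allele[vi]
    have_oth <- gm$variants$other_allele[vi]
    flip <- want == have_oth
    bad <- !(want == have_eff | flip)
    if (any(bad)) stop("orientation allele not present at: ",
                       paste(ids[bad], collapse = ", "))
    D[, flip] <- 2 - D[, flip, drop = FALSE]
  }
  frac_missing <- colMeans(is.na(D))
  if (any(frac_missing > 0.1))
    stop(">10% missing dosages for: ",
         paste(ids[frac_missing > 0.1], collapse = ", "))
  n_imputed <- sum(is.na(D))
  if (n_imputed > 0) {
    eaf <- colMeans(D, na.rm = TRUE) / 2
    for (k in which(frac_missing > 0))
      D[is.na(D[, k]), k] <- 2 * eaf[k]
  }
  score <- drop(D %*% weights)
  names(score) <- gm$sample_ids
  attr(score, "n_imputed") <- n_imputed
  score
}

#' Associate a polygenic score with an outcome
#'
#' Standardizes the score to unit SD (effects are per SD of score) and fits
#' either a logistic model for case-control status or a Cox proportional
#' hazards model for incident events, with the supplied covariates. For Cox
#' fits a Schoenfeld-residual proportional-hazards diagnostic is reported.
#'
#' @param score numeric score vector.
#' @param outcome for `model = "logistic"` a 0/1 vector; for `model = "cox"`
#'   ignored (use `time`/`event`).
#' @param covariates data.frame/matrix or NULL.
#' @param model `"logistic"` or `"cox"`.
#' @param time,event follow-up times (> 0) and 0/1 event indicators for Cox
#'   fits; samples with missing time/event (e.g., prevalent cases excluded
#'   upstream) are dropped.
#' @param score_name,outcome_name labels carried into the result.
#' @return list of class `effect_estimate`: `score_name`, `outcome`,
#'   `model`, `beta` (log-OR or log-HR per SD), `se`, `ci95`, `p`,
#'   `n_cases`, `n_total`, `fit`, and `ph_p` (Cox only).
#' @export
outcome_assoc <- function(score, outcome = NULL, covariates = NULL,
                          model = c("logistic", "cox"),
                          time = NULL, event = NULL,
                          score_name = "score", outcome_name = "outcome") {
  model <- match.arg(model)
  n_all <- length(score)
  X <- covariate_design(covariates, n_all)
  s <- standardize(score)
  if (model == "logistic") {
    stopifnot(length(outcome) == n_all)
    keep <- is.finite(s) & is.finite(outcome) & stats::complete.cases(X)
    df <- data.frame(y = outcome[keep], s = s[keep])
    df <- cbind(df, as.data.frame(X[keep, , drop = FALSE]))
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    if (!fit$converged) warning("logistic fit did not converge")
    co <- summary(fit)$coefficients["s", ]
    beta <- co[1]; se <- co[2]; p <- co[4]
    n_cases <- sum(df$y == 1)
    n_total <- nrow(df)
    ph_p <- NA_real_
  } else {
    stopifnot(!is.null(time), !is.null(event),
              length(time) == n_all, length(event) == n_all)
    keep <- is.finite(s) & is.finite(time) & is.finite(event) & time > 0 &
      stats::complete.cases(X)
    df <- data.frame(time = time[keep], event = event[keep], s = s[keep])
    df <- cbind(df, as.data.frame(X[keep, , drop = FALSE]))
    fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
    co <- summary(fit)$coefficients["s", ]
    beta <- co["coef"]; se <- co["se(coef)"]; p <- co["Pr(>|z|)"]
    n_cases <- sum(df$event == 1)
    n_total <- nrow(df)
    ph_p <- tryCatch(survival::cox.zph(fit)$table["s", "p"],
                     error = function(e) NA_real_)
  }
  structure(list(score_name = score_name, outcome = outcome_name,
                 model = model, beta = unname(beta), se = unname(se),
                 ci95 = unname(c(beta - 1.96 * se, beta + 1.96 * se)),
                 p = unname(p), n_cases = n_cases, n_total = n_total,
                 ph_p = ph_p, fit = fit),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- if (x$model == "logistic") "OR" else "HR"
  cat(sprintf("%s ~ %s [%s]: %s = %.3f (95%% CI %.3f-%.3f), P = %.3g, %d/%d cases\n",
              x$outcome, x$score_name, x$model, lab, exp(x$beta),
              exp(x$ci95[1]), exp(x$ci95[2]), x$p, x$n_cases, x$n_total))
  invisible(x)
}

#' Wald comparison of two score effects
#'
#' `W = (b1 - b2) / sqrt(se1^2 + se2^2)`; `W^2` is chi-squared with 1 df
#' under equality of the two effects. Used to ask whether the discordant and
#' concordant scores (or the hypothesis-driven and bNMF scores) carry
#' different risks for the same outcome.
#'
#' @param e1,e2 effect_estimate objects (or lists with `beta`, `se`) for the
#'   same outcome and model.
#' @return list of class `wald_result`: `w`, `w2`, `p`, `df = 1`.
#' @export
wald_compare <- function(e1, e2) {
  if (inherits(e1, "effect_estimate") && inherits(e2, "effect_estimate")) {
    if (!identical(e1$outcome, e2$outcome) || !identical(e1$model, e2$model))
      stop("effects must share outcome and model")
  }
  if (e1$se <= 0 || e2$se <= 0) stop("standard errors must be positive")
  w <- (e1$beta - e2$beta) / sqrt(e1$se^2 + e2$se^2)
  structure(list(w = w, w2 = w^2,
                 p = stats::pchisq(w^2, df = 1, lower.tail = FALSE),
                 df = 1L), class = "wald_result")
}

#' Pairwise AIC comparison of model fits
#'
#' `AIC = 2k - 2 logLik` per fit; entry `(i, j)` of the matrix is
#' `AIC_i - AIC_j` (negative favors model `i`).
#'
#' @param fits named list of fitted models with `logLik` methods (e.g., the
#'   `fit` elements of [outcome_assoc()] results), all on identical samples.
#' @return list: `aic` (named vector) and `delta` (pairwise matrix).
#' @export
aic_compare <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, function(f) stats::nobs(f), numeric(1))
  if (length(unique(ns)) != 1)
    stop("fits use different sample sizes: ", paste(ns, collapse = ", "))
  aic <- vapply(fits, stats::AIC, numeric(1))
  if (is.null(names(aic))) names(aic) <- paste0("fit", seq_along(aic))
  delta <- outer(aic, aic, `-`)
  list(aic = aic, delta = delta)
}

#' Contrast biomarkers between score quartiles
#'
#' Compares each biomarker between samples in the top and bottom quartile of
#' the score (type-7 empirical quantile boundaries) with a two-sided
#' Wilcoxon rank-sum test and a difference of means.
#'
#' @param score numeric score vector, length >= 8, nonconstant.
#' @param biomarkers data.frame of numeric biomarkers (rows aligned to
#'   `score`).
#' @return data.frame: `biomarker`, `mean_top`, `mean_bottom`, `difference`,
#'   `p`, `n_top`, `n_bottom`.
#' @export
quartile_contrast <- function(score, biomarkers) {
  stopifnot(length(score) >= 8)
  if (stats::sd(score, na.rm = TRUE) == 0) stop("constant score")
  qs <- stats::quantile(score, c(0.25, 0.75), na.rm = TRUE, type = 7)
  bottom <- which(score <= qs[1])
  top <- which(score >= qs[2])
  out <- lapply(names(biomarkers), function(b) {
    x <- biomarkers[[b]]
    wt <- stats::wilcox.test(x[top], x[bottom], exact = FALSE)
    data.frame(biomarker = b,
               mean_top = mean(x[top], na.rm = TRUE),
               mean_bottom = mean(x[bottom], na.rm = TRUE),
               difference = mean(x[top], na.rm = TRUE) -
                 mean(x[bottom], na.rm = TRUE),
               p = wt$p.value, n_top = length(top), n_bottom = length(bottom),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Variance explained by a score beyond covariates
#'
#' Nagelkerke pseudo-R-squared gain for logistic outcomes, partial
#' R-squared for linear ones.
#'
#' @param score numeric score vector.
#' @param outcome 0/1 or numeric outcome.
#' @param covariates data.frame/matrix or NULL.
#' @param family `"logistic"` or `"linear"`.
#' @return incremental variance explained (scalar).
#' @export
score_r2 <- function(score, outcome, covariates = NULL,
                     family = c("logistic", "linear")) {
  family <- match.arg(family)
  n <- length(score)
  X <- covariate_design(covariates, n)
  keep <- is.finite(score) & is.finite(outcome) & stats::complete.cases(X)
  s <- standardize(score)[keep]
  y <- outcome[keep]
  Xk <- X[keep, , drop = FALSE]
  if (family == "logistic") {
    nagelkerke <- function(fit, fit0, nn) {
      r2cs <- 1 - exp((stats::deviance(fit) - stats::deviance(fit0)) / nn)
      r2cs / (1 - exp(-stats::deviance(fit0) / nn))
    }
    d0 <- data.frame(y = y)
    if (ncol(Xk)) d0 <- cbind(d0, as.data.frame(Xk))
    fit0 <- stats::glm(y ~ ., data = d0, family = stats::binomial())
    fit1 <- stats::glm(y ~ ., data = cbind(d0, s = s),
                       family = stats::binomial())
    nagelkerke(fit1, fit0, sum(keep)) - 0
  } else {
    d0 <- data.frame(y = y)
    if (ncol(Xk)) d0 <- cbind(d0, as.data.frame(Xk))
    fit0 <- stats::lm(y ~ ., data = d0)
    fit1 <- stats::lm(y ~ ., data = cbind(d0, s = s))
    (stats::deviance(fit0) - stats::deviance(fit1)) / stats::deviance(fit0)
  }
}
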