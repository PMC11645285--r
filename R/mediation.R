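#' Causal mediation analysis for a genetic variant
#'
#' Quantifies how much of a variant's effect on a quantitative liver trait
#' passes through an adiposity mediator, in the potential-outcomes
#' framework. Two linear models are fitted:
#' `mediator ~ exposure + covariates` and
#' `outcome ~ exposure + mediator (+ exposure:mediator) + covariates`.
#' The average causal mediation effect (ACME) and average direct effect
#' (ADE) are computed by counterfactual prediction contrasting exposure
#' levels 0 vs 2 alleles (averaged over the two treatment levels when an
#' interaction is present; for linear models the potential-outcomes
#' estimator has a closed form, so no simulation noise enters the point
#' estimates). Percentile bootstrap confidence intervals are obtained by
#' refitting both models on `n_boot` nonparametric resamples.
#'
#' @param exposure numeric vector (typically an allele dosage).
#' @param mediator numeric vector.
#' @param outcome numeric vector.
#' @param covariates data.frame/matrix or NULL.
#' @param n_boot bootstrap resamples; default 1000.
#' @param interaction include an exposure-by-mediator interaction; default
#'   FALSE.
#' @param treat_levels exposure contrast, default `c(0, 1)` (per-allele
#'   contrast, so in the linear no-interaction case the ACME equals the
#'   product of the fitted path coefficients; use `c(0, 2)` for the
#'   homozygote contrast).
#' @param conf confidence level; default 0.95.
#' @param seed integer seed for the bootstrap.
#' @return list of class `mediation_result`: `acme`, `ade`, `total`,
#'   `prop_mediated`, `ci` (matrix with rows acme/ade/total/prop_mediated),
#'   `n_boot`, `interaction`, `classification`, plus internal model pieces
#'   used by [sensitivity_rho()].
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    n_boot = 1000, interaction = FALSE,
                    treat_levels = c(0, 1), conf = 0.95, seed = 1) {
  n_all <- length(exposure)
  stopifnot(length(mediator) == n_all, length(outcome) == n_all,
            n_boot >= 1, length(treat_levels) == 2)
  X <- covariate_design(covariates, n_all)
  keep <- is.finite(exposure) & is.finite(mediator) & is.finite(outcome) &
    stats::complete.cases(X)
  t_ <- exposure[keep]; m_ <- mediator[keep]; y_ <- outcome[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(t_)
  if (n < 50) stop("need at least 50 complete cases")
  if (stats::var(m_) == 0 || stats::var(y_) == 0)
    stop("mediator or outcome is constant")

  point <- mediate_point(t_, m_, y_, X, interaction, treat_levels)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("acme", "ade", "total",
                                         "prop_mediated")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      mediate_point(t_[idx], m_[idx], y_[idx], X[idx, , drop = FALSE],
                    interaction, treat_levels),
      error = function(e) NULL)
    if (!is.null(est))
      boot[b, ] <- c(est$acme, est$ade, est$total, est$prop_mediated)
  }
  al <- (1 - conf) / 2
  ci <- t(apply(boot, 2, stats::quantile, probs = c(al, 1 - al),
                na.rm = TRUE))
  cls <- classify_mediation(point$acme, point$ade, point$total,
                            acme_ci = ci["acme", ], ade_ci = ci["ade", ],
                            total_ci = ci["total", ])
  structure(list(acme = point$acme, ade = point$ade, total = point$total,
                 prop_mediated = point$prop_mediated, ci = ci,
                 n_boot = n_boot, interaction = interaction,
                 classification = cls, boot = boot,
                 models = point$models, data = list(t = t_, m = m_, y = y_,
                                                    X = X),
                 treat_levels = treat_levels, conf = conf),
            class = "mediation_result")
}

# Point estimates by counterfactual prediction from two linear fits.
mediate_point <- function(t_, m_, y_, X, interaction, treat_levels) {
  t0 <- treat_levels[1]; t1 <- treat_levels[2]
  Xm <- cbind(`(Intercept)` = 1, t = t_, X)
  fit_m <- stats::lm.fit(Xm, m_)
  Xy <- cbind(`(Intercept)` = 1, t = t_, m = m_, X)
  if (interaction) Xy <- cbind(Xy, tm = t_ * m_)
  fit_y <- stats::lm.fit(Xy, y_)
  cm <- fit_m$coefficients
  cy <- fit_y$coefficients
  pred_m <- function(t) {
    Xt <- Xm; Xt[, "t"] <- t
    drop(Xt %*% cm)
  }
  pred_y <- function(t, mhat) {
    Xt <- Xy
    Xt[, "t"] <- t
    Xt[, "m"] <- mhat
    if (interaction) Xt[, "tm"] <- t * mhat
    drop(Xt %*% cy)
  }
  m0 <- pred_m(t0); m1 <- pred_m(t1)
  acme <- mean(c(mean(pred_y(t0, m1) - pred_y(t0, m0)),
                 mean(pred_y(t1, m1) - pred_y(t1, m0))))
  ade <- mean(c(mean(pred_y(t1, m0) - pred_y(t0, m0)),
                mean(pred_y(t1, m1) - pred_y(t0, m1))))
  total <- acme + ade
  list(acme = acme, ade = ade, total = total,
       prop_mediated = if (total != 0) acme / total else NA_real_,
       models = list(mediator = fit_m, outcome = fit_y))
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result (%s):\n", x$classification))
  q <- rbind(acme = x$acme, ade = x$ade, total = x$total,
             prop_mediated = x$prop_mediated)
  for (k in rownames(q))
    cat(sprintf("  %-14s %8.4f  [%.4f, %.4f]\n", k, q[k, 1],
                x$ci[k, 1], x$ci[k, 2]))
  invisible(x)
}

#' Sensitivity of the ACME to unobserved confounding
#'
#' Sequential ignorability assumes no unobserved confounder between
#' mediator and outcome; its violation is indexed by the correlation `rho`
#' between the errors of the mediator and outcome models. For linear models
#' the ACME under a hypothesized `rho` has the closed form
#' `ACME(rho) = a * (sd_y / sd_m) * (rho* - rho * sqrt((1 - rho*^2) / (1 - rho^2)))`
#' where `a` is the exposure effect on the mediator, `rho*` is the observed
#' correlation between the residuals of the mediator model and of an
#' outcome model WITHOUT the mediator, and `sd_m`, `sd_y` are those
#' residual SDs. `ACME(0)` equals the primary estimate and the ACME crosses
#' zero exactly at `rho = rho*`.
#'
#' @param fit mediation_result from [mediate()] with `interaction = FALSE`.
#' @param rho_grid grid of error correlations; default `seq(-0.9, 0.9, 0.05)`.
#' @param n_boot bootstrap resamples for the per-rho CI; default 200.
#' @param seed integer seed.
#' @return list of class `sensitivity_curve`: `rho_grid`, `acme`
#'   (point estimates), `ci` (2-column matrix), `rho_zero` (smallest `|rho|`
#'   whose CI covers zero), `rho_star` (where the estimated ACME itself is
#'   zero).
#' @export
sensitivity_rho <- function(fit, rho_grid = seq(-0.9, 0.9, by = 0.05),
                            n_boot = 200, seed = 1) {
  stopifnot(inherits(fit, "mediation_result"))
  if (fit$interaction)
    stop("sensitivity analysis is defined for models without interaction")
  stopifnot(all(abs(rho_grid) < 1))
  d <- fit$data
  t0 <- fit$treat_levels[1]; t1 <- fit$treat_levels[2]

  acme_rho <- function(t_, m_, y_, X, rho) {
    Xm <- cbind(1, t_, X)
    rm_ <- stats::lm.fit(Xm, m_)
    ry_ <- stats::lm.fit(Xm, y_)  # outcome model without the mediator
    a <- rm_$coefficients[2]
    e_m <- rm_$residuals; e_y <- ry_$residuals
    rho_star <- stats::cor(e_m, e_y)
    s_m <- stats::sd(e_m); s_y <- stats::sd(e_y)
    b_rho <- (s_y / s_m) *
      (rho_star - rho * sqrt((1 - rho_star^2) / (1 - rho^2)))
    (t1 - t0) * a * b_rho
  }

  est <- vapply(rho_grid, function(r)
    acme_rho(d$t, d$m, d$y, d$X, r), numeric(1))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n <- length(d$t)
  bmat <- matrix(NA_real_, n_boot, length(rho_grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bmat[b, ] <- vapply(rho_grid, function(r)
      acme_rho(d$t[idx], d$m[idx], d$y[idx], d$X[idx, , drop = FALSE], r),
      numeric(1))
  }
  al <- (1 - fit$conf) / 2
  ci <- t(apply(bmat, 2, stats::quantile, probs = c(al, 1 - al),
                na.rm = TRUE))
  covers0 <- ci[, 1] <= 0 & ci[, 2] >= 0
  rho_zero <- if (any(covers0)) rho_grid[covers0][
    which.min(abs(rho_grid[covers0]))] else NA_real_
  # analytic zero-crossing of the point estimate
  Xm <- cbind(1, d$t, d$X)
  rho_star <- stats::cor(stats::lm.fit(Xm, d$m)$residuals,
                         stats::lm.fit(Xm, d$y)$residuals)
  structure(list(rho_grid = rho_grid, acme = est, ci = ci,
                 rho_zero = rho_zero, rho_star = rho_star),
            class = "sensitivity_curve")
}

#' Classify a mediation pattern
#'
#' `"none"` if the ACME interval covers 0; `"complete"` if the ADE interval
#' covers 0 but the ACME's does not; `"inconsistent"` if the ACME and total
#' effect have opposite signs with both intervals excluding 0 (partial
#' mediation in the opposite direction); otherwise `"consistent-partial"`.
#'
#' @param acme,ade,total point estimates.
#' @param acme_ci,ade_ci,total_ci length-2 confidence intervals.
#' @return one of `"none"`, `"complete"`, `"inconsistent"`,
#'   `"consistent-partial"`.
#' @export
classify_mediation <- function(acme, ade, total, acme_ci, ade_ci, total_ci) {
  stopifnot(is.finite(acme), is.finite(ade), is.finite(total))
  covers0 <- function(ci) ci[1] <= 0 && ci[2] >= 0
  if (covers0(acme_ci)) return("none")
  if (covers0(ade_ci)) return("complete")
  if (sign(acme) != sign(total) && !covers0(total_ci)) return("inconsistent")
  "consistent-partial"
}
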