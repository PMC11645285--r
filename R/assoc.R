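#' Per-variant association scan
#'
#' Fits, for every variant in `gm`, an additive single-variant model
#' `phenotype ~ dosage + covariates` (linear least squares or logistic
#' maximum likelihood) and returns one association record per variant with
#' the effect per copy of the effect allele, its standard error, a two-sided
#' Wald p-value and the sample size actually used. Samples with a missing
#' phenotype, covariate or dosage are dropped listwise per variant.
#'
#' This is the desk-scale stand-in for a whole-genome regression scan: with
#' no relatedness or polygenic background in the cohort, the per-variant GLM
#' yields the same estimands (beta, SE, P).
#'
#' @param gm genotype_matrix.
#' @param phenotype numeric vector (0/1 for `family = "logistic"`), one entry
#'   per sample.
#' @param covariates data.frame or matrix of numeric covariates, or `NULL`.
#' @param family `"linear"` or `"logistic"`.
#' @param trait,adjustment labels stored in the output records (the
#'   adjustment names which adiposity index, if any, sits in `covariates`).
#' @return data.frame of association records with columns `variant_id`,
#'   `trait`, `adjustment`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `p`, `n`, `flag`. Variants with constant dosage or separation are
#'   flagged (`flag != "ok"`) with `NA` estimates rather than dropped.
#' @export
assoc_scan <- function(gm, phenotype, covariates = NULL,
                       family = c("linear", "logistic"),
                       trait = "trait", adjustment = "none") {
  stopifnot(inherits(gm, "genotype_matrix"))
  family <- match.arg(family)
  n_all <- length(gm$sample_ids)
  if (length(phenotype) != n_all) stop("phenotype length != sample count")
  X <- cbind(`(Intercept)` = rep(1, n_all), covariate_design(covariates, n_all))
  keep <- is.finite(phenotype) & stats::complete.cases(X)
  y <- phenotype[keep]
  X <- X[keep, , drop = FALSE]
  G <- gm$dosages[keep, , drop = FALSE]

  m <- ncol(G)
  beta <- se <- p <- rep(NA_real_, m)
  nvec <- integer(m)
  flag <- rep("ok", m)

  if (family == "linear" && !anyNA(G)) {
    # Frisch-Waugh: residualize once, then vectorized per-variant OLS
    qrX <- qr(X)
    ry <- qr.resid(qrX, y)
    RG <- qr.resid(qrX, G)
    gg <- colSums(RG^2)
    const <- gg < 1e-10
    gy <- colSums(RG * ry)
    df <- length(y) - ncol(X) - 1L
    b <- gy / gg
    rss <- sum(ry^2) - b^2 * gg
    s <- sqrt(pmax(rss, 0) / df / gg)
    tstat <- b / s
    beta <- b
    se <- s
    p <- 2 * stats::pt(-abs(tstat), df)
    nvec[] <- length(y)
    beta[const] <- se[const] <- p[const] <- NA_real_
    flag[const] <- "constant_dosage"
  } else {
    for (j in seq_len(m)) {
      g <- G[, j]
      ok <- is.finite(g)
      gj <- g[ok]
      if (length(gj) < ncol(X) + 2 || stats::var(gj) < 1e-10) {
        flag[j] <- "constant_dosage"
        next
      }
      Xj <- cbind(X[ok, , drop = FALSE], dosage = gj)
      nvec[j] <- length(gj)
      if (family == "linear") {
        fit <- stats::lm.fit(Xj, y[ok])
        df <- length(gj) - fit$rank
        rss <- sum(fit$residuals^2)
        XtXinv <- chol2inv(chol(crossprod(Xj)))
        k <- which(colnames(Xj) == "dosage")
        beta[j] <- fit$coefficients[k]
        se[j] <- sqrt(rss / df * XtXinv[k, k])
        p[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), df)
      } else {
        fit <- suppressWarnings(
          stats::glm.fit(Xj, y[ok], family = stats::binomial()))
        k <- which(colnames(Xj) == "dosage")
        co <- fit$coefficients[k]
        mu <- fit$fitted.values
        if (!fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
          flag[j] <- if (!fit$converged) "nonconverged" else "separation"
        }
        w <- fit$weights
        XtWXinv <- tryCatch(chol2inv(chol(crossprod(Xj * sqrt(w)))),
                            error = function(e) NULL)
        if (is.null(XtWXinv) || !is.finite(co)) {
          flag[j] <- "separation"
          next
        }
        beta[j] <- co
        se[j] <- sqrt(XtWXinv[k, k])
        p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
      }
    }
    if (family == "linear" && anyNA(G)) nvec[flag == "constant_dosage"] <- 0L
  }
  if (family == "linear" && !anyNA(G)) nvec[flag != "ok"] <- length(y)

  data.frame(variant_id = gm$variants$variant_id,
             trait = trait, adjustment = adjustment,
             effect_allele = gm$variants$effect_allele,
             other_allele = gm$variants$other_allele,
             eaf = colMeans(G, na.rm = TRUE) / 2,
             beta = beta, se = se, p = p, n = nvec, flag = flag,
             stringsAsFactors = FALSE)
}

#' Gene-environment interaction scan with HC3 robust errors
#'
#' Fits `phenotype ~ dosage + modifier + dosage:modifier + covariates` per
#' variant and reports the interaction coefficient with an HC3 sandwich
#' standard error, which guards the Wald test against heteroskedasticity
#' (interaction effect sizes are sensitive to the trait scale, so a log
#' transform of the phenotype is supported).
#'
#' @param gm genotype_matrix.
#' @param phenotype numeric vector; must be strictly positive when
#'   `log_phenotype = TRUE`.
#' @param modifier numeric vector (e.g., an adiposity index).
#' @param covariates data.frame/matrix or `NULL`.
#' @param log_phenotype log-transform the phenotype before fitting.
#' @param trait,adjustment labels for the output records.
#' @return data.frame of association records for the interaction term
#'   (columns as [assoc_scan()]).
#' @export
interaction_scan <- function(gm, phenotype, modifier, covariates = NULL,
                             log_phenotype = FALSE,
                             trait = "trait", adjustment = "none") {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_all <- length(gm$sample_ids)
  stopifnot(length(phenotype) == n_all, length(modifier) == n_all)
  if (log_phenotype) {
    if (any(phenotype <= 0, na.rm = TRUE))
      stop("phenotype must be strictly positive for log transform")
    phenotype <- log(phenotype)
  }
  X0 <- cbind(`(Intercept)` = rep(1, n_all),
              covariate_design(covariates, n_all), modifier = modifier)
  keep <- is.finite(phenotype) & stats::complete.cases(X0)
  m <- ncol(gm$dosages)
  beta <- se <- p <- rep(NA_real_, m)
  nvec <- integer(m)
  flag <- rep("ok", m)
  for (j in seq_len(m)) {
    g <- gm$dosages[keep, j]
    ok <- is.finite(g)
    y <- phenotype[keep][ok]
    Xj <- cbind(X0[keep, , drop = FALSE][ok, , drop = FALSE],
                dosage = g[ok], gxe = g[ok] * X0[keep, "modifier"][ok])
    nvec[j] <- length(y)
    if (length(y) < ncol(Xj) + 2 || stats::var(g[ok]) < 1e-10) {
      flag[j] <- "constant_dosage"
      next
    }
    fit <- stats::lm.fit(Xj, y)
    V <- hc3_vcov(Xj, fit$residuals)
    k <- which(colnames(Xj) == "gxe")
    beta[j] <- fit$coefficients[k]
    se[j] <- sqrt(V[k, k])
    p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
  }
  data.frame(variant_id = gm$variants$variant_id,
             trait = trait, adjustment = adjustment,
             effect_allele = gm$variants$effect_allele,
             other_allele = gm$variants$other_allele,
             eaf = colMeans(gm$dosages[keep, , drop = FALSE], na.rm = TRUE) / 2,
             beta = beta, se = se, p = p, n = nvec, flag = flag,
             stringsAsFactors = FALSE)
}

# HC3 sandwich covariance for an OLS fit: (X'X)^-1 X' D X (X'X)^-1 with
# D = diag(e_i^2 / (1 - h_i)^2). Leverages from the thin QR.
hc3_vcov <- function(X, residuals) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  u <- residuals / (1 - pmin(h, 1 - 1e-8))
  bread <- chol2inv(qr.R(qrX))
  meat <- crossprod(X * u)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# Coerce covariates to a numeric matrix aligned to n samples (NULL -> 0 cols)
covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  M <- as.matrix(as.data.frame(covariates))
  storage.mode(M) <- "double"
  if (nrow(M) != n) stop("covariates have ", nrow(M), " rows, expected ", n)
  M
}
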