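#' Rank adiposity indices by penalized regression with nested CV
#'
#' Which adiposity indices independently predict a liver trait? Lasso,
#' ridge and elastic net are compared in a nested cross-validation: the
#' data are split 80/20 into training and test; within the training set an
#' outer CV scores each model family while an inner CV tunes (alpha,
#' lambda) by minimum mean squared error; the winning family is re-tuned on
#' the full training set under 10-fold CV, evaluated once on the held-out
#' 20%, and finally refit on all data. Adiposity predictors are
#' standardized before training and the response is rank-based inverse
#' normal transformed; covariates (age, sex and their interactions) enter
#' unpenalized.
#'
#' @param predictors data.frame of candidate predictors (e.g., BMI, WFM,
#'   VAT, WHR, impedance).
#' @param response numeric liver trait vector.
#' @param covariates data.frame/matrix entering every model unpenalized, or
#'   NULL.
#' @param outer_folds,inner_folds CV folds; default 10 each.
#' @param holdout held-out test fraction; default 0.2.
#' @param alpha_grid elastic-net mixing grid; default `seq(0, 1, 0.1)`.
#' @param families which model families compete; any subset of
#'   `c("L1", "L2", "elastic-net")`.
#' @param rint_response transform the response with
#'   [rank_inverse_normal()]; default TRUE.
#' @param seed integer seed (fold assignment and split).
#' @return list of class `penalized_fit`: `model_kind` ("L1", "L2",
#'   "elastic-net"), `alpha`, `lambda`, `coefficients` (standardized-scale,
#'   ranked by absolute value), `ranking` (predictor names, strongest
#'   first), `cv_mse` (per family), `test_mse`.
#' @export
nested_cv_penalized <- function(predictors, response, covariates = NULL,
                                outer_folds = 10, inner_folds = 10,
                                holdout = 0.2,
                                alpha_grid = seq(0, 1, by = 0.1),
                                families = c("L1", "L2", "elastic-net"),
                                rint_response = TRUE, seed = 1) {
  P <- as.matrix(as.data.frame(predictors))
  storage.mode(P) <- "double"
  n_all <- length(response)
  stopifnot(nrow(P) == n_all, holdout > 0, holdout < 1)
  X0 <- covariate_design(covariates, n_all)
  keep <- is.finite(response) & stats::complete.cases(P) &
    stats::complete.cases(X0)
  P <- P[keep, , drop = FALSE]
  X0 <- X0[keep, , drop = FALSE]
  y <- response[keep]
  if (rint_response) y <- rank_inverse_normal(y)
  n <- length(y)
  if (n < 10 * ncol(P)) stop("need at least 10 samples per predictor")
  sds <- apply(P, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor: ",
                          paste(colnames(P)[sds == 0], collapse = ", "))
  P <- scale(P)
  X <- cbind(P, X0)
  pf <- c(rep(1, ncol(P)), rep(0, ncol(X0)))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  test_idx <- sample.int(n, round(holdout * n))
  train_idx <- setdiff(seq_len(n), test_idx)
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  folds <- sample(rep_len(seq_len(outer_folds), length(train_idx)))

  inner_tune <- function(Xi, yi, alphas) {
    best <- NULL
    fold_id <- sample(rep_len(seq_len(inner_folds), length(yi)))
    for (a in alphas) {
      cv <- glmnet::cv.glmnet(Xi, yi, alpha = a, penalty.factor = pf,
                              standardize = FALSE, foldid = fold_id,
                              thresh = 1e-10)
      mse <- min(cv$cvm)
      if (is.null(best) || mse < best$mse)
        best <- list(alpha = a, lambda = cv$lambda.min, mse = mse)
    }
    best
  }

  all_fams <- list(L1 = 1, L2 = 0, `elastic-net` = alpha_grid)
  families <- all_fams[match.arg(families, names(all_fams),
                                 several.ok = TRUE)]
  cv_mse <- vapply(families, function(alphas) {
    errs <- vapply(seq_len(outer_folds), function(f) {
      hold <- folds == f
      tuned <- inner_tune(Xtr[!hold, , drop = FALSE], ytr[!hold], alphas)
      fit <- glmnet::glmnet(Xtr[!hold, , drop = FALSE], ytr[!hold],
                            alpha = tuned$alpha, lambda = tuned$lambda,
                            penalty.factor = pf, standardize = FALSE,
                            thresh = 1e-10)
      mean((ytr[hold] - drop(stats::predict(fit,
                                            Xtr[hold, , drop = FALSE])))^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))

  winner <- names(cv_mse)[which.min(cv_mse)]
  tuned <- inner_tune(Xtr, ytr, families[[winner]])
  fit_tr <- glmnet::glmnet(Xtr, ytr, alpha = tuned$alpha,
                           lambda = tuned$lambda, penalty.factor = pf,
                           standardize = FALSE, thresh = 1e-10)
  test_mse <- mean((y[test_idx] -
                    drop(stats::predict(fit_tr,
                                        X[test_idx, , drop = FALSE])))^2)
  fit_all <- glmnet::glmnet(X, y, alpha = tuned$alpha, lambda = tuned$lambda,
                            penalty.factor = pf, standardize = FALSE,
                            thresh = 1e-10)
  co <- as.matrix(stats::coef(fit_all))[, 1][colnames(P)]
  ranking <- names(sort(abs(co), decreasing = TRUE))
  structure(list(model_kind = winner, alpha = tuned$alpha,
                 lambda = tuned$lambda,
                 coefficients = co[ranking], ranking = ranking,
                 cv_mse = cv_mse, test_mse = test_mse),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("penalized_fit: %s (alpha = %.2f, lambda = %.4g), test MSE %.4g\n",
              x$model_kind, x$alpha, x$lambda, x$test_mse))
  cat("standardized coefficients (ranked):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}
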