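#' Build a nonnegative variant-trait z-score matrix
#'
#' Constructs the input for bNMF soft clustering: per variant and trait,
#' `z = beta / se`, scaled by `sqrt(median(N) / N_trait)` to equalize
#' sample-size differences across trait GWAS; each variant's row is
#' sign-flipped so the alignment trait's z is positive (PDFF-increasing
#' orientation); each trait column is then split into nonnegative positive
#' and negative parts (`trait_pos`, `trait_neg`). One trait of each pair
#' with absolute correlation above `corr_prune` is dropped (first by input
#' order kept).
#'
#' @param assoc_by_trait named list: trait -> data.frame of association
#'   records (`variant_id`, `beta`, `se`, `n`). All traits must cover the
#'   alignment trait's variants.
#' @param align_trait trait used for allele alignment; default `"pdff"`.
#' @param corr_prune drop one of each trait pair whose z-score columns are
#'   correlated beyond this; default 0.85.
#' @param trait_corr optional pre-computed trait correlation matrix
#'   (dimnames = traits); default: correlation of the signed z columns.
#' @return list of class `z_matrix`: `z` (nonnegative matrix, rows variants,
#'   columns `<trait>_pos`/`<trait>_neg`), `signed` (aligned signed z),
#'   `dropped_traits`, `flipped` (logical per variant).
#' @export
build_z_matrix <- function(assoc_by_trait, align_trait = "pdff",
                           corr_prune = 0.85, trait_corr = NULL) {
  stopifnot(is.list(assoc_by_trait), length(assoc_by_trait) >= 1,
            align_trait %in% names(assoc_by_trait))
  ids <- assoc_by_trait[[align_trait]]$variant_id
  traits <- names(assoc_by_trait)
  Z <- matrix(NA_real_, length(ids), length(traits),
              dimnames = list(ids, traits))
  nmed <- stats::median(vapply(assoc_by_trait, function(a)
    stats::median(a$n), numeric(1)))
  for (tr in traits) {
    a <- assoc_by_trait[[tr]]
    j <- match(ids, a$variant_id)
    if (anyNA(j)) stop("trait ", tr, " missing records for: ",
                       paste(ids[is.na(j)], collapse = ", "))
    if (any(a$se[j] <= 0, na.rm = TRUE)) stop("non-positive SE in trait ", tr)
    Z[, tr] <- a$beta[j] / a$se[j] * sqrt(nmed / stats::median(a$n[j]))
  }
  flipped <- Z[, align_trait] < 0
  Z[flipped, ] <- -Z[flipped, , drop = FALSE]
  # prune highly correlated traits (keep the earlier one)
  if (is.null(trait_corr))
    trait_corr <- suppressWarnings(stats::cor(Z))  # constant cols -> NA, skipped
  dropped <- character(0)
  keep <- traits
  for (i in seq_along(traits)) for (j in seq_along(traits)) {
    if (j <= i) next
    cval <- trait_corr[traits[i], traits[j]]
    if (is.finite(cval) && traits[i] %in% keep && traits[j] %in% keep &&
        abs(cval) > corr_prune) {
      keep <- setdiff(keep, traits[j])
      dropped <- c(dropped, traits[j])
    }
  }
  Zk <- Z[, keep, drop = FALSE]
  pos <- pmax(Zk, 0)
  neg <- pmax(-Zk, 0)
  colnames(pos) <- paste0(keep, "_pos")
  colnames(neg) <- paste0(keep, "_neg")
  V <- cbind(pos, neg)[, order(rep(seq_along(keep), 2)), drop = FALSE]
  structure(list(z = V, signed = Zk, dropped_traits = dropped,
                 flipped = flipped), class = "z_matrix")
}

#' Bayesian NMF with automatic relevance determination
#'
#' Factorizes a nonnegative matrix `V ~ W H` under a squared-Frobenius
#' likelihood with per-component relevance scales `lambda_k` carrying
#' inverse-gamma-type hyperpriors. Multiplicative updates shrink the scales
#' of unneeded components to the prior floor, so the effective number of
#' clusters is learned rather than fixed; over many random restarts the
#' modal effective K is selected and the best-posterior restart at that K is
#' returned.
#'
#' Objective (negative log posterior, up to constants):
#' `||V - WH||^2 / (2 phi) + sum_k [(||W_k||^2 + ||H_k||^2)/2 + b0] / lambda_k
#'  + ((M + N)/2 + a0 + 1) * sum_k log lambda_k`,
#' with `phi = var(V)`, `a0 = 10`, and `b0` set from the data scale. Each
#' update (W, H multiplicative; lambda closed form) decreases the objective.
#'
#' @param z z_matrix from [build_z_matrix()], or a nonnegative matrix.
#' @param k_max maximum number of components; default 7.
#' @param n_restarts random restarts; default 1000.
#' @param tol relative objective change declaring convergence; default 1e-7.
#' @param max_iter iteration cap per restart; default 2000.
#' @param noise_var likelihood noise variance `phi`; default `var(V)`, the
#'   usual conservative ARD convention.
#' @param seed master seed; restart seeds are derived from it.
#' @return list of class `bnmf_result`: `w` (variants x K), `h` (K x
#'   traits), `k_selected` (modal effective K), `objective`, `restart_log`
#'   (data.frame: restart, seed, k_effective, objective), `lambda`.
#' @export
bnmf_fit <- function(z, k_max = 7, n_restarts = 1000, tol = 1e-7,
                     max_iter = 2000, noise_var = NULL, seed = 1) {
  V <- if (inherits(z, "z_matrix")) z$z else as.matrix(z)
  if (is.null(noise_var)) noise_var <- stats::var(as.vector(V))
  if (any(V < 0)) stop("matrix must be nonnegative")
  if (all(V == 0)) stop("all-zero matrix")
  if (is.null(rownames(V))) rownames(V) <- paste0("v", seq_len(nrow(V)))
  if (is.null(colnames(V))) colnames(V) <- paste0("t", seq_len(ncol(V)))
  # normalize the overall scale so the fit (and the selected K) is invariant
  # to multiplying the input by a constant; factors are rescaled on return
  v_scale <- mean(V[V > 0])
  V <- V / v_scale
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  N <- nrow(V); M <- ncol(V)
  a0 <- 10
  phi <- noise_var / v_scale^2
  b0 <- sqrt((a0 - 1) * (a0 - 2) * mean(V) / k_max)
  Cconst <- (N + M) / 2 + a0 + 1
  lambda_floor <- b0 / Cconst
  eps <- .Machine$double.eps

  run_one <- function(rseed) {
    set.seed(rseed)
    W <- matrix(stats::runif(N * k_max) * sqrt(mean(V)), N, k_max)
    H <- matrix(stats::runif(k_max * M) * sqrt(mean(V)), k_max, M)
    lambda <- (0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b0) / Cconst
    obj_of <- function(W, H, lambda) {
      sum((V - W %*% H)^2) / (2 * phi) +
        sum(((0.5 * colSums(W^2) + 0.5 * rowSums(H^2)) + b0) / lambda) +
        Cconst * sum(log(lambda))
    }
    obj <- obj_of(W, H, lambda)
    trace <- obj
    for (it in seq_len(max_iter)) {
      WH <- W %*% H
      H <- H * crossprod(W, V) /
        (crossprod(W, WH) + phi * H / lambda + eps)
      WH <- W %*% H
      W <- W * tcrossprod(V, H) /
        (tcrossprod(WH, H) + phi * sweep(W, 2, lambda, `/`) + eps)
      lambda <- (0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b0) / Cconst
      new_obj <- obj_of(W, H, lambda)
      trace <- c(trace, new_obj)
      if (is.finite(obj) && abs(obj - new_obj) <= tol * abs(obj)) {
        obj <- new_obj
        break
      }
      obj <- new_obj
    }
    k_eff <- sum(lambda > lambda_floor * 1.05)
    list(W = W, H = H, lambda = lambda, objective = obj,
         k_effective = max(k_eff, 1L), trace = trace)
  }

  set.seed(seed)
  rseeds <- sample.int(.Machine$integer.max, n_restarts)
  runs <- lapply(rseeds, run_one)
  ks <- vapply(runs, function(r) as.integer(r$k_effective), integer(1))
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  k_tab <- table(ks)
  k_selected <- as.integer(names(k_tab)[which.max(k_tab)])
  at_k <- which(ks == k_selected)
  best <- at_k[which.min(objs[at_k])]
  fit <- runs[[best]]
  keep <- order(fit$lambda, decreasing = TRUE)[seq_len(k_selected)]
  W <- fit$W[, keep, drop = FALSE] * sqrt(v_scale)
  H <- fit$H[keep, , drop = FALSE] * sqrt(v_scale)
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  colnames(W) <- rownames(H) <- paste0("cluster", seq_len(k_selected))
  structure(list(w = W, h = H, k_selected = k_selected,
                 objective = fit$objective, lambda = fit$lambda[keep],
                 objective_trace = fit$trace,
                 restart_log = data.frame(restart = seq_len(n_restarts),
                                          seed = rseeds, k_effective = ks,
                                          objective = objs)),
            class = "bnmf_result")
}

#' @export
print.bnmf_result <- function(x, ...) {
  k_share <- mean(x$restart_log$k_effective == x$k_selected)
  cat(sprintf("bnmf_result: modal K = %d (%.0f%% of %d restarts), objective %.4g\n",
              x$k_selected, 100 * k_share, nrow(x$restart_log), x$objective))
  invisible(x)
}

#' Extract soft cluster memberships via a signal-to-noise cutoff
#'
#' Membership is decided on each variant's relative cluster affinity: with
#' two or more clusters the rows of the weight matrix are normalized to sum
#' to one (a variant's soft membership profile), so a weakly associated
#' variant that clearly belongs to one cluster is not penalized for its
#' small absolute weight. A cutoff on the pooled (normalized) weights is
#' chosen to maximize the separation between the "background" and "signal"
#' classes — the between-class variance
#' `n_lo * n_hi * (mean_hi - mean_lo)^2` (Otsu's criterion) over a grid of
#' candidate cutoffs (midpoints between sorted unique weights). Variants
#' above the cutoff in a cluster are members; a variant can exceed the
#' cutoff in several clusters (soft clustering). With a single cluster the
#' raw weights are used (relative affinity is undefined). The reported
#' `snr` is the realized mean-above / mean-below ratio at the chosen
#' cutoff. Cluster names are the two top-weighted trait-direction labels.
#'
#' @param result bnmf_result.
#' @return list of class `bnmf_clusters`: `memberships` (named list:
#'   cluster -> data.frame `variant_id`, `weight`), `names` (two
#'   top-weighted trait labels per cluster), `cutoff`, `snr`.
#' @export
extract_clusters <- function(result) {
  stopifnot(inherits(result, "bnmf_result"))
  W <- result$w
  if (ncol(W) >= 2) {
    rs <- rowSums(W)
    W <- W / ifelse(rs > 0, rs, 1)
  }
  pooled <- sort(unique(as.vector(W)))
  if (length(pooled) < 2) {
    warning("degenerate all-equal weights: all variants in every cluster")
    members <- lapply(seq_len(ncol(W)), function(k)
      data.frame(variant_id = rownames(W), weight = W[, k],
                 stringsAsFactors = FALSE))
    names(members) <- colnames(W)
    return(structure(list(memberships = members,
                          names = rep(NA_character_, ncol(W)),
                          cutoff = NA_real_, snr = NA_real_),
                     class = "bnmf_clusters"))
  }
  grid <- (pooled[-1] + pooled[-length(pooled)]) / 2
  all_w <- as.vector(W)
  sep_at <- vapply(grid, function(cut) {
    hi <- all_w[all_w > cut]; lo <- all_w[all_w <= cut]
    if (!length(hi) || !length(lo)) return(NA_real_)
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  if (all(!is.finite(sep_at))) stop("no valid separation cutoff")
  cutoff <- grid[which.max(sep_at)]
  snr <- mean(all_w[all_w > cutoff]) / max(mean(all_w[all_w <= cutoff]),
                                           .Machine$double.eps)
  members <- lapply(seq_len(ncol(W)), function(k) {
    keep <- which(W[, k] > cutoff)
    data.frame(variant_id = rownames(W)[keep], weight = W[keep, k],
               stringsAsFactors = FALSE)
  })
  names(members) <- colnames(W)
  cl_names <- vapply(seq_len(nrow(result$h)), function(k) {
    top <- order(result$h[k, ], decreasing = TRUE)[1:2]
    paste(colnames(result$h)[top], collapse = "/")
  }, character(1))
  structure(list(memberships = members, names = cl_names,
                 cutoff = cutoff, snr = snr),
            class = "bnmf_clusters")
}

#' Build per-cluster score weights from memberships
#'
#' Emits weight maps consumable by [compute_score()], one per cluster, using
#' the (adiposity-adjusted) PDFF effect of each member variant as the
#' weight. A variant in several clusters contributes to each of their
#' scores.
#'
#' @param clusters bnmf_clusters from [extract_clusters()].
#' @param pdff_weights named numeric vector, variant id -> PDFF weight.
#' @return named list: cluster -> named weight vector.
#' @export
cluster_pprs <- function(clusters, pdff_weights) {
  stopifnot(inherits(clusters, "bnmf_clusters"))
  lapply(clusters$memberships, function(mem) {
    if (!nrow(mem)) {
      warning("empty cluster: empty weight map")
      return(stats::setNames(numeric(0), character(0)))
    }
    miss <- setdiff(mem$variant_id, names(pdff_weights))
    if (length(miss)) stop("member without PDFF weight: ",
                           paste(miss, collapse = ", "))
    pdff_weights[mem$variant_id]
  })
}
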