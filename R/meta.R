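#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Pools per-study effect estimates with weights `1/se^2`:
#' `pooled_beta = sum(b/se^2) / sum(1/se^2)`, `pooled_se = 1/sqrt(sum(1/se^2))`,
#' with a two-sided normal p-value and Cochran's Q heterogeneity statistic.
#'
#' @param beta numeric vector of study effects.
#' @param se numeric vector of study standard errors, all > 0.
#' @return list of class `meta_result`: `pooled_beta`, `pooled_se`, `p`,
#'   `k_studies`, `q_het`, `q_p`, `per_study` (data.frame beta/se/weight).
#' @examples
#' ivw_meta(c(0.1, 0.3), c(0.1, 0.1))$pooled_beta  # 0.2
#' @export
ivw_meta <- function(beta, se) {
  if (length(beta) == 0) stop("no studies supplied")
  stopifnot(length(beta) == length(se), all(is.finite(beta)),
            all(is.finite(se)), all(se > 0))
  w <- 1 / se^2
  pooled_beta <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - pooled_beta)^2)
  k <- length(beta)
  structure(list(
    pooled_beta = pooled_beta,
    pooled_se = pooled_se,
    p = 2 * stats::pnorm(-abs(pooled_beta / pooled_se)),
    k_studies = k,
    q_het = q,
    q_p = if (k > 1) stats::pchisq(q, k - 1, lower.tail = FALSE) else NA_real_,
    per_study = data.frame(beta = beta, se = se, weight = w / sum(w))),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("IVW fixed-effect meta-analysis: k = %d\n", x$k_studies))
  cat(sprintf("  pooled beta = %.4g (SE %.4g), P = %.3g\n",
              x$pooled_beta, x$pooled_se, x$p))
  if (x$k_studies > 1)
    cat(sprintf("  Cochran Q = %.3g (P = %.3g)\n", x$q_het, x$q_p))
  invisible(x)
}

#' Select an LD proxy for a lead variant
#'
#' When a lead variant is unavailable in a replication cohort, the best
#' in-sample proxy is the variant with the highest dosage r-squared with the
#' lead, above `r2_min`, within `window_bp` of it. Ties are broken by smaller
#' distance, then lexicographic variant id (annotation-based ranking by
#' functional consequence is out of scope here).
#'
#' @param gm genotype_matrix.
#' @param target lead variant id (must be present).
#' @param r2_min minimum r-squared; default 0.4.
#' @param window_bp search window in base pairs around the lead; default
#'   1.5e6.
#' @return the proxy variant id, or `NA_character_` if no candidate passes.
#' @export
select_proxy <- function(gm, target, r2_min = 0.4, window_bp = 1.5e6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  i <- match(target, v$variant_id)
  if (is.na(i)) stop("target variant not found: ", target)
  cand <- which(v$chrom == v$chrom[i] &
                abs(v$pos - v$pos[i]) <= window_bp &
                v$variant_id != target)
  if (!length(cand)) return(NA_character_)
  r2 <- vapply(v$variant_id[cand], function(id)
    tryCatch(ld_r2(gm, target, id), error = function(e) NA_real_), numeric(1))
  keep <- which(is.finite(r2) & r2 > r2_min)
  if (!length(keep)) return(NA_character_)
  cand <- cand[keep]; r2 <- r2[keep]
  dist <- abs(v$pos[cand] - v$pos[i])
  ord <- order(-r2, dist, v$variant_id[cand])
  v$variant_id[cand[ord[1]]]
}
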