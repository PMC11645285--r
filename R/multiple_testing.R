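#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 19535)  # 2.56e-06
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(m) != 1 || m < 1 || m != as.integer(m))
    stop("m must be a positive integer count")
  alpha / m
}

#' Benjamini-Hochberg step-up discovery flags
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param q target false discovery rate.
#' @return logical vector: TRUE where the hypothesis is rejected at FDR `q`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(p > 0 & p <= 1), q > 0, q < 1)
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  thresh <- q * seq_len(m) / m
  passed <- which(p[ord] <= thresh)
  flags <- logical(m)
  if (length(passed)) flags[ord[seq_len(max(passed))]] <- TRUE
  flags
}

#' One-sided Fisher's exact test for enrichment
#'
#' Upper-tail hypergeometric probability that the top-left cell of a 2x2
#' contingency table is at least as large as observed, margins fixed. Used for
#' overlap-enrichment questions (e.g., do liver-fat loci overlap ALT loci more
#' than chance?).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return one-sided p-value.
#' @export
fisher_one_sided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  a <- tab[1, 1]
  m <- sum(tab[1, ])        # white balls: row-1 margin
  n <- sum(tab[2, ])        # black balls
  k <- sum(tab[, 1])        # draws: column-1 margin
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  # P(X >= a) for X ~ Hypergeom(m, n, k)
  stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
}
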