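#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their Blom-offset rank scores,
#' `qnorm((r - c) / (n + 1 - 2c))` with offset `c = 3/8` by default and ties
#' given average ranks. Standard pre-processing for quantitative traits before
#' genetic association scans: it removes skew and makes per-allele effects
#' comparable across traits on an SD scale.
#'
#' @param values numeric vector, length >= 3 after dropping non-finite
#'   entries. `NA`s propagate to the output.
#' @param offset Blom constant `c` in `[0, 0.5)`; default `3/8`.
#' @return numeric vector of the same length as `values`.
#' @examples
#' rank_inverse_normal(c(1, 2, 3))
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  stopifnot(is.numeric(values), offset >= 0, offset < 0.5)
  ok <- is.finite(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 finite values")
  v <- values[ok]
  if (diff(range(v)) == 0)
    stop("all finite values identical: ranks are degenerate")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  out
}

#' Standardize a numeric vector to zero mean and unit SD
#' @param x numeric vector (NAs kept).
#' @return standardized vector.
#' @keywords internal
standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x, na.rm = TRUE)) / s
}
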