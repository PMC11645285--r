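#' Construct a genotype dosage matrix
#'
#' A `genotype_matrix` holds additive allele dosages in `[0, 2]` for
#' `n_samples x n_variants`, together with per-variant metadata. Dosages are
#' counted on the effect allele (A1); all downstream effect sizes are per A1
#' copy. Positions are 1-based (VCF convention).
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   `NA` encodes a missing dosage. Column names must match
#'   `variants$variant_id`; row names are sample ids.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` and optionally `eaf`. If `eaf` is
#'   missing it is computed from the dosages.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0, 1, 2, 2, 0, 1), nrow = 3,
#'          dimnames = list(paste0("s", 1:3), c("v1", "v2"))),
#'   data.frame(variant_id = c("v1", "v2"), chrom = c("1", "1"),
#'              pos = c(1000L, 2000L), effect_allele = c("A", "T"),
#'              other_allele = c("G", "C")))
#' dim(gm$dosages)
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.data.frame(variants))
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != variant rows (",
         nrow(variants), ")")
  if (anyDuplicated(variants$variant_id))
    stop("duplicated variant ids: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$variant_id
  if (!identical(colnames(dosages), as.character(variants$variant_id)))
    stop("dosage column names do not match variant ids")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("sample_%d", seq_len(nrow(dosages)))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  # positions strictly increasing within chromosome (keeps window logic sane)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  if (is.null(variants$eaf))
    variants$eaf <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(dosages = dosages,
                 variants = variants,
                 sample_ids = rownames(dosages)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss) cat("missing dosages:", nmiss, "\n")
  invisible(x)
}

#' Subset a genotype matrix by variant id
#'
#' @param gm genotype_matrix.
#' @param ids character vector of variant ids to keep (order preserved).
#' @return genotype_matrix restricted to `ids`.
#' @export
subset_variants <- function(gm, ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- setdiff(ids, gm$variants$variant_id)
  if (length(miss))
    stop("variants absent from matrix: ", paste(miss, collapse = ", "))
  idx <- match(ids, gm$variants$variant_id)
  v <- gm$variants[idx, , drop = FALSE]
  rownames(v) <- NULL
  # re-sorting by (chrom, pos) keeps the strict-position invariant
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  genotype_matrix(gm$dosages[, v$variant_id, drop = FALSE], v)
}

#' Extract one variant's dosage vector
#' @param gm genotype_matrix.
#' @param id variant id.
#' @return numeric dosage vector (length n_samples).
#' @export
dosage <- function(gm, id) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!id %in% gm$variants$variant_id) stop("variant not found: ", id)
  gm$dosages[, id]
}
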