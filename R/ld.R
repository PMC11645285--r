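#' Dosage-based LD r-squared between two variants
#'
#' Squared Pearson correlation of the two dosage vectors over samples
#' non-missing for both. All LD in this package is computed from the in-run
#' genotype matrix (no external reference panel).
#'
#' @param gm genotype_matrix.
#' @param a,b variant ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(gm, a, b) {
  x <- dosage(gm, a)
  y <- dosage(gm, b)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 jointly observed samples")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant dosage vector: LD undefined")
  stats::cor(x, y)^2
}

#' Greedy LD clumping of an association scan
#'
#' Reduces genome-wide significant variants to approximately independent
#' leads, PLINK-style: significant variants (`p < p1`) are sorted by
#' ascending p-value (ties by position, then id); the best remaining variant
#' becomes a lead and claims every unassigned significant variant within
#' `kb` kilobases with dosage r-squared >= `r2`.
#'
#' @param assoc data.frame of association records (needs `variant_id`, `p`).
#' @param gm genotype_matrix containing all scanned variants.
#' @param p1 index-variant significance threshold; default `5e-8`.
#' @param r2 clumping r-squared threshold (members have r2 >= this);
#'   default 0.01.
#' @param kb clumping window in kilobases; default 1000.
#' @return character vector of lead variant ids (in claim order), with
#'   attribute `"members"`: a named list mapping each lead to the variant
#'   ids of its clump (lead included).
#' @export
clump <- function(assoc, gm, p1 = 5e-8, r2 = 0.01, kb = 1000) {
  stopifnot(inherits(gm, "genotype_matrix"), p1 > 0, p1 < 1, r2 > 0, r2 < 1,
            kb > 0)
  miss <- setdiff(assoc$variant_id, gm$variants$variant_id)
  if (length(miss))
    stop("assoc variants absent from genotype matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  sig <- assoc[is.finite(assoc$p) & assoc$p < p1, , drop = FALSE]
  if (!nrow(sig)) {
    out <- character(0)
    attr(out, "members") <- list()
    return(out)
  }
  vi <- match(sig$variant_id, gm$variants$variant_id)
  sig$chrom <- gm$variants$chrom[vi]
  sig$pos <- gm$variants$pos[vi]
  sig <- sig[order(sig$p, sig$pos, sig$variant_id), , drop = FALSE]
  unassigned <- rep(TRUE, nrow(sig))
  leads <- character(0)
  members <- list()
  while (any(unassigned)) {
    i <- which(unassigned)[1]
    lead <- sig$variant_id[i]
    unassigned[i] <- FALSE
    near <- which(unassigned &
                  sig$chrom == sig$chrom[i] &
                  abs(sig$pos - sig$pos[i]) <= kb * 1000)
    claimed <- character(0)
    for (j in near) {
      if (ld_r2(gm, lead, sig$variant_id[j]) >= r2) {
        claimed <- c(claimed, sig$variant_id[j])
        unassigned[j] <- FALSE
      }
    }
    leads <- c(leads, lead)
    members[[lead]] <- c(lead, claimed)
  }
  attr(leads, "members") <- members
  leads
}

#' Stepwise conditional selection of independent variants
#'
#' Identifies statistically independent association signals among candidate
#' variants by forward selection on individual-level data: at each step the
#' candidate with the smallest p-value conditional on already-selected
#' variants within `window_bp` is added while that p-value is below
#' `p_thresh`; a backward pass then drops any selected variant whose joint
#' p-value exceeds the threshold.
#'
#' @param gm genotype_matrix.
#' @param phenotype numeric vector.
#' @param covariates data.frame/matrix or NULL.
#' @param candidates variant ids to consider (must be in `gm`).
#' @param p_thresh selection threshold; default `5e-8`.
#' @param window_bp LD window: only selected variants within this distance
#'   of a candidate are conditioned on; default 10 Mb.
#' @return character vector of selected variant ids (selection order).
#' @export
stepwise_conditional <- function(gm, phenotype, covariates = NULL,
                                 candidates, p_thresh = 5e-8,
                                 window_bp = 1e7) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- setdiff(candidates, gm$variants$variant_id)
  if (length(miss))
    stop("candidates absent from matrix: ", paste(miss, collapse = ", "))
  v <- gm$variants
  pos_of <- function(id) v$pos[match(id, v$variant_id)]
  chr_of <- function(id) v$chrom[match(id, v$variant_id)]
  selected <- character(0)
  remaining <- candidates
  n <- length(gm$sample_ids)
  base_cov <- covariate_design(covariates, n)

  cond_p <- function(id) {
    in_window <- selected[chr_of(selected) == chr_of(id) &
                          abs(pos_of(selected) - pos_of(id)) <= window_bp]
    covs <- base_cov
    if (length(in_window))
      covs <- cbind(covs, gm$dosages[, in_window, drop = FALSE])
    sub <- subset_variants(gm, id)
    rec <- assoc_scan(sub, phenotype, covs, family = "linear")
    rec$p[1]
  }

  while (length(remaining)) {
    ps <- vapply(remaining, cond_p, numeric(1))
    ps[!is.finite(ps)] <- 1  # collinear with selected set: skip
    best <- which.min(ps)
    if (ps[best] >= p_thresh) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }

  # backward pass on joint model
  repeat {
    if (length(selected) < 2) break
    Xsel <- gm$dosages[, selected, drop = FALSE]
    joint_p <- vapply(seq_along(selected), function(k) {
      covs <- cbind(base_cov, Xsel[, -k, drop = FALSE])
      rec <- assoc_scan(subset_variants(gm, selected[k]), phenotype, covs,
                        family = "linear")
      rec$p[1]
    }, numeric(1))
    worst <- which.max(joint_p)
    if (joint_p[worst] <= p_thresh) break
    warning("dropping ", selected[worst], " in backward pass (joint P = ",
            signif(joint_p[worst], 3), ")")
    selected <- selected[-worst]
  }
  selected
}

#' Merge lead variants across traits and adjustments into pleiotropic loci
#'
#' Builds a graph over all supplied lead variants with an edge whenever two
#' leads lie on the same chromosome within `dist_bp` of each other and have
#' dosage r-squared strictly greater than `r2_min`; connected components
#' become loci with consecutive ids ordered by genomic position. Within each
#' locus the member with the lowest p-value per trait is that trait's lead
#' (ties broken by trait name order, then position, then id).
#'
#' @param leads data.frame of association records for lead variants across
#'   scans (columns `variant_id`, `trait`, `adjustment`, `p`); the same
#'   variant may appear under several scans.
#' @param gm genotype_matrix containing all leads.
#' @param dist_bp merge distance; default 1 Mb.
#' @param r2_min LD threshold (edges require r2 > this); default 0.2.
#' @return list with elements `loci` (data.frame: `locus_id`, `chrom`,
#'   `span_start`, `span_end`, `members` comma-joined) and `lead_by_trait`
#'   (data.frame: `locus_id`, `trait`, `variant_id`, `p`).
#' @export
merge_pleiotropic <- function(leads, gm, dist_bp = 1e6, r2_min = 0.2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- sort(unique(leads$variant_id))
  miss <- setdiff(ids, gm$variants$variant_id)
  if (length(miss))
    stop("leads absent from genotype matrix: ", paste(miss, collapse = ", "))
  vi <- match(ids, gm$variants$variant_id)
  chrom <- gm$variants$chrom[vi]
  pos <- gm$variants$pos[vi]
  k <- length(ids)
  parent <- seq_len(k)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= dist_bp &&
        ld_r2(gm, ids[i], ids[j]) > r2_min) {
      ri <- findr(i); rj <- findr(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(k), findr, integer(1))
  groups <- split(seq_len(k), comp)
  # order loci by (chrom, min pos) for deterministic consecutive ids
  ord <- order(vapply(groups, function(g) chrom[g[1]], chrom[1]),
               vapply(groups, function(g) min(pos[g]), numeric(1)))
  groups <- groups[ord]
  loci <- data.frame(
    locus_id = seq_along(groups),
    chrom = vapply(groups, function(g) chrom[g[1]], chrom[1]),
    span_start = vapply(groups, function(g) min(pos[g]), numeric(1)),
    span_end = vapply(groups, function(g) max(pos[g]), numeric(1)),
    members = vapply(groups, function(g)
      paste(ids[g][order(pos[g])], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  lead_rows <- list()
  for (li in seq_along(groups)) {
    member_ids <- ids[groups[[li]]]
    sub <- leads[leads$variant_id %in% member_ids, , drop = FALSE]
    for (tr in sort(unique(sub$trait))) {
      st <- sub[sub$trait == tr, , drop = FALSE]
      st_pos <- pos[match(st$variant_id, ids)]
      pick <- order(st$p, st_pos, st$variant_id)[1]
      lead_rows[[length(lead_rows) + 1L]] <- data.frame(
        locus_id = li, trait = tr, variant_id = st$variant_id[pick],
        p = st$p[pick], stringsAsFactors = FALSE)
    }
  }
  list(loci = loci,
       lead_by_trait = do.call(rbind, c(lead_rows,
                                        make.row.names = FALSE)))
}
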