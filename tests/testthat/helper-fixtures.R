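# Shared fixture builders; everything is generated in code at test time.

# genotype_matrix from a bare dosage matrix: variants laid out 100 kb apart
# on one chromosome unless positions are supplied.
make_gm <- function(D, chrom = NULL, pos = NULL, eaf = NULL) {
  m <- ncol(D)
  if (is.null(colnames(D))) colnames(D) <- sprintf("v%02d", seq_len(m))
  if (is.null(rownames(D))) rownames(D) <- sprintf("s%04d", seq_len(nrow(D)))
  v <- data.frame(variant_id = colnames(D),
                  chrom = if (is.null(chrom)) rep("1", m) else chrom,
                  pos = if (is.null(pos)) 1e6 + (seq_len(m) - 1) * 1e5 else pos,
                  effect_allele = "A", other_allele = "G",
                  stringsAsFactors = FALSE)
  if (!is.null(eaf)) v$eaf <- eaf
  genotype_matrix(D, v)
}

# pair of variants with controllable LD: tag copies the causal haplotypes
# with per-allele fidelity s, so dosage r^2 ~= s^2
make_ld_pair <- function(n, maf, s, seed = 1) {
  set.seed(seed)
  a1 <- rbinom(n, 1, maf); a2 <- rbinom(n, 1, maf)
  t1 <- ifelse(runif(n) < s, a1, rbinom(n, 1, maf))
  t2 <- ifelse(runif(n) < s, a2, rbinom(n, 1, maf))
  cbind(causal = a1 + a2, tag = t1 + t2)
}

# random multi-variant panel with LD blocks, plus synthetic assoc records,
# for clumping tests
make_panel <- function(n = 400, m = 200, frac_tagged = 0.3, seed = 1) {
  set.seed(seed)
  mafs <- runif(m, 0.1, 0.5)
  D <- matrix(rbinom(n * m, 2, rep(mafs, each = n)), n, m)
  n_tag <- round(frac_tagged * m)
  src <- sample(seq_len(m - n_tag), n_tag, replace = TRUE)
  for (k in seq_len(n_tag)) {
    j <- m - n_tag + k
    s <- runif(1, 0.6, 0.99)
    keep <- matrix(runif(2 * n) < s, n, 2)
    base <- D[, src[k]]
    # approximate allele-level copy from the dosage
    h1 <- as.integer(base >= 1); h2 <- as.integer(base == 2)
    t1 <- ifelse(keep[, 1], h1, rbinom(n, 1, mafs[src[k]]))
    t2 <- ifelse(keep[, 2], h2, rbinom(n, 1, mafs[src[k]]))
    D[, j] <- t1 + t2
  }
  ord <- sample(m)  # interleave tags with their sources positionally
  D <- D[, ord]
  chrom <- as.character(1 + (seq_len(m) - 1) %/% 50)
  pos <- 1e6 + ((seq_len(m) - 1) %% 50) * 1e5
  gm <- make_gm(D, chrom = chrom, pos = pos)
  assoc <- data.frame(variant_id = gm$variants$variant_id,
                      p = runif(m)^3, stringsAsFactors = FALSE)
  list(gm = gm, assoc = assoc)
}

# brute-force greedy clumping oracle, independent of partprs::clump
oracle_clump <- function(assoc, gm, p1, r2, kb) {
  sig <- assoc[assoc$p < p1, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  vi <- match(sig$variant_id, gm$variants$variant_id)
  sig$chrom <- gm$variants$chrom[vi]
  sig$pos <- gm$variants$pos[vi]
  sig <- sig[order(sig$p, sig$pos, sig$variant_id), ]
  leads <- character(0)
  while (nrow(sig)) {
    lead <- sig[1, ]
    leads <- c(leads, lead$variant_id)
    drop <- logical(nrow(sig))
    drop[1] <- TRUE
    for (i in seq_len(nrow(sig))[-1]) {
      if (sig$chrom[i] == lead$chrom &&
          abs(sig$pos[i] - lead$pos) <= kb * 1000) {
        r <- cor(gm$dosages[, lead$variant_id], gm$dosages[, sig$variant_id[i]])^2
        if (r >= r2) drop[i] <- TRUE
      }
    }
    sig <- sig[!drop, , drop = FALSE]
  }
  leads
}

# cohorts cached across test files (built once)
.partprs_test_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.partprs_test_cache$coh)) {
    cfg <- sim_config(n_samples = 4000, n_null_variants = 40, seed = 421)
    .partprs_test_cache$cfg <- cfg
    .partprs_test_cache$coh <- simulate_cohort(cfg)
  }
  list(cfg = .partprs_test_cache$cfg, coh = .partprs_test_cache$coh)
}
# full-size default world (samples only; few nulls to keep memory light)
default_cohort <- function() {
  if (is.null(.partprs_test_cache$dcoh)) {
    cfg <- sim_config(n_null_variants = 40, seed = 731)
    .partprs_test_cache$dcfg <- cfg
    .partprs_test_cache$dcoh <- simulate_cohort(cfg)
  }
  list(cfg = .partprs_test_cache$dcfg, coh = .partprs_test_cache$dcoh)
}
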