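#' Describe a planted causal variant
#'
#' A planted variant has a true per-allele effect on liver fat (PDFF, SD
#' units) and on circulating triglycerides (TG, SD units). Discordant
#' variants (liver-retention mechanism) have opposite effect signs on the
#' two traits; concordant (systemic) variants share the sign. Optional tag
#' variants in LD with the causal variant can be requested.
#'
#' @param variant_id variant name.
#' @param maf minor/effect allele frequency in (0, 1).
#' @param beta_pdff true PDFF effect per effect allele (SD units), nonzero.
#' @param beta_tg true TG effect per effect allele (SD units), nonzero.
#' @param n_tags number of LD tag variants to generate alongside.
#' @param tag_r2 target r-squared between each tag and the causal variant.
#' @return list of class `planted_variant`.
#' @export
planted_variant <- function(variant_id, maf, beta_pdff, beta_tg,
                            n_tags = 0, tag_r2 = 0.8) {
  stopifnot(maf > 0, maf < 1, beta_pdff != 0, beta_tg != 0,
            n_tags >= 0, tag_r2 > 0, tag_r2 < 1)
  structure(list(variant_id = variant_id, maf = maf,
                 beta_pdff = beta_pdff, beta_tg = beta_tg,
                 n_tags = as.integer(n_tags), tag_r2 = tag_r2),
            class = "planted_variant")
}

# Default planted architecture: 10 discordant + 13 concordant loci with
# per-allele |beta_pdff| drawn uniformly from [0.03, 0.29] (the span of
# reported genome-wide significant PDFF effects) and MAF uniform on
# [0.10, 0.50]. Each variant's TG effect tracks its PDFF effect (one
# underlying pathway activity drives both traits, with modest jitter), so
# the variant-trait signal matrix has the near-rank-two structure that soft
# clustering is meant to recover.
default_planted_loci <- function(seed) {
  set.seed(seed)
  make <- function(prefix, n, tg_sign) {
    lapply(seq_len(n), function(i) {
      b_pdff <- stats::runif(1, 0.03, 0.29)
      b_tg <- min(max(b_pdff * stats::runif(1, 0.95, 1.05), 0.03), 0.29)
      planted_variant(
        variant_id = sprintf("%s%02d", prefix, i),
        maf = stats::runif(1, 0.10, 0.50),
        beta_pdff = b_pdff,
        beta_tg = tg_sign * b_tg)
    })
  }
  list(discordant = make("disc", 10, -1),
       concordant = make("conc", 13, +1))
}

#' Build a synthetic-cohort configuration
#'
#' Encodes the statistical world the analysis assumes: a cohort with planted
#' discordant (10) and concordant (13) causal loci for liver fat, null
#' variants, correlated adiposity indices, partial mediation of concordant
#' variant effects through an adiposity index, and binary/prospective
#' outcomes whose risks dissociate by pathway (liver outcomes load
#' positively on the discordant score, cardiovascular negatively; systemic
#' outcomes load positively on the concordant score).
#'
#' @param n_samples cohort size; default 20000.
#' @param n_null_variants unassociated variants; default 500.
#' @param discordant_loci,concordant_loci lists of [planted_variant()];
#'   defaults drawn deterministically from `seed` with 10 and 13 loci.
#' @param adiposity_mean,adiposity_sd named length-4 vectors for BMI, WFM,
#'   VAT, WHR.
#' @param adiposity_corr 4x4 positive-definite correlation matrix.
#' @param mediation_fraction fraction of each concordant variant's PDFF
#'   effect routed through `mediated_index`; default 0.2.
#' @param mediated_index which adiposity index carries the mediated path;
#'   default `"VAT"`.
#' @param outcome_spec data.frame with columns `outcome`, `prevalence`,
#'   `logor_disc`, `logor_conc` (log odds / log hazard per SD of the true
#'   pathway scores).
#' @param noise_sd residual SD of quantitative traits; default 1.
#' @param interaction_coef optional gene-adiposity amplification coefficient
#'   (per SD of the mediated index); default 0.
#' @param follow_up_years prospective follow-up horizon; default 14.5.
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20000,
                       n_null_variants = 500,
                       discordant_loci = NULL,
                       concordant_loci = NULL,
                       adiposity_mean = c(BMI = 27, WFM = 24, VAT = 3.8,
                                          WHR = 0.87),
                       adiposity_sd = c(BMI = 4.5, WFM = 9, VAT = 2.2,
                                        WHR = 0.09),
                       adiposity_corr = default_adiposity_corr(),
                       mediation_fraction = 0.2,
                       mediated_index = "VAT",
                       outcome_spec = default_outcome_spec(),
                       noise_sd = 1,
                       interaction_coef = 0,
                       follow_up_years = 14.5,
                       seed = 1) {
  if (is.null(discordant_loci) || is.null(concordant_loci)) {
    defaults <- default_planted_loci(seed + 90001L)
    if (is.null(discordant_loci)) discordant_loci <- defaults$discordant
    if (is.null(concordant_loci)) concordant_loci <- defaults$concordant
  }
  for (pv in c(discordant_loci, concordant_loci))
    stopifnot(inherits(pv, "planted_variant"))
  bad_d <- vapply(discordant_loci,
                  function(p) sign(p$beta_pdff) == sign(p$beta_tg), logical(1))
  bad_c <- vapply(concordant_loci,
                  function(p) sign(p$beta_pdff) != sign(p$beta_tg), logical(1))
  if (any(bad_d)) stop("discordant loci must have opposite PDFF/TG signs")
  if (any(bad_c)) stop("concordant loci must have equal PDFF/TG signs")
  stopifnot(length(adiposity_mean) == 4, length(adiposity_sd) == 4,
            all(dim(adiposity_corr) == c(4, 4)),
            mediation_fraction >= 0, mediation_fraction < 1,
            mediated_index %in% names(adiposity_mean),
            noise_sd > 0, n_samples >= 10, n_null_variants >= 0,
            follow_up_years > 0)
  ev <- eigen(adiposity_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("adiposity correlation matrix is not positive-definite")
  if (any(outcome_spec$prevalence <= 0 | outcome_spec$prevalence >= 1))
    stop("outcome prevalences must lie in (0, 1)")
  structure(list(n_samples = as.integer(n_samples),
                 n_null_variants = as.integer(n_null_variants),
                 discordant_loci = discordant_loci,
                 concordant_loci = concordant_loci,
                 adiposity_mean = adiposity_mean,
                 adiposity_sd = adiposity_sd,
                 adiposity_corr = adiposity_corr,
                 mediation_fraction = mediation_fraction,
                 mediated_index = mediated_index,
                 outcome_spec = outcome_spec,
                 noise_sd = noise_sd,
                 interaction_coef = interaction_coef,
                 follow_up_years = follow_up_years,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_adiposity_corr <- function() {
  R <- matrix(c(1.00, 0.85, 0.75, 0.55,
                0.85, 1.00, 0.70, 0.45,
                0.75, 0.70, 1.00, 0.65,
                0.55, 0.45, 0.65, 1.00), 4, 4)
  dimnames(R) <- list(c("BMI", "WFM", "VAT", "WHR"),
                      c("BMI", "WFM", "VAT", "WHR"))
  R
}

#' @rdname sim_config
#' @export
default_outcome_spec <- function() {
  data.frame(
    outcome = c("masld", "cardiovascular", "hypertension", "diabetes"),
    prevalence = c(0.05, 0.10, 0.25, 0.08),
    logor_disc = c(0.35, -0.15, 0.00, 0.10),
    logor_conc = c(0.20, 0.25, 0.20, 0.25),
    stringsAsFactors = FALSE)
}

#' Ground-truth pathway assignment of a configuration
#'
#' Returns the planted discordant/concordant labels and the true PDFF betas
#' as score weights, for parameter-recovery tests.
#'
#' @param config sim_config.
#' @return list with `discordant` and `concordant` named weight vectors
#'   (true PDFF betas, PDFF-increasing orientation) and `table`
#'   (data.frame: `variant_id`, `group`, `maf`, `beta_pdff`, `beta_tg`).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  row1 <- function(p, g) data.frame(variant_id = p$variant_id, group = g,
                                    maf = p$maf, beta_pdff = p$beta_pdff,
                                    beta_tg = p$beta_tg,
                                    stringsAsFactors = FALSE)
  tab <- do.call(rbind, c(
    lapply(config$discordant_loci, row1, g = "discordant"),
    lapply(config$concordant_loci, row1, g = "concordant"),
    make.row.names = FALSE))
  wts <- function(g) {
    s <- tab[tab$group == g, , drop = FALSE]
    if (!nrow(s)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(abs(s$beta_pdff), s$variant_id)
  }
  list(discordant = wts("discordant"), concordant = wts("concordant"),
       table = tab)
}

#' Simulate a synthetic cohort with a planted two-pathway architecture
#'
#' Draws genotype dosages as `Binomial(2, MAF)` (tag variants by
#' copy-with-error of the causal haplotypes), correlated adiposity indices,
#' quantitative liver traits with the configured genetic, covariate and
#' mediated components, and binary plus prospective outcomes from logistic
#' and exponential proportional-hazards models on the true pathway scores.
#' Identical configurations (including seed) yield bit-identical output.
#'
#' @param config sim_config.
#' @return list with `genotypes` (genotype_matrix) and `phenotypes`
#'   (data.frame keyed by `sample_id`). Phenotypes include covariates (age,
#'   sex and derived terms), adiposity indices, quantitative traits (`pdff`,
#'   `ct1`, `tg`, `alt`, `ldl`, `glucose`, SD-scale), and per outcome `<out>` (case-control
#'   status), `<out>_prev` (prevalent at baseline), `<out>_inc`,
#'   `<out>_time`, `<out>_event` (incident follow-up among non-prevalent;
#'   `NA` for prevalent cases).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_samples
  planted <- c(config$discordant_loci, config$concordant_loci)

  # --- genotypes ------------------------------------------------------
  # causal variants at haplotype level so tags can copy-with-error
  geno_cols <- list()
  meta_rows <- list()
  for (pv in planted) {
    a1 <- stats::rbinom(n, 1, pv$maf)
    a2 <- stats::rbinom(n, 1, pv$maf)
    geno_cols[[pv$variant_id]] <- a1 + a2
    meta_rows[[pv$variant_id]] <- c(role = "causal", maf = pv$maf)
    if (pv$n_tags > 0) {
      s <- sqrt(pv$tag_r2)  # per-allele copy fidelity gives dosage r2 = s^2
      for (t in seq_len(pv$n_tags)) {
        keep1 <- stats::runif(n) < s
        keep2 <- stats::runif(n) < s
        t1 <- ifelse(keep1, a1, stats::rbinom(n, 1, pv$maf))
        t2 <- ifelse(keep2, a2, stats::rbinom(n, 1, pv$maf))
        tid <- sprintf("%s_tag%d", pv$variant_id, t)
        geno_cols[[tid]] <- t1 + t2
        meta_rows[[tid]] <- c(role = "tag", maf = pv$maf)
      }
    }
  }
  if (config$n_null_variants > 0) {
    null_maf <- stats::runif(config$n_null_variants, 0.05, 0.5)
    for (i in seq_len(config$n_null_variants)) {
      nid <- sprintf("null%03d", i)
      geno_cols[[nid]] <- stats::rbinom(n, 2, null_maf[i])
      meta_rows[[nid]] <- c(role = "null", maf = null_maf[i])
    }
  }
  ids <- names(geno_cols)
  G <- matrix(unlist(geno_cols, use.names = FALSE), nrow = n,
              dimnames = list(sprintf("s%05d", seq_len(n)), ids))
  role <- vapply(meta_rows, function(x) x[["role"]], character(1))
  mafs <- as.numeric(vapply(meta_rows, function(x) x[["maf"]], character(1)))
  # genome layout: 40 variants per chromosome, 500 kb spacing, tags offset
  m <- length(ids)
  slot <- seq_len(m) - 1L
  chrom <- as.character(1L + slot %/% 40L)
  pos <- 1e6 + (slot %% 40L) * 5e5
  variants <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                         effect_allele = "A", other_allele = "G",
                         role = role, true_maf = mafs,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(G, variants)

  # --- covariates and adiposity --------------------------------------
  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1, 0.5)
  Z <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(config$adiposity_corr)
  colnames(Z) <- colnames(config$adiposity_corr)
  # mediated genetic component enters the designated index on its SD scale
  gamma_med <- 0.3  # effect (SD PDFF per SD index) carried by the mediator
  a_coef <- stats::setNames(numeric(0), character(0))
  if (config$mediation_fraction > 0) {
    a_coef <- vapply(config$concordant_loci, function(p)
      config$mediation_fraction * p$beta_pdff / gamma_med, numeric(1))
    names(a_coef) <- vapply(config$concordant_loci, `[[`, "", "variant_id")
  }
  med_genetic <- rep(0, n)
  for (id in names(a_coef))
    med_genetic <- med_genetic + a_coef[[id]] * (G[, id] - 2 * mafs[match(id, ids)])
  adi_std <- Z
  adi_std[, config$mediated_index] <- adi_std[, config$mediated_index] +
    med_genetic
  # mild age/sex structure so covariate adjustment matters
  adi_std <- adi_std + outer(0.01 * (age - 55), rep(1, 4)) -
    outer(0.15 * sex, c(1, 1, 0.5, -0.5))
  adiposity <- sweep(sweep(adi_std, 2, config$adiposity_sd, `*`), 2,
                     config$adiposity_mean, `+`)

  # --- quantitative traits -------------------------------------------
  med_std <- adi_std[, config$mediated_index]
  center <- function(id) G[, id] - 2 * mafs[match(id, ids)]
  direct_pdff <- rep(0, n)
  disc_score <- rep(0, n)
  conc_score <- rep(0, n)
  tg_gen <- rep(0, n)
  for (pv in config$discordant_loci) {
    gc <- center(pv$variant_id)
    direct_pdff <- direct_pdff + pv$beta_pdff * gc
    disc_score <- disc_score + pv$beta_pdff * gc
    tg_gen <- tg_gen + pv$beta_tg * gc
  }
  for (pv in config$concordant_loci) {
    gc <- center(pv$variant_id)
    f <- if (length(a_coef)) config$mediation_fraction else 0
    direct_pdff <- direct_pdff + (1 - f) * pv$beta_pdff * gc
    conc_score <- conc_score + pv$beta_pdff * gc
    tg_gen <- tg_gen + pv$beta_tg * gc
  }
  covar_eff <- 0.004 * (age - 55) + 0.10 * sex
  pdff <- covar_eff + direct_pdff + gamma_med * med_std +
    config$interaction_coef * direct_pdff * med_std +
    stats::rnorm(n, 0, config$noise_sd)
  ct1 <- 0.5 * covar_eff + 0.4 * disc_score +
    stats::rnorm(n, 0, config$noise_sd)
  tg <- 0.006 * (age - 55) - 0.05 * sex + tg_gen +
    stats::rnorm(n, 0, config$noise_sd)
  alt <- 0.4 * pdff + stats::rnorm(n, 0, config$noise_sd)
  # circulating LDL falls with the liver-retention pathway (lipoproteins
  # retained in the liver) and rises mildly with the systemic pathway;
  # glucose tracks the systemic pathway only
  ldl <- 0.004 * (age - 55) - 0.5 * disc_score + 0.3 * conc_score +
    stats::rnorm(n, 0, config$noise_sd)
  glucose <- 0.005 * (age - 55) + 0.4 * conc_score +
    stats::rnorm(n, 0, config$noise_sd)

  # --- outcomes -------------------------------------------------------
  sd0 <- stats::sd(disc_score); if (sd0 == 0) sd0 <- 1
  sc0 <- stats::sd(conc_score); if (sc0 == 0) sc0 <- 1
  d_std <- (disc_score - mean(disc_score)) / sd0
  c_std <- (conc_score - mean(conc_score)) / sc0
  pheno <- data.frame(sample_id = rownames(G), age = age, sex = sex,
                      age2 = age^2, age_sex = age * sex,
                      age2_sex = age^2 * sex,
                      BMI = adiposity[, "BMI"], WFM = adiposity[, "WFM"],
                      VAT = adiposity[, "VAT"], WHR = adiposity[, "WHR"],
                      pdff = pdff, ct1 = ct1, tg = tg, alt = alt,
                      ldl = ldl, glucose = glucose,
                      stringsAsFactors = FALSE)
  fu <- config$follow_up_years
  for (k in seq_len(nrow(config$outcome_spec))) {
    os <- config$outcome_spec[k, ]
    eta <- os$logor_disc * d_std + os$logor_conc * c_std
    prev <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(os$prevalence) +
                                              eta))
    lam0 <- os$prevalence / fu  # baseline hazard targets ~prevalence events
    t_ev <- stats::rexp(n, lam0 * exp(eta))
    cens <- stats::runif(n, 0.7 * fu, fu)
    inc <- as.integer(t_ev <= cens)
    tim <- pmin(t_ev, cens)
    inc[prev == 1] <- NA_integer_
    tim[prev == 1] <- NA_real_
    pheno[[os$outcome]] <- as.integer(prev == 1 |
                                      (!is.na(inc) & inc == 1))
    pheno[[paste0(os$outcome, "_prev")]] <- prev
    pheno[[paste0(os$outcome, "_inc")]] <- inc
    pheno[[paste0(os$outcome, "_time")]] <- tim
    pheno[[paste0(os$outcome, "_event")]] <- inc
  }
  list(genotypes = gm, phenotypes = pheno)
}

#' Standard covariate design used throughout the analyses
#'
#' Age, sex, age^2, age x sex, age^2 x sex, optionally plus one adiposity
#' index — the adjustment set used by every association model here.
#'
#' @param phenotypes phenotype data.frame from [simulate_cohort()].
#' @param adiposity optional adiposity column name (`"BMI"`, `"WFM"`,
#'   `"VAT"`, `"WHR"`) or `NULL` for no adiposity adjustment.
#' @return numeric covariate matrix.
#' @export
standard_covariates <- function(phenotypes, adiposity = NULL) {
  M <- cbind(age = phenotypes$age, sex = phenotypes$sex,
             age2 = phenotypes$age2, age_sex = phenotypes$age_sex,
             age2_sex = phenotypes$age2_sex)
  if (!is.null(adiposity)) {
    stopifnot(adiposity %in% c("BMI", "WFM", "VAT", "WHR"))
    M <- cbind(M, adiposity = phenotypes[[adiposity]])
  }
  M
}
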