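#' Assemble a full-run configuration
#'
#' Bundles the simulation world and every stage's tunables. All thresholds
#' default to the values used throughout the package; the master seed
#' drives every stochastic stage.
#'
#' @param sim sim_config for the synthetic cohort.
#' @param out_dir directory for stage outputs.
#' @param adjustments adiposity adjustments for the liver-fat scans.
#' @param clump_p1,clump_r2,clump_kb LD clumping parameters.
#' @param cond_p stepwise conditional selection threshold.
#' @param merge_dist_bp,merge_r2 pleiotropic locus merging parameters.
#' @param alpha_tg TG-association threshold for the partition.
#' @param bnmf_k_max,bnmf_restarts bNMF settings (restarts scaled down from
#'   1000 for pipeline runs; set 1000 for a full analysis).
#' @param mediation_boot bootstrap resamples per mediation fit.
#' @param seed master seed (overrides `sim$seed`).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("partprs_run_"),
                       adjustments = c("none", "BMI", "WFM", "VAT"),
                       clump_p1 = 5e-8, clump_r2 = 0.01, clump_kb = 1000,
                       cond_p = 5e-8, merge_dist_bp = 1e6, merge_r2 = 0.2,
                       alpha_tg = 0.05, bnmf_k_max = 7, bnmf_restarts = 100,
                       mediation_boot = 200, seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, out_dir = out_dir, adjustments = adjustments,
                 clump_p1 = clump_p1, clump_r2 = clump_r2,
                 clump_kb = clump_kb, cond_p = cond_p,
                 merge_dist_bp = merge_dist_bp, merge_r2 = merge_r2,
                 alpha_tg = alpha_tg, bnmf_k_max = bnmf_k_max,
                 bnmf_restarts = bnmf_restarts,
                 mediation_boot = mediation_boot,
                 seed = sim$seed), class = "run_config")
}

#' Run the whole analysis end to end on a synthetic cohort
#'
#' Executes simulate -> transform -> scan (per adiposity adjustment) ->
#' clump -> stepwise conditional -> pleiotropic merge -> partition ->
#' score -> outcome association -> Wald/AIC comparison -> bNMF clustering
#' -> mediation, writing every stage as a schema-tagged TSV plus a plain
#' text run log into `config$out_dir`. Reruns with the same configuration
#' reproduce all outputs bit-identically (timings excepted, which go only
#' to the log).
#'
#' @param config run_config.
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory stage results (`cohort`,
#'   `scans`, `leads`, `loci`, `partition`, `scores`, `effects`,
#'   `wald`, `bnmf`, `clusters`, `mediation`, `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("partprs run, seed %d", config$seed),
                 sprintf("started %s", format(Sys.time())))
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    say("stage: ", name)
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-12s %.2fs", name,
                                       as.numeric(Sys.time() - t0,
                                                  units = "secs")))
    res
  }

  cohort <- stage("simulate", simulate_cohort(config$sim))
  gm <- cohort$genotypes
  ph <- cohort$phenotypes
  write_genotypes(gm, out("genotypes.tsv"))
  write_phenotypes(ph, out("phenotypes.tsv"))
  write_sim_config(config$sim, out("sim_config.json"))
  truth <- planted_truth(config$sim)
  write_tsv_schema(truth$table, out("planted_truth.tsv"))

  scans <- stage("scan", {
    pdff_t <- rank_inverse_normal(ph$pdff)
    tg_t <- rank_inverse_normal(ph$tg)
    alt_t <- rank_inverse_normal(ph$alt)
    ct1_t <- rank_inverse_normal(ph$ct1)
    s <- list()
    for (adj in config$adjustments) {
      a <- if (adj == "none") NULL else adj
      s[[paste0("pdff_", adj)]] <- assoc_scan(
        gm, pdff_t, standard_covariates(ph, a), "linear",
        trait = "pdff", adjustment = adj)
    }
    # baseline traits use WHR in place of VAT (VAT unavailable at baseline)
    for (tr in c("tg", "alt", "ct1", "ldl", "glucose"))
      s[[tr]] <- assoc_scan(gm, rank_inverse_normal(ph[[tr]]),
                            standard_covariates(ph, "WHR"), "linear",
                            trait = tr, adjustment = "WHR")
    s
  })
  all_scans <- do.call(rbind, c(scans, make.row.names = FALSE))
  write_tsv_schema(all_scans, out("summary_stats.tsv"))

  leads <- stage("clump+conditional", {
    L <- list()
    for (adj in config$adjustments) {
      sc <- scans[[paste0("pdff_", adj)]]
      cl <- clump(sc, gm, p1 = config$clump_p1, r2 = config$clump_r2,
                  kb = config$clump_kb)
      if (length(cl) > 1) {
        a <- if (adj == "none") NULL else adj
        cl <- stepwise_conditional(gm, rank_inverse_normal(ph$pdff),
                                   standard_covariates(ph, a), cl,
                                   p_thresh = config$cond_p)
      }
      L[[adj]] <- sc[sc$variant_id %in% cl, , drop = FALSE]
    }
    L
  })
  lead_df <- do.call(rbind, c(leads, make.row.names = FALSE))

  if (!nrow(lead_df)) {
    say("no significant variants: writing empty partition")
    empty <- data.frame(variant_id = character(0), group = character(0),
                        effect_allele = character(0),
                        other_allele = character(0), weight = numeric(0),
                        tg_beta = numeric(0), tg_p = numeric(0))
    write_tsv_schema(empty, out("partition.tsv"))
    log_lines <- c(log_lines, "no significant variants; stopped early")
    writeLines(log_lines, out("run_log.txt"))
    return(invisible(list(cohort = cohort, scans = scans,
                          leads = lead_df, partition = NULL,
                          files = list.files(config$out_dir,
                                             full.names = TRUE))))
  }

  merged <- stage("merge", merge_pleiotropic(lead_df, gm,
                                             dist_bp = config$merge_dist_bp,
                                             r2_min = config$merge_r2))
  write_tsv_schema(merged$loci, out("loci.tsv"))

  partition <- stage("partition", {
    # strongest PDFF association per locus is the locus lead and weight
    lb <- merged$lead_by_trait
    pdff_leads <- lb$variant_id[lb$trait == "pdff"]
    pdff_best <- do.call(rbind, lapply(pdff_leads, function(id) {
      rows <- lead_df[lead_df$variant_id == id, , drop = FALSE]
      rows[which.min(rows$p), , drop = FALSE]
    }))
    tg_rec <- scans$tg[match(pdff_best$variant_id, scans$tg$variant_id), ,
                       drop = FALSE]
    partition_by_concordance(pdff_best, tg_rec, alpha_tg = config$alpha_tg)
  })
  write_tsv_schema(partition$table, out("partition.tsv"))

  scores <- stage("score", {
    list(discordant = compute_score(gm, partition$discordant,
                                    partition$orientation),
         concordant = compute_score(gm, partition$concordant,
                                    partition$orientation))
  })
  write_tsv_schema(data.frame(sample_id = gm$sample_ids,
                              discordant = unname(scores$discordant),
                              concordant = unname(scores$concordant)),
                   out("scores.tsv"))

  effects <- stage("associate", {
    res <- list()
    covs <- cbind(standard_covariates(ph), BMI = ph$BMI)
    for (os in config$sim$outcome_spec$outcome) {
      for (sc_name in names(scores)) {
        if (!length(partition[[sc_name]])) next
        res[[paste(sc_name, os, "logistic", sep = ".")]] <-
          outcome_assoc(scores[[sc_name]], ph[[os]], covs, "logistic",
                        score_name = sc_name, outcome_name = os)
        res[[paste(sc_name, os, "cox", sep = ".")]] <-
          outcome_assoc(scores[[sc_name]], covariates = covs, model = "cox",
                        time = ph[[paste0(os, "_time")]],
                        event = ph[[paste0(os, "_event")]],
                        score_name = sc_name, outcome_name = os)
      }
    }
    res
  })
  eff_df <- do.call(rbind, c(lapply(effects, function(e)
    data.frame(score = e$score_name, outcome = e$outcome, model = e$model,
               beta = e$beta, se = e$se, or_hr = exp(e$beta),
               ci_low = exp(e$ci95[1]), ci_high = exp(e$ci95[2]), p = e$p,
               n_cases = e$n_cases, n_total = e$n_total,
               stringsAsFactors = FALSE)), make.row.names = FALSE))
  write_tsv_schema(eff_df, out("score_effects.tsv"))

  wald <- stage("compare", {
    # NB: no return() here -- stage() evaluates its expression lazily in
    # this frame, so return() would exit run_pipeline itself
    both <- length(partition$discordant) && length(partition$concordant)
    if (!both) NULL else {
      rows <- lapply(config$sim$outcome_spec$outcome, function(os) {
        e1 <- effects[[paste("discordant", os, "logistic", sep = ".")]]
        e2 <- effects[[paste("concordant", os, "logistic", sep = ".")]]
        w <- wald_compare(e1, e2)
        data.frame(outcome = os, w = w$w, p = w$p, stringsAsFactors = FALSE)
      })
      do.call(rbind, c(rows, make.row.names = FALSE))
    }
  })
  if (!is.null(wald)) write_tsv_schema(wald, out("wald_compare.tsv"))

  bn <- stage("bnmf", {
    part_ids <- c(names(partition$discordant), names(partition$concordant))
    if (length(part_ids) < 3) NULL else {
    traits <- c("tg", "alt", "ct1", "ldl", "glucose")
    by_trait <- c(
      list(pdff = do.call(rbind, lapply(part_ids, function(id) {
        rows <- lead_df[lead_df$variant_id == id, , drop = FALSE]
        rows[which.min(rows$p), , drop = FALSE]
      }))),
      lapply(stats::setNames(traits, traits), function(tr)
        scans[[tr]][scans[[tr]]$variant_id %in% part_ids, , drop = FALSE]))
    # prune on phenotypic trait correlations, not z-column correlations
    tc <- stats::cor(as.matrix(ph[, c("pdff", traits)]))
    z <- build_z_matrix(by_trait, align_trait = "pdff", trait_corr = tc)
    fit <- bnmf_fit(z, k_max = config$bnmf_k_max,
                    n_restarts = config$bnmf_restarts,
                    seed = config$seed + 1L)
    cl <- extract_clusters(fit)
    write_tsv_schema(fit$restart_log, out("bnmf_restarts.tsv"))
    mem <- do.call(rbind, c(lapply(names(cl$memberships), function(k)
      if (nrow(cl$memberships[[k]]))
        cbind(cluster = k, cl$memberships[[k]])), make.row.names = FALSE))
    if (!is.null(mem)) write_tsv_schema(mem, out("bnmf_memberships.tsv"))
    list(fit = fit, clusters = cl)
    }
  })

  med <- stage("mediate", {
    ids <- names(partition$concordant)
    if (!length(ids)) NULL else {
    covs <- standard_covariates(ph)
    rows <- lapply(ids, function(id) {
      mr <- mediate(dosage(gm, id), ph[[config$sim$mediated_index]],
                    rank_inverse_normal(ph$pdff), covs,
                    n_boot = config$mediation_boot,
                    seed = config$seed + match(id, ids))
      data.frame(variant_id = id, mediator = config$sim$mediated_index,
                 trait = "pdff", acme = mr$acme, ade = mr$ade,
                 total = mr$total, prop_mediated = mr$prop_mediated,
                 acme_low = mr$ci["acme", 1], acme_high = mr$ci["acme", 2],
                 classification = mr$classification,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
    }
  })
  if (!is.null(med)) write_tsv_schema(med, out("mediation.tsv"))

  log_lines <- c(log_lines,
                 sprintf("total %.2fs", as.numeric(Sys.time() - t_start,
                                                   units = "secs")),
                 sprintf("R %s, partprs %s", getRversion(),
                         as.character(utils::packageVersion("partprs"))))
  writeLines(log_lines, out("run_log.txt"))
  say("done: ", config$out_dir)
  invisible(list(cohort = cohort, scans = scans, leads = lead_df,
                 loci = merged, partition = partition, scores = scores,
                 effects = effects, wald = wald,
                 bnmf = if (!is.null(bn)) bn$fit,
                 clusters = if (!is.null(bn)) bn$clusters,
                 mediation = med,
                 files = list.files(config$out_dir, full.names = TRUE)))
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands: `simulate`, `scan`, `clump`,
#' `merge`, `partition`, `score`, `assoc`, `bnmf`, `mediate`, `meta`,
#' `select-adiposity`, `run-all`. `run-all` executes the whole analysis in
#' one go; the other subcommands are file-based stages that read their
#' inputs from (and write their outputs into) the `--out` directory, so a
#' run can be re-entered stage by stage. All accept `--seed`, `--config`
#' (a sim-config JSON) and `--out`.
#'
#' @param args character vector, e.g.
#'   `c("run-all", "--seed", "1", "--out", "run1")`.
#' @return invisibly, the result of the dispatched stage.
#' @export
partprs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: partprs",
                 "<simulate|scan|clump|merge|partition|score|assoc|bnmf|",
                 "mediate|meta|select-adiposity|run-all>",
                 "[--seed S] [--config cfg.json] [--out dir]")
  if (!length(args)) {
    cat(usage, "\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- list(seed = "1", config = NULL, out = "partprs_out")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt$seed <- as.integer(opt$seed)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(opt$out, f)
  need <- function(f) {
    if (!file.exists(out(f)))
      stop("stage input missing: ", out(f), " (run the earlier stages first)")
    out(f)
  }
  load_sim <- function() {
    p <- if (!is.null(opt$config)) opt$config
         else if (file.exists(out("sim_config.json"))) out("sim_config.json")
    if (is.null(p)) {
      sim <- sim_config(seed = opt$seed)
    } else {
      sim <- read_sim_config(p)
      if (is.null(opt$config)) return(sim)  # keep the run's own seed
      sim$seed <- opt$seed
    }
    sim
  }
  load_scans <- function() {
    ss <- read_tsv_schema(need("summary_stats.tsv"))
    split(ss, paste(ss$trait, ss$adjustment, sep = "_"))
  }
  pdff_tg_records <- function() {
    ss <- read_tsv_schema(need("summary_stats.tsv"))
    pdff <- ss[ss$trait == "pdff", , drop = FALSE]
    # strongest adjusted association per variant
    best <- do.call(rbind, lapply(split(pdff, pdff$variant_id), function(d)
      d[which.min(d$p), , drop = FALSE]))
    tg <- ss[ss$trait == "tg", , drop = FALSE]
    list(pdff = best, tg = tg)
  }

  res <- switch(cmd,
    simulate = {
      sim <- load_sim()
      cohort <- simulate_cohort(sim)
      write_genotypes(cohort$genotypes, out("genotypes.tsv"))
      write_phenotypes(cohort$phenotypes, out("phenotypes.tsv"))
      write_sim_config(sim, out("sim_config.json"))
      write_tsv_schema(planted_truth(sim)$table, out("planted_truth.tsv"))
      cohort
    },
    scan = {
      gm <- read_genotypes(need("genotypes.tsv"))
      ph <- read_phenotypes(need("phenotypes.tsv"))
      s <- list()
      for (adj in c("none", "BMI", "WFM", "VAT")) {
        a <- if (adj == "none") NULL else adj
        s[[paste0("pdff_", adj)]] <- assoc_scan(
          gm, rank_inverse_normal(ph$pdff), standard_covariates(ph, a),
          "linear", trait = "pdff", adjustment = adj)
      }
      for (tr in c("tg", "alt", "ct1", "ldl", "glucose"))
        s[[tr]] <- assoc_scan(gm, rank_inverse_normal(ph[[tr]]),
                              standard_covariates(ph, "WHR"), "linear",
                              trait = tr, adjustment = "WHR")
      all <- do.call(rbind, c(s, make.row.names = FALSE))
      write_tsv_schema(all, out("summary_stats.tsv"))
      all
    },
    clump = {
      gm <- read_genotypes(need("genotypes.tsv"))
      scans <- load_scans()
      rows <- lapply(scans[startsWith(names(scans), "pdff_")], function(sc) {
        leads <- clump(sc, gm)
        sc[sc$variant_id %in% leads, , drop = FALSE]
      })
      lead_df <- do.call(rbind, c(rows, make.row.names = FALSE))
      write_tsv_schema(lead_df, out("leads.tsv"))
      lead_df
    },
    merge = {
      gm <- read_genotypes(need("genotypes.tsv"))
      lead_df <- read_tsv_schema(need("leads.tsv"))
      merged <- merge_pleiotropic(lead_df, gm)
      write_tsv_schema(merged$loci, out("loci.tsv"))
      write_tsv_schema(merged$lead_by_trait, out("locus_leads.tsv"))
      merged
    },
    partition = {
      rec <- pdff_tg_records()
      lead_df <- read_tsv_schema(need("leads.tsv"))
      pdff <- rec$pdff[rec$pdff$variant_id %in% lead_df$variant_id, ,
                       drop = FALSE]
      tg <- rec$tg[match(pdff$variant_id, rec$tg$variant_id), , drop = FALSE]
      part <- partition_by_concordance(pdff, tg)
      write_tsv_schema(part$table, out("partition.tsv"))
      part
    },
    score = {
      gm <- read_genotypes(need("genotypes.tsv"))
      tab <- read_tsv_schema(need("partition.tsv"))
      ori <- data.frame(variant_id = tab$variant_id,
                        effect_allele = tab$effect_allele)
      sc <- data.frame(sample_id = gm$sample_ids)
      for (g in c("discordant", "concordant")) {
        s <- tab[tab$group == g, , drop = FALSE]
        sc[[g]] <- if (nrow(s))
          unname(compute_score(gm, stats::setNames(s$weight, s$variant_id),
                               ori)) else 0
      }
      write_tsv_schema(sc, out("scores.tsv"))
      sc
    },
    assoc = {
      ph <- read_phenotypes(need("phenotypes.tsv"))
      sc <- read_tsv_schema(need("scores.tsv"))
      covs <- cbind(standard_covariates(ph), BMI = ph$BMI)
      outcomes <- intersect(default_outcome_spec()$outcome, names(ph))
      rows <- list()
      for (os in outcomes) for (g in c("discordant", "concordant")) {
        if (stats::sd(sc[[g]]) == 0) next
        e <- outcome_assoc(sc[[g]], ph[[os]], covs, "logistic",
                           score_name = g, outcome_name = os)
        rows[[paste(g, os)]] <- data.frame(
          score = g, outcome = os, model = "logistic", beta = e$beta,
          se = e$se, or_hr = exp(e$beta), ci_low = exp(e$ci95[1]),
          ci_high = exp(e$ci95[2]), p = e$p, n_cases = e$n_cases,
          n_total = e$n_total, stringsAsFactors = FALSE)
      }
      eff <- do.call(rbind, c(rows, make.row.names = FALSE))
      write_tsv_schema(eff, out("score_effects.tsv"))
      eff
    },
    bnmf = {
      ss <- read_tsv_schema(need("summary_stats.tsv"))
      ph <- read_phenotypes(need("phenotypes.tsv"))
      tab <- read_tsv_schema(need("partition.tsv"))
      ids <- tab$variant_id[tab$group != "excluded"]
      rec <- pdff_tg_records()
      by_trait <- list(pdff = rec$pdff[rec$pdff$variant_id %in% ids, ,
                                       drop = FALSE])
      for (tr in setdiff(unique(ss$trait), "pdff")) {
        d <- ss[ss$trait == tr & ss$variant_id %in% ids, , drop = FALSE]
        by_trait[[tr]] <- d
      }
      tc <- stats::cor(as.matrix(ph[, names(by_trait)]))
      z <- build_z_matrix(by_trait, align_trait = "pdff", trait_corr = tc)
      fit <- bnmf_fit(z, n_restarts = 100, seed = opt$seed)
      cl <- extract_clusters(fit)
      write_tsv_schema(fit$restart_log, out("bnmf_restarts.tsv"))
      mem <- do.call(rbind, c(lapply(names(cl$memberships), function(k)
        if (nrow(cl$memberships[[k]]))
          cbind(cluster = k, cl$memberships[[k]])), make.row.names = FALSE))
      if (!is.null(mem)) write_tsv_schema(mem, out("bnmf_memberships.tsv"))
      list(fit = fit, clusters = cl)
    },
    mediate = {
      gm <- read_genotypes(need("genotypes.tsv"))
      ph <- read_phenotypes(need("phenotypes.tsv"))
      tab <- read_tsv_schema(need("partition.tsv"))
      sim <- load_sim()
      ids <- tab$variant_id[tab$group == "concordant"]
      ids <- intersect(ids, gm$variants$variant_id)
      rows <- lapply(ids, function(id) {
        mr <- mediate(dosage(gm, id), ph[[sim$mediated_index]],
                      rank_inverse_normal(ph$pdff),
                      standard_covariates(ph), n_boot = 200,
                      seed = opt$seed + match(id, ids))
        data.frame(variant_id = id, mediator = sim$mediated_index,
                   trait = "pdff", acme = mr$acme, ade = mr$ade,
                   total = mr$total, prop_mediated = mr$prop_mediated,
                   acme_low = mr$ci["acme", 1],
                   acme_high = mr$ci["acme", 2],
                   classification = mr$classification,
                   stringsAsFactors = FALSE)
      })
      med <- do.call(rbind, c(rows, make.row.names = FALSE))
      if (!is.null(med)) write_tsv_schema(med, out("mediation.tsv"))
      med
    },
    meta = {
      # pools per-study estimates from <out>/meta_input.tsv (beta, se [, study])
      d <- read_tsv_schema(need("meta_input.tsv"))
      mr <- ivw_meta(d$beta, d$se)
      pooled <- data.frame(pooled_beta = mr$pooled_beta,
                           pooled_se = mr$pooled_se, p = mr$p,
                           k_studies = mr$k_studies, q_het = mr$q_het)
      write_tsv_schema(pooled, out("meta_result.tsv"))
      mr
    },
    `select-adiposity` = {
      ph <- read_phenotypes(need("phenotypes.tsv"))
      fit <- nested_cv_penalized(ph[, c("BMI", "WFM", "VAT", "WHR")],
                                 ph$pdff, standard_covariates(ph),
                                 seed = opt$seed)
      write_tsv_schema(data.frame(model = fit$model_kind, alpha = fit$alpha,
                                  lambda = fit$lambda,
                                  predictor = names(fit$coefficients),
                                  standardized_beta = unname(fit$coefficients),
                                  cv_mse = fit$cv_mse[fit$model_kind],
                                  test_mse = fit$test_mse),
                      out("adiposity_selection.tsv"))
      fit
    },
    `run-all` = {
      cfg <- run_config(sim = load_sim(), out_dir = opt$out,
                        seed = opt$seed)
      run_pipeline(cfg, quiet = TRUE)
    },
    stop("unknown subcommand: ", cmd, "\n", usage))
  invisible(res)
}
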