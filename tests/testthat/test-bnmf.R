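mk_assoc <- function(ids, beta, se = 0.02, n = 30000) {
  data.frame(variant_id = ids, beta = beta, se = se, n = n,
             stringsAsFactors = FALSE)
}

test_that("build_z_matrix aligns, scales and splits signed z-scores", {
  ids <- c("v1", "v2")
  ab <- list(pdff = mk_assoc(ids, c(0.04, -0.04)),
             tg = mk_assoc(ids, c(0.04, 0.04)))
  z <- build_z_matrix(ab, align_trait = "pdff")
  # v2 has a negative PDFF beta: its whole row is sign-flipped
  expect_true(z$flipped[2])
  expect_true(all(z$signed[, "pdff"] > 0))
  expect_equal(z$signed["v2", "tg"], -2)
  # z = +2 splits into (pos = 2, neg = 0)
  expect_equal(unname(z$z["v1", c("tg_pos", "tg_neg")]), c(2, 0))
  expect_equal(unname(z$z["v2", c("tg_pos", "tg_neg")]), c(0, 2))
  # pos - neg reconstructs the signed aligned matrix exactly
  traits <- colnames(z$signed)
  recon <- z$z[, paste0(traits, "_pos")] - z$z[, paste0(traits, "_neg")]
  expect_equal(unname(recon), unname(z$signed))
  expect_true(all(z$z >= 0))
})

test_that("build_z_matrix prunes one of each highly correlated trait pair", {
  set.seed(61)
  ids <- sprintf("v%02d", 1:12)
  b <- runif(12, 0.01, 0.05)
  ab <- list(pdff = mk_assoc(ids, b),
             tg = mk_assoc(ids, b * 1.02 + 1e-4),   # corr ~ 1 with pdff
             alt = mk_assoc(ids, runif(12, -0.05, 0.05)))
  z <- build_z_matrix(ab, align_trait = "pdff", corr_prune = 0.85)
  expect_identical(z$dropped_traits, "tg")  # first-in-order kept
  expect_false("tg_pos" %in% colnames(z$z))
  # sample-size scaling: median N here is 22,500, so the half-N trait is
  # up-weighted by sqrt(22500 / 15000)
  b2 <- runif(12, 0.01, 0.05)
  ab2 <- list(pdff = mk_assoc(ids, b, n = 30000),
              alt = mk_assoc(ids, b2, n = 15000))
  z2 <- build_z_matrix(ab2, align_trait = "pdff", corr_prune = 0.999)
  expect_equal(z2$signed[, "alt"], (b2 / 0.02) * sqrt(22500 / 15000),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(build_z_matrix(list(tg = mk_assoc(ids, b))), "align_trait")
})

test_that("bnmf_fit learns the planted component count", {
  set.seed(62)
  w <- runif(18, 0.5, 2); h <- runif(6, 0.5, 2)
  V1 <- outer(w, h) + matrix(abs(rnorm(108, 0, 0.05)), 18)
  f1 <- bnmf_fit(V1, k_max = 7, n_restarts = 30, seed = 63)
  expect_identical(f1$k_selected, 1L)
  expect_identical(dim(f1$w), c(18L, 1L))
  expect_identical(nrow(f1$restart_log), 30L)
  # determinism under the same seed
  f1b <- bnmf_fit(V1, k_max = 7, n_restarts = 30, seed = 63)
  expect_identical(f1$objective, f1b$objective)
  expect_identical(f1$w, f1b$w)
  expect_error(bnmf_fit(matrix(0, 3, 3)), "all-zero")
  expect_error(bnmf_fit(matrix(-1, 3, 3)), "nonnegative")
})

test_that("bnmf memberships are invariant to rescaling the input", {
  set.seed(64)
  V <- matrix(0.02, 20, 8)
  V[1:8, 1:4] <- V[1:8, 1:4] + outer(runif(8, 1, 2), runif(4, 1, 2))
  V[9:20, 5:8] <- V[9:20, 5:8] + outer(runif(12, 1, 2), runif(4, 1, 2))
  f <- bnmf_fit(V, n_restarts = 25, seed = 65)
  fc <- bnmf_fit(7 * V, n_restarts = 25, seed = 65)
  expect_identical(f$k_selected, fc$k_selected)
  m1 <- extract_clusters(f)$memberships
  m2 <- extract_clusters(fc)$memberships
  expect_identical(lapply(m1, `[[`, "variant_id"),
                   lapply(m2, `[[`, "variant_id"))
})

test_that("extract_clusters maximizes the separation SNR on the weight grid", {
  res <- structure(list(
    w = matrix(c(10, 9, 0.1, 0.05), 4, 1,
               dimnames = list(paste0("v", 1:4), "cluster1")),
    h = matrix(c(5, 1, 0.2), 1, 3,
               dimnames = list("cluster1", c("a_pos", "b_pos", "a_neg")))),
    class = "bnmf_result")
  cl <- extract_clusters(res)
  expect_setequal(cl$memberships$cluster1$variant_id, c("v1", "v2"))
  expect_identical(cl$names, "a_pos/b_pos")
  # a variant weighted high in two clusters joins both
  res2 <- structure(list(
    w = matrix(c(10, 9, 0.1, 8, 0.1, 9), 3, 2,
               dimnames = list(paste0("v", 1:3),
                               c("cluster1", "cluster2"))),
    h = matrix(runif(6), 2, 3,
               dimnames = list(c("cluster1", "cluster2"),
                               c("a_pos", "b_pos", "a_neg")))),
    class = "bnmf_result")
  both <- extract_clusters(res2)$memberships
  expect_true("v1" %in% both$cluster1$variant_id &&
              "v1" %in% both$cluster2$variant_id)
  # all-equal weights take the degenerate everything-in path
  res3 <- res
  res3$w[] <- 1
  expect_warning(cl3 <- extract_clusters(res3), "degenerate")
  expect_identical(nrow(cl3$memberships$cluster1), 4L)
})

test_that("cluster_pprs emits score weights per cluster", {
  cl <- structure(list(memberships = list(
    cluster1 = data.frame(variant_id = "v1", weight = 3),
    cluster2 = data.frame(variant_id = c("v1", "v2"), weight = c(2, 1)),
    empty = data.frame(variant_id = character(0), weight = numeric(0)))),
    class = "bnmf_clusters")
  pw <- c(v1 = 0.2, v2 = 0.07)
  expect_warning(w <- cluster_pprs(cl, pw), "empty cluster")
  expect_equal(w$cluster1, c(v1 = 0.2))
  expect_equal(w$cluster2, pw)  # overlapping variant feeds both scores
  expect_length(w$empty, 0)
  expect_error(suppressWarnings(cluster_pprs(cl, c(v1 = 0.2))),
               "without PDFF weight")
})

test_that("bnmf separates planted pathways from cohort association scans", {
  cc <- default_cohort()
  ph <- cc$coh$phenotypes
  truth <- planted_truth(cc$cfg)
  gm <- subset_variants(cc$coh$genotypes, truth$table$variant_id)
  scan1 <- function(tr, adj) assoc_scan(gm, rank_inverse_normal(ph[[tr]]),
                                        standard_covariates(ph, adj),
                                        trait = tr)
  traits <- c("pdff", "tg", "alt", "ct1", "ldl", "glucose")
  ab <- setNames(lapply(traits, function(tr)
    scan1(tr, if (tr == "pdff") "VAT" else "WHR")), traits)
  z <- build_z_matrix(ab, align_trait = "pdff",
                      trait_corr = cor(as.matrix(ph[, traits])))
  fit <- bnmf_fit(z, n_restarts = 50, seed = 66)
  expect_identical(fit$k_selected, 2L)
  mem <- extract_clusters(fit)$memberships
  sets <- lapply(mem, function(m) m$variant_id)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  disc <- truth$table$variant_id[truth$table$group == "discordant"]
  conc <- truth$table$variant_id[truth$table$group == "concordant"]
  best <- max(jac(sets[[1]], disc) + jac(sets[[2]], conc),
              jac(sets[[1]], conc) + jac(sets[[2]], disc)) / 2
  expect_gte(best, 0.7)
})
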