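test_that("ld_r2 is the squared dosage correlation", {
  D <- cbind(a = c(0, 1, 2, 2), b = c(0, 1, 1, 2), c = c(0, 1, 2, 2))
  gm <- make_gm(D)
  expect_equal(ld_r2(gm, "a", "c"), 1.0)
  # hand Pearson computation: r = 2 / sqrt(2.75 * 2), r^2 = 4 / 5.5
  expect_equal(ld_r2(gm, "a", "b"), 4 / 5.5, tolerance = 1e-12)
  expect_equal(round(ld_r2(gm, "a", "b"), 4), 0.7273)
  gm2 <- make_gm(cbind(a = c(0, 1, 2), k = c(1, 1, 1)))
  expect_error(ld_r2(gm2, "a", "k"), "constant")
})

test_that("independently simulated variants show near-zero LD", {
  set.seed(41)
  D <- matrix(rbinom(10000 * 2, 2, 0.3), 10000, 2)
  gm <- make_gm(D)
  expect_lt(ld_r2(gm, "v01", "v02"), 0.01)
})

test_that("clump applies the greedy lead/claim rule", {
  # single significant variant is its own lead
  set.seed(42)
  D <- matrix(rbinom(200 * 3, 2, 0.3), 200, 3)
  gm <- make_gm(D)
  assoc <- data.frame(variant_id = c("v01", "v02", "v03"),
                      p = c(1e-10, 0.5, 0.9))
  leads <- clump(assoc, gm, p1 = 5e-8)
  expect_identical(as.character(leads), "v01")

  # two linked significant variants 10 kb apart -> one clump, lower P leads
  pair <- make_ld_pair(2000, 0.3, sqrt(0.5), seed = 43)
  gm2 <- make_gm(pair, pos = c(1e6, 1.01e6))
  assoc2 <- data.frame(variant_id = c("causal", "tag"), p = c(1e-12, 1e-9))
  leads2 <- clump(assoc2, gm2, p1 = 5e-8, r2 = 0.01, kb = 1000)
  expect_identical(as.character(leads2), "causal")
  expect_setequal(attr(leads2, "members")$causal, c("causal", "tag"))
})

test_that("clump matches the brute-force oracle and partitions all hits", {
  for (seed in 1:5) {
    panel <- make_panel(n = 300, m = 150, seed = seed)
    leads <- clump(panel$assoc, panel$gm, p1 = 0.05, r2 = 0.2, kb = 300)
    oracle <- oracle_clump(panel$assoc, panel$gm, p1 = 0.05, r2 = 0.2,
                           kb = 300)
    expect_identical(as.character(leads), oracle)
    # every significant variant in exactly one clump; leads mutually unlinked
    members <- attr(leads, "members")
    all_assigned <- unlist(members, use.names = FALSE)
    expect_setequal(all_assigned,
                    panel$assoc$variant_id[panel$assoc$p < 0.05])
    expect_identical(anyDuplicated(all_assigned), 0L)
    v <- panel$gm$variants
    any_linked <- FALSE
    for (i in seq_along(leads)) for (j in seq_along(leads)) {
      if (j <= i || any_linked) next
      a <- match(leads[i], v$variant_id); b <- match(leads[j], v$variant_id)
      any_linked <- v$chrom[a] == v$chrom[b] &&
        abs(v$pos[a] - v$pos[b]) <= 300 * 1000 &&
        ld_r2(panel$gm, leads[i], leads[j]) >= 0.2
    }
    expect_false(any_linked)
  }
})

test_that("stepwise_conditional keeps independent signals and drops tags", {
  set.seed(44)
  n <- 8000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- rbinom(n, 2, 0.4)  # linkage equilibrium with g1
  pair <- make_ld_pair(n, 0.25, sqrt(0.95), seed = 45)
  y <- 0.15 * g1 + 0.12 * g2 + 0.2 * pair[, "causal"] + rnorm(n)
  D <- cbind(g1 = g1, g2 = g2, causal = pair[, "causal"],
             tag = pair[, "tag"])
  gm <- make_gm(D, pos = c(1e6, 2e6, 3e6, 3.01e6))
  sel <- stepwise_conditional(gm, y, candidates = colnames(D),
                              p_thresh = 5e-5)
  expect_true(all(c("g1", "g2", "causal") %in% sel))
  expect_false("tag" %in% sel)

  # no candidate below the threshold -> empty selection
  y0 <- rnorm(n)
  expect_length(stepwise_conditional(gm, y0, candidates = colnames(D)), 0)
})

test_that("merge_pleiotropic applies the distance-AND-LD edge rule", {
  n <- 3000
  pair <- make_ld_pair(n, 0.3, sqrt(0.35), seed = 46)  # r2 ~ 0.35 > 0.2
  indep <- rbinom(n, 2, 0.3)
  mk <- function(pos) make_gm(cbind(a = pair[, "causal"], b = pair[, "tag"],
                                    c = indep), pos = pos)
  leads <- data.frame(variant_id = c("a", "b", "c"),
                      trait = "pdff", adjustment = c("BMI", "VAT", "BMI"),
                      p = c(1e-10, 1e-9, 1e-8))
  # within 1 Mb and linked -> same locus (c stays alone: no LD)
  res <- merge_pleiotropic(leads, mk(c(1e6, 1.5e6, 2.0e6)))
  expect_identical(nrow(res$loci), 2L)
  expect_identical(res$loci$members[1], "a,b")
  # the per-trait lead is the lowest-P member
  lead_row <- res$lead_by_trait[res$lead_by_trait$locus_id == 1, ]
  expect_identical(lead_row$variant_id, "a")
  # far apart -> distance fails despite LD
  res2 <- merge_pleiotropic(leads[1:2, ], mk(c(1e6, 3.5e6, 9e6)))
  expect_identical(nrow(res2$loci), 2L)
  # invariant to input ordering
  res3 <- merge_pleiotropic(leads[c(3, 1, 2), ], mk(c(1e6, 1.5e6, 2.0e6)))
  expect_identical(res3$loci, res$loci)
})

test_that("merge_pleiotropic keeps unlinked neighbours apart", {
  n <- 3000
  set.seed(47)
  D <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.4))
  gm <- make_gm(D, pos = c(1e6, 1.1e6))  # 100 kb apart but r2 ~ 0
  leads <- data.frame(variant_id = c("a", "b"), trait = "pdff",
                      adjustment = "BMI", p = c(1e-9, 1e-8))
  expect_identical(nrow(merge_pleiotropic(leads, gm)$loci), 2L)
})
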