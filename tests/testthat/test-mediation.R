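gen_med <- function(n, a, b, direct, seed, sd_m = 1, sd_y = 1) {
  set.seed(seed)
  t <- rbinom(n, 2, 0.3)
  m <- a * t + rnorm(n, 0, sd_m)
  y <- direct * t + b * m + rnorm(n, 0, sd_y)
  list(t = t, m = m, y = y)
}

test_that("linear no-interaction ACME equals the product of path coefficients", {
  d <- gen_med(5000, a = 0.3, b = 0.4, direct = 0.1, seed = 71)
  mr <- mediate(d$t, d$m, d$y, n_boot = 200, seed = 72)
  a_hat <- coef(lm(d$m ~ d$t))[2]
  b_hat <- coef(lm(d$y ~ d$t + d$m))[3]
  expect_equal(mr$acme, unname(a_hat * b_hat), tolerance = 1e-10)
  expect_equal(mr$acme + mr$ade, mr$total, tolerance = 1e-12)
  expect_lt(abs(mr$acme - 0.12), 0.05)
  expect_true(mr$ci["acme", 1] <= mr$acme && mr$acme <= mr$ci["acme", 2])
  expect_identical(mr$classification, "consistent-partial")
  # deterministic given the seed
  mr2 <- mediate(d$t, d$m, d$y, n_boot = 200, seed = 72)
  expect_identical(mr$ci, mr2$ci)
})

test_that("no mediator path yields an ACME interval covering zero", {
  d <- gen_med(2000, a = 0, b = 0.4, direct = 0.3, seed = 73)
  mr <- mediate(d$t, d$m, d$y, n_boot = 200, seed = 74)
  expect_true(mr$ci["acme", 1] <= 0 && 0 <= mr$ci["acme", 2])
  expect_identical(mr$classification, "none")
})

test_that("opposite-sign mediated and total effects classify as inconsistent", {
  d <- gen_med(5000, a = 0.5, b = -0.4, direct = 0.5, seed = 75)
  # acme = -0.2, total = +0.3
  mr <- mediate(d$t, d$m, d$y, n_boot = 200, seed = 76)
  expect_lt(mr$acme, 0)
  expect_gt(mr$total, 0)
  expect_identical(mr$classification, "inconsistent")
})

test_that("classify_mediation applies the interval rules", {
  expect_identical(classify_mediation(0.1, 0.2, 0.3, c(-0.01, 0.2),
                                      c(0.1, 0.3), c(0.2, 0.4)), "none")
  expect_identical(classify_mediation(0.1, 0.01, 0.11, c(0.05, 0.15),
                                      c(-0.05, 0.07), c(0.05, 0.17)),
                   "complete")
  expect_identical(classify_mediation(-0.2, 0.5, 0.3, c(-0.3, -0.1),
                                      c(0.4, 0.6), c(0.2, 0.4)),
                   "inconsistent")
  expect_identical(classify_mediation(0.1, 0.2, 0.3, c(0.05, 0.15),
                                      c(0.1, 0.3), c(0.2, 0.4)),
                   "consistent-partial")
})

test_that("exposure-mediator interaction averages over treatment levels", {
  set.seed(77)
  n <- 6000
  t <- rbinom(n, 2, 0.3)
  m <- 0.3 * t + rnorm(n)
  y <- 0.1 * t + 0.4 * m + 0.2 * t * m + rnorm(n)
  mr <- mediate(t, m, y, n_boot = 100, interaction = TRUE, seed = 78)
  # closed form for the 0-vs-1 contrast averaged over both levels:
  # a * (b + d * (t0 + t1) / 2)
  fm <- lm(m ~ t)
  fy <- lm(y ~ t + m + t:m)
  a_hat <- coef(fm)["t"]
  oracle <- unname(a_hat * (coef(fy)["m"] + coef(fy)["t:m"] * 0.5))
  expect_equal(mr$acme, oracle, tolerance = 1e-10)
  expect_error(sensitivity_rho(mr), "without interaction")
})

test_that("sensitivity curve anchors at the primary ACME and crosses zero once", {
  d <- gen_med(2000, a = 0.5, b = 0.5, direct = 0.1, seed = 79)
  mr <- mediate(d$t, d$m, d$y, n_boot = 100, seed = 80)
  sens <- sensitivity_rho(mr, n_boot = 60, seed = 81)
  expect_equal(sens$acme[sens$rho_grid == 0], mr$acme, tolerance = 1e-10)
  # exactly one sign change across the grid
  signs <- sign(sens$acme)
  expect_identical(sum(diff(signs) != 0), 1L)
  # analytic zero-crossing sits at the observed residual correlation
  i_zero <- which(diff(sign(sens$acme)) != 0)
  expect_true(sens$rho_grid[i_zero] <= sens$rho_star &&
              sens$rho_star <= sens$rho_grid[i_zero + 1])
  # strong mediation generated with independent errors is robust
  expect_gt(abs(sens$rho_zero), 0.3)
})

test_that("mediate validates its inputs", {
  d <- gen_med(100, a = 0.3, b = 0.4, direct = 0, seed = 82)
  expect_error(mediate(d$t[1:30], d$m[1:30], d$y[1:30], n_boot = 10),
               "at least 50")
  expect_error(mediate(d$t, rep(1, 100), d$y, n_boot = 10), "constant")
})
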