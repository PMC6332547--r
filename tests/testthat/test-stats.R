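test_that("odds_ratio satisfies symmetry, swap and inversion invariants", {
  expect_equal(odds_ratio(10, 10, 10, 10)$or, 1)

  orr <- odds_ratio(6, 15, 20, 142)
  # swapping both rows and both columns simultaneously leaves the OR fixed
  swapped <- odds_ratio(142, 20, 15, 6)
  expect_equal(swapped$or, orr$or)
  # swapping groups inverts the OR
  inv <- odds_ratio(20, 142, 6, 15)
  expect_equal(inv$or, 1 / orr$or)
  expect_equal(inv$ci_low, 1 / orr$ci_high)
  expect_equal(inv$p, orr$p)
})

test_that("odds_ratio flags zero cells as non-estimable with the degenerate point estimate", {
  z <- odds_ratio(0, 14, 20, 95)
  expect_false(z$estimable)
  expect_equal(z$or, 0)
  expect_true(is.na(z$p))
  expect_error(odds_ratio(1.5, 2, 3, 4), "integer")
})

test_that("univariate logistic regression on a binary covariate equals the 2x2 closed form", {
  # counts: exposed 6/15, reference 20/142 (the gender table)
  x <- c(rep(1, 21), rep(0, 162))
  y <- c(rep(1, 6), rep(0, 15), rep(1, 20), rep(0, 142))
  fit <- logistic_fit_univariate(x, y)
  orr <- odds_ratio(6, 15, 20, 142)
  expect_equal(fit$or_per_unit, orr$or, tolerance = 1e-7)
  expect_equal(fit$ci_low, orr$ci_low, tolerance = 1e-6)
  expect_equal(fit$ci_high, orr$ci_high, tolerance = 1e-6)
  expect_equal(fit$p, orr$p, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("logistic regression flags degenerate designs instead of estimating", {
  expect_error(logistic_fit_univariate(1:10, rep(1, 10)), "both outcome")

  flat <- logistic_fit_univariate(rep(2, 20), rep(c(0, 1), 10))
  expect_false(flat$identifiable)
  expect_true(is.na(flat$beta))

  # complete separation
  sep <- logistic_fit_univariate(c(1:10, 21:30),
                                 c(rep(0, 10), rep(1, 10)))
  expect_false(sep$converged)
})

test_that("logistic regression recovers a known slope", {
  set.seed(31)
  n <- 5000
  x <- rnorm(n)
  beta_true <- 0.35
  y <- rbinom(n, 1, plogis(-1 + beta_true * x))
  fit <- logistic_fit_univariate(x, y)
  expect_lt(abs(fit$beta - beta_true), 3 * fit$se)
  expect_true(fit$converged)
})

test_that("Mann-Whitney U handles the textbook cases", {
  a <- c(3, 1, 4, 1, 5)
  same <- mann_whitney_u(a, a)
  expect_equal(same$u, length(a)^2 / 2)
  expect_gt(same$p, 0.9)

  small <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(small$u, 0)
  expect_equal(small$p, 2 / 6)
  expect_equal(small$method, "exact")

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney U from midranks matches the enumeration oracle, and the normal approximation is close at n=8+8", {
  set.seed(41)
  for (rep_i in 1:5) {
    a <- round(rnorm(8), 3)
    b <- round(rnorm(8, 0.4), 3)
    res <- mann_whitney_u(a, b)
    expect_equal(res$method, "normal_approx")
    expect_lt(abs(res$p - oracle_mwu_exact(a, b)), 0.02)
  }
})

test_that("paired mean difference covers exact shifts and degenerate variance", {
  x <- rnorm(20)
  same <- paired_mean_difference(x, x)
  expect_equal(same$mean_difference, 0)
  expect_true(same$degenerate)

  shifted <- paired_mean_difference(x + 1.7, x)
  expect_equal(shifted$mean_difference, 1.7)
  expect_true(shifted$degenerate)
  expect_equal(shifted$ci_low, shifted$ci_high)

  expect_error(paired_mean_difference(1:3, 1:4), "length mismatch")
})

test_that("paired-difference CI covers the true simulated 1.7 Gy offset in most replicates", {
  cover <- 0
  for (s in 1:100) {
    co <- simulate_cohort(cohort_config(seed = s))
    pd <- paired_mean_difference(co$mld_lungpgtv, co$mld_lungptv)
    if (pd$ci_low <= 1.7 && 1.7 <= pd$ci_high) cover <- cover + 1
  }
  expect_gte(cover, 93)
})

test_that("repeated-measures ANOVA matches the aov Error-stratum oracle and detects shifts", {
  set.seed(51)
  n <- 12
  vals <- cbind(rnorm(n), rnorm(n, 0.5), rnorm(n, 1))
  res <- repeated_measures_anova(vals)

  # aov with a within-subject error stratum as independent oracle
  long <- data.frame(y = as.vector(vals),
                     subject = factor(rep(seq_len(n), times = 3)),
                     condition = factor(rep(1:3, each = n)))
  tab <- summary(aov(y ~ condition + Error(subject),
                     data = long))[["Error: Within"]][[1]]
  expect_equal(res$f, tab["condition", "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab["condition", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 2 * (n - 1))

  # constant shifts with noise, n = 200: overwhelming evidence
  n2 <- 200
  base <- rnorm(n2)
  big <- cbind(base + rnorm(n2, 0, .3), base + 1 + rnorm(n2, 0, .3),
               base + 2 + rnorm(n2, 0, .3))
  expect_lt(repeated_measures_anova(big)$p, 0.001)
})

test_that("repeated-measures ANOVA flags degenerate inputs", {
  x <- rnorm(10)
  ident <- repeated_measures_anova(cbind(x, x, x))
  expect_equal(ident$degenerate, "identical_columns")
  expect_true(is.na(ident$f))

  shift <- repeated_measures_anova(cbind(x, x + 1, x + 2))
  expect_equal(shift$degenerate, "zero_error_variance")
  expect_equal(shift$p, 0)

  expect_error(repeated_measures_anova(cbind(1:2, 2:3, 3:4)), ">= 3 subjects")
})

test_that("repeated-measures ANOVA holds its type-I error under the null", {
  set.seed(61)
  rej <- 0; reps <- 1000
  for (i in seq_len(reps)) {
    vals <- matrix(rnorm(20 * 3), 20, 3) + rnorm(20)  # subject effects only
    if (repeated_measures_anova(vals)$p < 0.05) rej <- rej + 1
  }
  # binomial MC error: 3 * sqrt(.05 * .95 / 1000) ~ 0.021
  expect_gt(rej / reps, 0.05 - 0.021)
  expect_lt(rej / reps, 0.05 + 0.021)
})
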