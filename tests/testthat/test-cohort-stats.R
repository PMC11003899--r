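# Statistical machinery: normality gate, gated comparisons,
# categorical tests, correlations, median split, regression strategy.

test_that("the normality gate admits normal samples and rejects log-normal ones", {
  set.seed(51)
  verdicts_norm <- replicate(400, normality_gate(rnorm(500))$is_normal)
  expect_gte(mean(verdicts_norm), 0.93)
  verdicts_ln <- replicate(200, normality_gate(rlnorm(500, sdlog = 1))$is_normal)
  expect_lte(mean(verdicts_ln), 0.01)
  # constant vector: degenerate, not normal
  g <- normality_gate(rep(3.2, 10))
  expect_false(g$is_normal); expect_true(g$degenerate)
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("the comparison branch is a pure function of the samples", {
  set.seed(52)
  x <- rnorm(54); y <- rnorm(32)
  expect_identical(compare_groups(x, y)$test_used, compare_groups(x, y)$test_used)
  expect_identical(compare_groups(x, y)$test_used, "t")
  xs <- rlnorm(54, sdlog = 1.5); ys <- rlnorm(32, sdlog = 1.5)
  expect_identical(compare_groups(xs, ys)$test_used, "wilcoxon")
  # identical samples on the t branch: statistic 0, p = 1
  cr <- compare_groups(x, x)
  expect_identical(cr$test_used, "t")
  expect_equal(cr$statistic, 0)
  expect_equal(cr$p_value, 1)
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("the gated comparison has power against a one-SD shift at cohort sizes", {
  set.seed(53)
  p <- replicate(400, compare_groups(rnorm(54), rnorm(32, mean = 1))$p_value)
  expect_gt(mean(p < 0.05), 0.9)
})

test_that("chi-squared matches the formula oracle and the smoking table", {
  # smoker-by-sex counts: near-identical proportions, so p is large
  res <- chi_squared_test(matrix(c(12, 7, 42, 25), 2))
  expect_gt(res$p_value, 0.9)
  # balanced table: statistic 0
  expect_equal(chi_squared_test(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  # any table equals sum((O-E)^2/E)
  set.seed(54)
  for (trial in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    res <- chi_squared_test(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E))
  }
  expect_error(chi_squared_test(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
  expect_error(chi_squared_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("correlation estimates are calibrated at the subgroup scale", {
  expect_equal(correlate(1:10, 1:10)$r, 1)
  set.seed(55)
  # permutation null: mean r near 0
  r_null <- replicate(1000, correlate(rnorm(20), rnorm(20))$r)
  expect_lt(abs(mean(r_null)), 0.05)
  # planted rho = -0.48 at n = 32 recovered on average
  rho <- -0.48
  r_alt <- replicate(2000, {
    x <- rnorm(32); y <- rho * x + sqrt(1 - rho^2) * rnorm(32)
    correlate(x, y)$r
  })
  expect_lt(abs(mean(r_alt) - rho), 0.05)
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate(1:3, 3:1), "at least 4")
})

test_that("median split partitions with ties going low", {
  df <- data.frame(mean_gd = c(1, 2, 3), v = c(10, 20, 30))
  sp <- median_split(df, "mean_gd", compare = character(0))
  expect_identical(sp$low$mean_gd, c(1, 2))
  expect_identical(sp$high$mean_gd, 3)

  set.seed(56)
  df2 <- data.frame(mean_gd = sample(seq(1.3, 3.5, length.out = 86)))
  sp2 <- median_split(df2, "mean_gd", compare = character(0))
  expect_identical(nrow(sp2$low), 43L)
  expect_identical(nrow(sp2$high), 43L)
  expect_identical(nrow(sp2$low) + nrow(sp2$high), nrow(df2))
})

test_that("median split on a planted negative density-area cohort finds larger areas at low density", {
  co <- generate_cohort(seed = 57L)$subjects   # planted cor(gd, area) < 0
  sp <- median_split(co, "mean_gd", compare = "mean_area")
  row <- sp$comparison[sp$comparison$variable == "mean_area", ]
  expect_gt(row$mean_low, row$mean_high)
  expect_lt(row$p_value, 0.05)
})

test_that("regression recovers slopes and screens noise covariates", {
  set.seed(58)
  # slope recovery: truth inside the unadjusted CI
  x <- rnorm(86); y <- 2 * x + rnorm(86, 0, 0.4)
  rr <- regression_strategy(data.frame(y = y, x = x), "y", "x")
  expect_lte(rr$table$ci_lower[1], 2)
  expect_gte(rr$table$ci_upper[1], 2)
  expect_identical(rr$selected, "x")

  # a pure-noise covariate stays out of the adjusted model ~95% of runs
  kept_noise <- replicate(600, {
    x <- rnorm(86); z <- rnorm(86); y <- 2 * x + rnorm(86, 0, 0.5)
    rr <- regression_strategy(data.frame(y = y, x = x, z = z), "y", c("x", "z"))
    "z" %in% rr$selected
  })
  expect_gte(mean(!kept_noise), 0.93)
})

test_that("a log-normal outcome triggers the log-transform branch", {
  set.seed(59)
  x <- rnorm(120)
  y <- exp(1 + 1.5 * x + rnorm(120, 0, 0.6))
  rr <- regression_strategy(data.frame(y = y, x = x), "y", "x")
  expect_true(rr$log_transformed)
  # after the transform the slope is on the log scale
  expect_equal(unname(coef(rr$full_model)["x"]), 1.5, tolerance = 0.2)
})

test_that("collinear covariates are refused with the offending pair named", {
  set.seed(60)
  x <- rnorm(50)
  df <- data.frame(y = rnorm(50), a = x, b = 2 * x + 1e-9 * rnorm(50))
  expect_error(regression_strategy(df, "y", c("a", "b")), "collinear.*a.*b")
  expect_error(regression_strategy(df[1:5, ], "y", "a"), "at least 10")
})
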