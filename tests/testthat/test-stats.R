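# Fixed two- and three-group ADC samples reused across the frozen-oracle
# checks below.
grp_a <- c(1.31, 0.95, 1.12, 1.48, 1.02, 1.25, 0.88, 1.17)
grp_b <- c(0.92, 0.81, 1.05, 0.74, 0.99, 0.68, 0.85)
grp_c <- c(1.55, 1.62, 1.38, 1.71, 1.49, 1.58)

test_that("t test degenerates and symmetries behave", {
  x <- c(1.0, 1.1, 1.2, 1.3)
  same <- adc_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ab <- adc_t_test(grp_a, grp_b)
  ba <- adc_t_test(grp_b, grp_a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(adc_t_test(1, grp_b), "at least 2")
})

test_that("Welch p agrees with the frozen permutation oracle", {
  # 0.00625: tail probability of |t| under 1e5 random relabelings of the
  # pooled grp_a/grp_b sample, computed once and frozen; Monte-Carlo SE at
  # that p is ~2.5e-4
  res <- adc_t_test(grp_a, grp_b, welch = TRUE)
  expect_equal(res$p_value, 0.00625, tolerance = 0.15)
  expect_gt(res$statistic, 0)
})

test_that("one-way ANOVA matches its algebraic identities", {
  # identical groups: zero between-group variance
  x <- c(1.0, 1.2, 1.4)
  null <- adc_anova(c(x, x, x), rep(1:3, each = 3))
  expect_equal(null$F, 0)
  expect_equal(null$p_value, 1)
  # two groups: F is the square of the pooled-variance t statistic
  two <- adc_anova(c(grp_a, grp_b), rep(c("a", "b"), c(8, 7)))
  t_pooled <- adc_t_test(grp_a, grp_b, welch = FALSE)
  expect_equal(two$F, t_pooled$statistic^2)
  expect_equal(two$p_value, t_pooled$p_value)
})

test_that("three-group ANOVA equals the explicit sum-of-squares decomposition", {
  vals <- c(grp_a, grp_b, grp_c)
  g <- rep(c("a", "b", "c"), c(8, 7, 6))
  res <- adc_anova(vals, g)
  # direct decomposition
  gm <- mean(vals)
  means <- tapply(vals, g, mean)
  ns <- tapply(vals, g, length)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((vals - means[g])^2)
  df1 <- 2; df2 <- length(vals) - 3
  F_oracle <- (ss_between / df1) / (ss_within / df2)
  expect_equal(res$F, F_oracle, tolerance = 1e-12)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_equal(res$p_value, pf(F_oracle, df1, df2, lower.tail = FALSE))
})

test_that("Games-Howell with two groups reduces to the Welch t test", {
  gh <- games_howell(c(grp_a, grp_b), rep(c("a", "b"), c(8, 7)))
  wt <- adc_t_test(grp_a, grp_b, welch = TRUE)
  expect_identical(nrow(gh), 1L)
  expect_equal(gh$q, abs(wt$statistic) * sqrt(2), tolerance = 1e-12)
  expect_equal(gh$df, wt$df, tolerance = 1e-12)
  expect_equal(gh$p_value, wt$p_value, tolerance = 1e-9)
})

test_that("Games-Howell matches the frozen reference implementation", {
  # p-values computed once with an independent Games-Howell implementation
  # (Python pingouin.pairwise_gameshowell) on the same fixed three groups
  gh <- games_howell(c(grp_a, grp_b, grp_c), rep(c("a", "b", "c"), c(8, 7, 6)))
  frozen <- c("a-b" = 0.015817, "a-c" = 0.001228, "b-c" = 0.000002)
  got <- setNames(gh$p_value, paste(gh$group1, gh$group2, sep = "-"))
  expect_equal(got[names(frozen)], frozen, tolerance = 5e-4)
  # pairwise p is invariant to observation and group ordering
  idx <- sample(21)
  gh2 <- games_howell(c(grp_a, grp_b, grp_c)[idx],
                      rep(c("a", "b", "c"), c(8, 7, 6))[idx])
  expect_equal(gh2$p_value, gh$p_value)
})

test_that("Games-Howell flags zero-variance pairs instead of failing", {
  vals <- c(rep(1, 3), rep(1, 3), c(1.2, 1.4, 1.3))
  gh <- games_howell(vals, rep(c("a", "b", "c"), each = 3))
  flagged <- gh[gh$group1 == "a" & gh$group2 == "b", ]
  expect_identical(flagged$flag, "zero_variance")
  expect_equal(flagged$p_value, 1)   # equal means, no evidence either way
  expect_true(all(gh$p_value >= 0 & gh$p_value <= 1))
})

test_that("regression reproduces the normal-equations solution", {
  co <- generate_cohort(default_generator_config(n_lesions = 250), seed = 21)
  fit <- suppressMessages(adc_regression(co, on_alias = "drop"))
  # independent normal-equations solve on the same design
  X <- model.matrix(fit$fit)
  beta <- solve(t(X) %*% X, t(X) %*% co$adc)
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  n <- nrow(X); p <- ncol(X) - 1
  resid <- co$adc - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((co$adc - mean(co$adc))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_equal(fit$adjusted_r_squared,
               1 - (1 - r2) * (n - 1) / (n - p - 1), tolerance = 1e-10)
})

test_that("regression degenerate cases: exact fit, pure noise, aliasing", {
  co <- make_cohort(adc = numeric(120), outcome = rep("benign", 120))
  co$size_mm <- seq(3, 60, length.out = 120)
  co$adc <- 0.5 + 0.01 * co$size_mm            # exactly linear, no noise
  fit <- suppressWarnings(suppressMessages(
    adc_regression(co, include_diagnosis = FALSE)))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(6)
  co$adc <- runif(120, 0.8, 1.6)               # pure noise
  fit2 <- suppressMessages(adc_regression(co, include_diagnosis = FALSE))
  expect_lt(abs(fit2$adjusted_r_squared), 0.05)
  # vendor is nested in center on the default cohort: error names it,
  # drop mode removes it
  big <- generate_cohort(default_generator_config(n_lesions = 400), seed = 3)
  expect_error(adc_regression(big), "vendor")
  dropped <- suppressMessages(adc_regression(big, on_alias = "drop"))
  expect_true("vendor" %in% dropped$dropped)
})

test_that("size-stratified comparisons cover the four published contrasts", {
  co <- generate_cohort(default_generator_config(), seed = 12)
  st <- size_stratified_tests(co)
  expect_identical(nrow(st), 4L)
  expect_true(all(st$p_value >= 0 & st$p_value <= 1))
  # benign vs malignant differs strongly within both size strata
  expect_lt(st$p_value[st$comparison == "small: benign vs malignant"], 0.001)
  expect_lt(st$p_value[st$comparison == "large: benign vs malignant"], 0.001)
})
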