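test_that("build_curve agrees exactly with the quadratic recount oracle", {
  for (seed in 1:20) {
    co <- random_cohort(sample(5:40, 1), seed)
    cv <- build_curve(co)
    oc <- oracle_curve(co$adc, co$outcome == "malignant")
    expect_equal(as.data.frame(cv), oc, ignore_attr = TRUE, info = seed)
    expect_identical(attr(cv, "n_total"), nrow(co))
  }
})

test_that("curve structure: descending ADC, non-decreasing counts, totals", {
  co <- random_cohort(60, 101)
  cv <- build_curve(co)
  expect_true(all(diff(cv$adc) < 0))
  expect_true(all(diff(cv$cum_malignant) >= 0))
  expect_true(all(diff(cv$cum_total) >= 0))
  expect_identical(cv$cum_total[nrow(cv)], nrow(co))
  expect_identical(cv$cum_malignant[nrow(cv)],
                   sum(co$outcome == "malignant"))
  # lesions without measurable ADC are excluded from the curve
  co$adc[1:5] <- NA
  expect_identical(attr(build_curve(co), "n_total"), nrow(co) - 5L)
  co$adc <- NA_real_
  expect_error(build_curve(co), "measurable ADC")
})

test_that("an all-benign cohort has a flat zero curve", {
  co <- make_cohort(c(0.9, 1.2, 1.2, 2.0), rep("benign", 4))
  cv <- build_curve(co)
  expect_true(all(cv$cum_rate == 0))
  expect_identical(nrow(cv), 3L)   # tied values collapse into one point
})

test_that("rate_at_threshold counts the closed-lower-bound tail", {
  co <- random_cohort(80, 55)
  cv <- build_curve(co)
  mal <- co$outcome == "malignant"
  for (t in c(0, 0.5, 1.0, 1.27, max(co$adc), max(co$adc) + 0.1)) {
    expect_equal(rate_at_threshold(cv, t),
                 sum(mal & co$adc >= t) / nrow(co))
  }
  expect_equal(rate_at_threshold(cv, 0), mean(mal))
  expect_equal(rate_at_threshold(cv, max(co$adc) + 1), 0)
  # non-increasing in the threshold
  grid <- seq(0, 3, by = 0.05)
  expect_true(all(diff(rate_at_threshold(cv, grid)) <= 0))
})

test_that("threshold_at_rate finds the crossing and rounds it", {
  # wide benign spread, all malignancy below 1.2: the crossing for a tiny
  # target must sit at or above 1.2 (checked against an exhaustive scan)
  set.seed(7)
  ben <- round(runif(60, 0.4, 2.6), 2)
  mal <- round(runif(15, 0.3, 1.19), 2)
  co <- make_cohort(c(ben, mal), rep(c("benign", "malignant"), c(60, 15)))
  cv <- build_curve(co)
  res <- threshold_at_rate(cv, 0.001, decimals = 1)
  expect_true(res$attained)
  # a 0.1% target over 75 lesions tolerates no malignant tail at all, so
  # the crossing must clear every malignant ADC
  expect_gt(res$raw_threshold, max(mal))
  # exhaustive scan over observed values: smallest ADC with rate <= target
  ok <- sort(co$adc)[vapply(sort(co$adc), function(t)
    rate_at_threshold(cv, t) <= 0.001, TRUE)]
  expect_equal(res$raw_threshold, min(ok))
  expect_equal(res$threshold, round(min(ok), 1))
})

test_that("threshold_at_rate handles degenerate and unattainable cases", {
  # all-benign: any target is met by the lowest observed ADC
  co <- make_cohort(c(0.82, 1.4, 2.1), rep("benign", 3))
  res <- threshold_at_rate(build_curve(co), 0.01)
  expect_true(res$attained)
  expect_equal(res$raw_threshold, 0.82)
  expect_equal(res$threshold, 0.8)
  expect_equal(res$rate_at_raw, 0)
  # single-ADC malignant cohort: target unattainable, flagged not thrown
  co2 <- make_cohort(rep(1.1, 4), rep("malignant", 4))
  res2 <- threshold_at_rate(build_curve(co2), 0.05)
  expect_false(res2$attained)
  expect_equal(res2$threshold, 1.1)
})

test_that("a smaller target rate never yields a smaller threshold", {
  for (seed in c(3, 9, 21)) {
    cv <- build_curve(random_cohort(100, seed))
    targets <- c(0.001, 0.005, 0.02, 0.1, 0.3, 0.6)
    thr <- vapply(targets, function(tr)
      threshold_at_rate(cv, tr)$threshold, numeric(1))
    raw <- vapply(targets, function(tr)
      threshold_at_rate(cv, tr)$raw_threshold, numeric(1))
    expect_true(all(diff(raw) <= 0), info = seed)
    expect_true(all(diff(thr) <= 0), info = seed)
  }
})

test_that("benchmark cohort reproduces the published cumulative rates", {
  cv <- build_curve(reference_cohort())
  rates <- rate_at_threshold(cv, c(1.9, 1.5, 1.0))
  expect_equal(rates, c(2, 30, 425) / 1736, tolerance = 1e-12)
  expect_equal(round(100 * rates, 1), c(0.1, 1.7, 24.5))
  # and the curve-read thresholds for the published targets round to the
  # published one-decimal cut-offs
  expect_equal(threshold_at_rate(cv, 0.001)$threshold, 1.9)
  expect_equal(threshold_at_rate(cv, 0.02)$threshold, 1.5)
})

test_that("curve export writes one row per distinct ADC", {
  cv <- build_curve(random_cohort(30, 77))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, path)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(cv))
  expect_equal(back$cum_rate, cv$cum_rate)
})
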