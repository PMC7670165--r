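test_that("normality screening behaves on normal, bimodal and tiny samples", {
  x <- withr::with_seed(1, rnorm(100))
  # frozen reference value for this fixed draw (Shapiro-Wilk)
  expect_equal(normality_test(x), 0.9876221, tolerance = 1e-6)
  bimodal <- withr::with_seed(2, c(rnorm(50, -4, 0.5), rnorm(50, 4, 0.5)))
  expect_lt(normality_test(bimodal), 0.01)
  expect_error(normality_test(c(1, 2)), class = "coronoid_precondition_error")
})

test_that("t statistics match the closed-form hand computation", {
  a <- c(1.1, 2.3, 3.7, 2.2, 4.1)
  b <- c(2.0, 3.5, 4.4, 3.1, 5.0)
  # equal-variance independent t, df = na + nb - 2
  sp2 <- ((4 * var(a)) + (4 * var(b))) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  res <- independent_t(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, 8)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-9)
  # identical groups: t = 0, p = 1
  same <- independent_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # strong separation
  expect_lt(independent_t(c(1, 2, 3), c(11, 12, 13))$p, 0.01)
})

test_that("paired t equals the one-sample t on differences", {
  a <- c(12.1, 11.8, 13.0, 12.6, 12.9)
  b <- c(12.5, 12.0, 13.4, 12.4, 13.3)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  res <- paired_t(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(paired_t(a, a)$t, 0)
  # constant shift gives an exact, infinite-precision t via sd(d) = 0?
  # a near-constant shift instead: large |t|
  expect_gt(abs(paired_t(a, a + 2 + 1e-3 * d)$t), 100)
  expect_error(paired_t(a, b[1:3]), class = "coronoid_precondition_error")
})

test_that("sample size search agrees with the noncentral-t power oracle", {
  expect_identical(sample_size_two_sample(0.5, 0.05, 0.2), 64L)
  expect_identical(sample_size_two_sample(0.5),
                   as.integer(ceiling(power.t.test(delta = 0.5, sd = 1,
                                                   power = 0.8)$n)))
  expect_identical(sample_size_two_sample(50), 2L)
  expect_error(sample_size_two_sample(0), class = "coronoid_precondition_error")
  # returned n achieves the power, n-1 does not
  n <- sample_size_two_sample(0.8)
  expect_gte(coronoid:::two_sample_t_power(n, 0.8, 0.05), 0.8)
  expect_lt(coronoid:::two_sample_t_power(n - 1, 0.8, 0.05), 0.8)
})

test_that("the cohort report covers every parameter-by-grouping comparison", {
  tbl <- simulate_measurement_cohort(40, seed = 3)
  rep <- build_report(tbl)
  expect_s3_class(rep, "cohort_comparisons")
  expect_equal(nrow(rep), 17L) # 6 params x 3 groupings, no laterality covering
  expect_equal(sum(rep$grouping == "laterality"), 5L)
  expect_true(all(rep$test_type[rep$grouping == "laterality"] == "paired"))
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  expect_true(all(is.finite(rep$normality_p)))
  expect_error(build_report(tbl[0, ]), class = "coronoid_precondition_error")
  txt <- format_report_text(rep)
  expect_length(txt, 17L)
  g <- glance(rep)
  expect_equal(g$n_comparisons, 17L)
})

test_that("an injected systematic side difference is detected with high power", {
  pvals <- sapply(1:50, function(i) {
    tbl <- simulate_measurement_cohort(60, seed = 5000 + i,
                                       right_shift = c(height_mm = 2))
    rep <- build_report(tbl)
    rep$p[rep$grouping == "laterality" & rep$parameter == "height_mm"]
  })
  expect_gte(mean(pvals < 0.01), 0.95)
})
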