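test_that("parameter validation rejects unphysical generators", {
  expect_error(synthetic_ulna_params(coronoid_height = -1),
               class = "coronoid_validation_error")
  expect_error(synthetic_ulna_params(asymmetry_scale = 3),
               class = "coronoid_validation_error")
  expect_error(synthetic_ulna_params(n_points = 100),
               class = "coronoid_validation_error")
  expect_error(synthetic_ulna_params(noise_sigma = -0.1),
               class = "coronoid_validation_error")
})

test_that("the left side is the exact mirror of the right when symmetric", {
  p <- synthetic_ulna_params(noise_sigma = 0, asymmetry_scale = 1,
                             asymmetry_warp = 0, n_points = 4000, seed = 21)
  pr <- generate_ulna_pair(p)
  mir <- pr$right$model$points
  mir[, 1] <- -mir[, 1]
  expect_lt(max(abs(pr$left$model$points - mir)), 1e-9)
  expect_identical(pr$left$ground_truth$articular,
                   pr$right$ground_truth$articular)
})

test_that("seeds control noise but not landmarks", {
  p1 <- synthetic_ulna_params(noise_sigma = 0.2, n_points = 4000, seed = 5)
  a <- generate_ulna(p1, "right")
  b <- generate_ulna(p1, "right")
  expect_identical(a$model$points, b$model$points) # same seed, same surface
  p2 <- synthetic_ulna_params(noise_sigma = 0.2, n_points = 4000, seed = 6)
  c_ <- generate_ulna(p2, "right")
  expect_false(isTRUE(all.equal(a$model$points, c_$model$points)))
  expect_equal(a$ground_truth$tip, c_$ground_truth$tip) # landmarks fixed
  expect_equal(a$ground_truth$measurements, c_$ground_truth$measurements)
})

test_that("ground-truth measurements follow the fragment-fraction rule", {
  p <- synthetic_ulna_params(coronoid_height = 30, coronoid_length = 22,
                             coronoid_width = 24, r_medial = 6, r_lateral = 12,
                             noise_sigma = 0, n_points = 4000, seed = 2)
  gt <- generate_ulna(p, "right")$ground_truth$measurements
  expect_equal(gt$height_mm, 0.4 * 30)
  expect_equal(gt$total_height_mm, 30)
  expect_equal(gt$length_mm, 22)
  expect_equal(gt$width_mm, 24)
  # the scaled left side scales every ground-truth value
  p2 <- synthetic_ulna_params(coronoid_height = 30, asymmetry_scale = 1.2,
                              noise_sigma = 0, n_points = 4000, seed = 2)
  gtl <- generate_ulna(p2, "left")$ground_truth$measurements
  expect_equal(gtl$height_mm, 1.2 * 0.4 * 30)
})

test_that("cohort draws reproduce the population means", {
  co <- generate_cohort(128, seed = 31)
  tbl <- co$table
  mu <- c(height = 12.40, length = 23.81, width = 23.12,
          r_medial = 6.44, r_lateral = 11.84)
  sdv <- c(height = 2.74, length = 2.67, width = 1.92,
           r_medial = 1.01, r_lateral = 3.71)
  for (nm in names(mu)) {
    se <- sdv[[nm]] / sqrt(128)
    expect_lt(abs(mean(tbl[[nm]]) - mu[[nm]]), 3 * se)
  }
  expect_true(all(tbl$age > 0))
  expect_true(all(tbl$asymmetry_scale >= 0.5 & tbl$asymmetry_scale <= 2))
  # reproducibility and the minimal cohort
  expect_identical(generate_cohort(128, seed = 31)$table, tbl)
  expect_equal(nrow(generate_cohort(2, seed = 1)$table), 2L)
  expect_error(generate_cohort(1), class = "coronoid_validation_error")
  expect_error(generate_cohort(10, sds = list(height = -1)),
               class = "coronoid_validation_error")
})

test_that("measurement-level cohorts hold the bilateral null exactly", {
  tbl <- simulate_measurement_cohort(200, seed = 9)
  wide <- tidyr::pivot_wider(tbl[, c("subject_id", "side", "height_mm")],
                             names_from = "side", values_from = "height_mm")
  d <- wide$left - wide$right
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(200))
  expect_identical(tbl, simulate_measurement_cohort(200, seed = 9))
})
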