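matrix_model <- function() {
  surface_model(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                faces = rbind(c(1L, 2L, 3L)))
}

test_that("mirroring is an involution that negates X and flips the side", {
  m <- small_pair()$right$model
  mm <- mirror_surface(m)
  expect_equal(mm$points[, 1], -m$points[, 1])
  expect_equal(mm$points[, 2:3], m$points[, 2:3])
  expect_equal(mm$side, "left")
  expect_identical(mirror_surface(mm)$points, m$points)
  expect_equal(mirror_surface(matrix_model())$faces[1, ], c(1L, 3L, 2L))
})

test_that("bilateral alignment overlays the frames of a symmetric pair", {
  pr <- small_pair()
  L <- suppressWarnings(analyze_side(pr$left$model))
  R <- suppressWarnings(analyze_side(pr$right$model))
  al <- align_bilateral(L$local, R$local)
  nn <- RANN::nn2(al$right$points, al$left$points, k = 1)$nn.dists[, 1]
  expect_lt(sqrt(mean(nn^2)), 0.1)
  expect_lt(al$tip_offset_mm, 0.2)
  expect_error(align_bilateral(pr$left$model, pr$right$model),
               class = "coronoid_precondition_error")
})

test_that("articular extraction matches the generator labels", {
  pr <- small_pair()
  side <- suppressWarnings(analyze_side(pr$right$model))
  frag <- side$fragment
  gl <- pr$right$ground_truth$articular[frag$indices]
  ex <- rep(FALSE, nrow(frag$points))
  ex[frag$articular] <- TRUE
  jac <- sum(ex & gl) / sum(ex | gl)
  expect_gte(jac, 0.8)
  # cone limits: everything at 180 degrees, a single point at 0
  all_idx <- extract_articular_surface(frag, cone_deg = 180)
  expect_equal(length(all_idx), nrow(frag$points))
  one <- extract_articular_surface(frag, cone_deg = 0)
  expect_lte(length(one), 1L)
})

test_that("proximity masks equal the brute-force all-pairs computation", {
  for (s in 1:20) {
    sets <- withr::with_seed(100 + s, {
      na <- sample(20:500, 1)
      nb <- sample(20:500, 1)
      list(a = cbind(runif(na, 0, 10), runif(na, 0, 10), runif(na, 0, 3)),
           b = cbind(runif(nb, 0, 10), runif(nb, 0, 10), runif(nb, 0, 3)))
    })
    pr <- proximity_region(sets$a, sets$b, d = 2)
    dm <- as.matrix(dist(rbind(sets$a, sets$b)))
    na <- nrow(sets$a)
    cross <- dm[seq_len(na), -seq_len(na), drop = FALSE]
    expect_identical(pr$mask_a, unname(apply(cross, 1, min) <= 2))
    expect_identical(pr$mask_b, unname(apply(cross, 2, min) <= 2))
  }
  # trivial limits
  idm <- cbind(1:10, 0, 0)
  expect_true(all(unlist(proximity_region(idm, idm, 2))))
  far <- proximity_region(idm, idm + matrix(c(0, 3, 0), 10, 3, TRUE), 2)
  expect_false(any(unlist(far)))
})

test_that("covering percentage implements the bilateral area formula", {
  expect_identical(covering_percentage(8, 10, 10), 80)
  expect_identical(covering_percentage(0, 5, 7), 0)
  expect_identical(covering_percentage(10, 10, 10), 100)
  expect_error(covering_percentage(1, 0, 5), class = "coronoid_degenerate_error")
  expect_error(covering_percentage(-1, 5, 5), class = "coronoid_degenerate_error")
})

test_that("a mirrored identical pair covers itself completely", {
  pr <- small_pair()
  res <- suppressWarnings(run_subject(pr$left$model, pr$right$model))
  expect_gte(res$match$covering_percentage, 99.9)
  expect_equal(res$match$S1, res$match$S2, tolerance = 0.02 * res$match$S1)
  expect_true(all(res$match$proximity_mask_left))
})

test_that("covering collapses when one side is displaced past the threshold", {
  pr <- small_pair()
  L <- suppressWarnings(analyze_side(pr$left$model))
  R <- suppressWarnings(analyze_side(pr$right$model))
  fragL <- L$fragment
  fragL$points[, 1] <- -fragL$points[, 1]
  fragL$notch_center[1] <- -fragL$notch_center[1]
  slid <- fragL
  slid$points[, 2] <- slid$points[, 2] + 5 # 5 mm anterior slide
  m_slide <- match_pair(slid, R$fragment, d = 2)
  # sliding along the articular sheet leaves partial overlap but far from
  # identity; displacing along the sheet normal separates it completely
  expect_lt(m_slide$covering_percentage, 60)
  lifted <- fragL
  lifted$points[, 3] <- lifted$points[, 3] + 5 # 5 mm proximal lift
  m_lift <- match_pair(lifted, R$fragment, d = 2)
  expect_lt(m_lift$covering_percentage, 5)
})

test_that("the covering statistic is symmetric under side swap", {
  pr <- small_pair()
  L <- suppressWarnings(analyze_side(pr$left$model))
  R <- suppressWarnings(analyze_side(pr$right$model))
  fragL <- L$fragment
  fragL$points[, 1] <- -fragL$points[, 1]
  fragL$notch_center[1] <- -fragL$notch_center[1]
  m1 <- match_pair(fragL, R$fragment)
  m2 <- match_pair(R$fragment, fragL)
  expect_equal(m1$covering_percentage, m2$covering_percentage, tolerance = 1e-6)
  td <- tidy(m1)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$covering_pct, m1$covering_percentage)
})
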