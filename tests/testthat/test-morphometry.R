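side_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(analyze_side(small_pair()$right$model))
    cache
  }
})

test_that("the posterior flat spot matches the generator facet", {
  fl <- side_fit()$flat_spot
  gt <- small_pair()$right$ground_truth$flat_plane
  ang <- acos(min(abs(sum(fl$normal * gt$normal)), 1)) * 180 / pi
  expect_lt(ang, 2)
  expect_error(find_posterior_flat_spot(small_pair()$right$model),
               class = "coronoid_precondition_error")
})

test_that("base plane modes: TLS through points and flat-anchored pipeline plane", {
  gt <- small_pair()$right$ground_truth
  # TLS branch on the generator's synthetic notch-plane anchor points
  pl <- fit_base_plane(side_fit()$local, gt$notch_plane_points)
  ang <- acos(min(abs(sum(pl$normal * gt$notch_plane$normal)), 1)) * 180 / pi
  expect_lt(ang, 2)
  # pipeline (anchored) branch: parallel to the flat spot by construction
  base <- side_fit()$base_plane
  expect_equal(abs(sum(base$normal * side_fit()$flat_spot$normal)), 1,
               tolerance = 1e-9)
  expect_error(fit_base_plane(side_fit()$local, rbind(c(0, 0, 0), c(1, 1, 1),
                                                      c(2, 2, 2))),
               class = "coronoid_degenerate_error")
})

test_that("fragment trimming follows the height fraction", {
  sf <- side_fit()
  frag <- sf$fragment
  expect_equal(measure_height(frag), 0.4 * frag$total_height, tolerance = 1e-9)
  # fraction outside (0,1) is rejected; a tiny fraction leaves too few points
  expect_error(trim_fragment(sf$local, sf$flat_spot, sf$base_plane, frag$tip,
                             fraction = 0),
               class = "coronoid_precondition_error")
  expect_error(trim_fragment(sf$local, sf$flat_spot, sf$base_plane, frag$tip,
                             fraction = 1e-4),
               class = "coronoid_fragment_error")
  # larger fraction keeps strictly more points
  f25 <- trim_fragment(sf$local, sf$flat_spot, sf$base_plane, frag$tip, 0.25)
  f60 <- trim_fragment(sf$local, sf$flat_spot, sf$base_plane, frag$tip, 0.60)
  expect_gt(nrow(f60$points), nrow(f25$points))
  expect_true(all(plane_distance(f60$points, f60$cutting_plane) > 0))
})

test_that("cross-section extents match a constructed box fragment", {
  withr::with_seed(8, {
    box <- cbind(runif(4000, -11.5, 11.5), runif(4000, 0, 10),
                 runif(4000, -12, 12))
  })
  frag <- structure(list(points = box,
                         cutting_plane = plane3d(c(0, 9.5, 0), c(0, 1, 0)),
                         tip = c(0, 22, 0), side = "right",
                         subject_id = "box", articular = NULL),
                    class = "target_fragment")
  expect_equal(measure_length(frag), 24, tolerance = 0.2)
  expect_equal(measure_width(frag), 23, tolerance = 0.2)
  expect_equal(measure_height(frag), 12.5, tolerance = 1e-9)
  empty <- structure(frag, class = "target_fragment")
  empty$cutting_plane <- plane3d(c(0, 50, 0), c(0, 1, 0))
  expect_error(measure_length(empty), class = "coronoid_degenerate_error")
})

test_that("facet radius fit recovers circles in arbitrary planes", {
  pl <- plane3d(c(1, 2, 3), c(0.2, -0.4, 0.89))
  e1 <- coronoid:::unit3(c(1, 0, 0) - sum(c(1, 0, 0) * pl$normal) * pl$normal)
  e2 <- coronoid:::cross3(pl$normal, e1)
  th <- c(0.1, 0.9, 2.2)
  pts <- t(sapply(th, function(t) pl$point + 6.44 * (cos(t) * e1 + sin(t) * e2)))
  expect_equal(fit_facet_radius(pts, pl), 6.44, tolerance = 1e-9)
  expect_error(fit_facet_radius(pts[c(1, 1, 1), ], pl),
               class = "coronoid_degenerate_error")
})

test_that("the five measurements recover generator truth on a clean bone", {
  meas <- measure_fragment(side_fit()$fragment)
  gt <- small_pair()$right$ground_truth$measurements
  expect_equal(meas$height_mm, gt$height_mm, tolerance = 0.03 * gt$height_mm)
  expect_equal(meas$length_mm, gt$length_mm, tolerance = 0.03 * gt$length_mm)
  expect_equal(meas$width_mm, gt$width_mm, tolerance = 0.03 * gt$width_mm)
  expect_equal(meas$r_medial_mm, gt$r_medial_mm, tolerance = 0.03 * gt$r_medial_mm)
  expect_equal(meas$r_lateral_mm, gt$r_lateral_mm,
               tolerance = 0.03 * gt$r_lateral_mm)
  # deterministic on repeat
  expect_identical(meas, measure_fragment(side_fit()$fragment))
})

test_that("scaling the fragment scales the measurements", {
  frag <- side_fit()$fragment
  s <- 1.7
  scaled <- frag
  scaled$points <- frag$points * s
  scaled$tip <- frag$tip * s
  scaled$cutting_plane <- plane3d(frag$cutting_plane$point * s,
                                  frag$cutting_plane$normal)
  scaled$base_plane <- plane3d(frag$base_plane$point * s, frag$base_plane$normal)
  m0 <- measure_fragment(frag)
  m1 <- measure_fragment(scaled)
  rel <- as.numeric(m1[1, 3:7]) / (s * as.numeric(m0[1, 3:7]))
  expect_lt(max(abs(rel - 1)), 0.01)
})

test_that("a fragment without articular indices fails with a clear error", {
  frag <- side_fit()$fragment
  frag$articular <- NULL
  expect_error(measure_fragment(frag), class = "coronoid_precondition_error")
})
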