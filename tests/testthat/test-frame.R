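test_that("shaft axis of a cylinder is exact and rotates with the cylinder", {
  cyl <- cylinder_grid()
  ax <- fit_shaft_axis(cyl)
  expect_lt(max(abs(abs(ax$direction[3]) - 1)), 1e-6)
  expect_lt(coronoid:::line_distance(rbind(c(0, 0, 30)), ax), 1e-6)
  g <- random_rigid_motion(9)
  rot <- surface_model(coronoid:::apply_rigid(cyl$points, g$rotation, g$translation))
  axr <- fit_shaft_axis(rot)
  target <- drop(g$rotation %*% ax$direction)
  expect_lt(1 - abs(sum(axr$direction * target)), 1e-9)
})

test_that("shaft axis tolerates surface noise to half a degree", {
  angs <- sapply(1:5, function(s) {
    cyl <- cylinder_cloud(radius = 5, length = 60, n = 6000, sigma = 0.1, seed = s)
    ax <- fit_shaft_axis(cyl)
    acos(min(abs(ax$direction[3]), 1)) * 180 / pi
  })
  expect_lt(max(angs), 0.5)
})

test_that("Gaussian curvature has the right sign and magnitude per shape", {
  K_sph <- estimate_gaussian_curvature(sphere_cloud(10, 4000))$gaussian_curvature
  expect_lt(abs(median(K_sph) - 0.01), 0.001)
  expect_gt(mean(abs(K_sph - 0.01) < 0.001), 0.9)
  flat <- withr::with_seed(2, surface_model(cbind(runif(1500, 0, 20),
                                                  runif(1500, 0, 20), 0)))
  expect_lt(max(abs(estimate_gaussian_curvature(flat)$gaussian_curvature)), 1e-4)
  cyl <- cylinder_cloud(radius = 5, length = 25, n = 12000, seed = 3)
  idx <- withr::with_seed(4, sample(which(cyl$points[, 3] > 3 &
                                            cyl$points[, 3] < 22), 300))
  K_cyl <- estimate_gaussian_curvature(cyl, indices = idx)$gaussian_curvature
  expect_lt(max(abs(K_cyl)), 1e-3)
  expect_error(estimate_gaussian_curvature(sphere_cloud(10, 4000), k_neighbors = 4),
               "k_neighbors")
})

test_that("ridge points land on the sigmoid-notch crease", {
  pr <- small_pair()
  m <- pr$right$model
  ax <- fit_shaft_axis(m)
  rg <- find_ridge_points(m, ax)
  expect_gte(nrow(rg), 4L)
  crest <- pr$right$ground_truth$crest
  dists <- apply(rg, 1, function(pt) min(sqrt(colSums((t(crest) - pt)^2))))
  expect_lt(max(dists), 1.2)
  # a featureless cylinder yields no distinguished maximum
  expect_warning(find_ridge_points(cylinder_cloud(n = 6000, seed = 5),
                                   fit_shaft_axis(cylinder_cloud(n = 6000, seed = 5))),
                 "ridge")
})

test_that("the coronoid tip is recovered at the generator landmark", {
  pr <- small_pair()
  m <- pr$right$model
  ax <- fit_shaft_axis(m)
  rg <- find_ridge_points(m, ax)
  tip <- find_coronoid_tip(m, fit_ridge_plane(rg, ax), ax)
  expect_lt(sqrt(sum((tip - pr$right$ground_truth$tip)^2)), 1)
  # a plane translated far past the coronoid misses it
  far <- plane3d(c(60, 0, 0), c(1, 0, 0))
  expect_error(find_coronoid_tip(m, far, ax), class = "coronoid_tip_error")
})

test_that("local frame construction is orthonormal, right-handed and exact", {
  ax <- line3d(c(0, 0, 0), c(0, 0, 1))
  fr <- build_local_frame(ax, c(0, 5, 3))
  expect_equal(fr$origin, c(0, 0, 3))
  expect_equal(fr$y_axis, c(0, 1, 0))
  expect_equal(fr$z_axis, c(0, 0, 1))
  M <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_equal(M %*% t(M), diag(3), tolerance = 1e-12)
  expect_equal(det(M), 1, tolerance = 1e-12)
  # tip maps to (0, |P-O|, 0)
  m <- cylinder_grid()
  loc <- to_local(m, fr)
  tipl <- attr(loc, "tip_local")
  expect_equal(tipl, c(0, 5, 0), tolerance = 1e-12)
  # pairwise distances preserved, round trip exact
  i <- c(1, 50, 500)
  d0 <- dist(m$points[i, ])
  expect_equal(as.numeric(dist(loc$points[i, ])), as.numeric(d0),
               tolerance = 1e-9)
  expect_lt(max(abs(from_local(loc)$points - m$points)), 1e-9)
  expect_error(build_local_frame(ax, c(0, 1e-9, 3)),
               class = "coronoid_degenerate_error")
})

test_that("frames built for randomly generated tips are always orthonormal", {
  for (s in 1:25) {
    pars <- withr::with_seed(s, list(dir = rnorm(3), pt = runif(3, -10, 10),
                                     tip = runif(3, -20, 20)))
    ax <- line3d(pars$pt, pars$dir)
    fr <- tryCatch(build_local_frame(ax, pars$tip), error = function(e) NULL)
    if (is.null(fr)) next
    M <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_equal(M %*% t(M), diag(3), tolerance = 1e-8)
    expect_gt(det(M), 0)
    off <- fr$tip - fr$origin
    expect_lt(abs(sum(off * fr$z_axis)), 1e-6)
  }
})
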