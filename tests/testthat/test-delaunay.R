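grid_pts <- function(zfun = function(x, y) 0, n = 11) {
  g <- expand.grid(x = seq(0, 1, length.out = n), y = seq(0, 1, length.out = n))
  cbind(g$x, g$y, zfun(g$x, g$y))
}

test_that("Delaunay area reproduces analytic areas of planar patches", {
  expect_equal(delaunay_area(grid_pts()), 1.0, tolerance = 1e-9)
  # plane tilted 60 degrees about x: area 1/cos(60) = 2
  tilted <- grid_pts(function(x, y) y * tan(pi / 3))
  expect_equal(delaunay_area(tilted), 2.0, tolerance = 1e-6)
  # pure 2D projected area ignores the tilt
  expect_equal(delaunay_area(tilted, use_3d = FALSE), 1.0, tolerance = 1e-9)
})

test_that("Delaunay area converges to the analytic hemisphere area", {
  hemi <- withr::with_seed(2, {
    n <- 10000
    z <- runif(n)
    th <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    10 * cbind(r * cos(th), r * sin(th), z)
  })
  expect_equal(delaunay_area(hemi), 2 * pi * 100, tolerance = 0.03 * 2 * pi * 100)
})

test_that("triangulation handles duplicates and rejects degenerate input", {
  pts <- rbind(grid_pts(n = 5), c(0.5, 0.5, 3)) # duplicate XY, higher z
  tr <- delaunay_triangulate(pts)
  expect_lt(nrow(tr$points), nrow(pts))
  expect_true(any(tr$points[, 3] == 3)) # nearest-to-viewer kept
  expect_error(delaunay_area(cbind(1:10, 2 * (1:10), 0)),
               class = "coronoid_degenerate_error")
  expect_error(delaunay_area(rbind(c(0, 0, 0), c(1, 1, 1))),
               class = "coronoid_degenerate_error")
})

test_that("area is invariant to in-plane rotation of the projected points", {
  pts <- withr::with_seed(4, cbind(runif(400), runif(400), runif(400, 0, 0.2)))
  a0 <- delaunay_area(pts)
  th <- 0.7
  rot <- pts
  rot[, 1] <- cos(th) * pts[, 1] - sin(th) * pts[, 2]
  rot[, 2] <- sin(th) * pts[, 1] + cos(th) * pts[, 2]
  expect_equal(delaunay_area(rot), a0, tolerance = 1e-6)
})
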