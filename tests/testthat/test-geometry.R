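test_that("total-least-squares plane fit matches analytic planes", {
  flat <- rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2), c(1, 1, 2), c(.3, .7, 2))
  pl <- fit_plane(flat)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$point[3], 2)
  # square tilted 45 degrees about x: normal (0, -sin45, cos45) up to sign
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, 1))
  pl45 <- fit_plane(sq)
  expect_equal(abs(sum(pl45$normal * c(0, -sin(pi / 4), cos(pi / 4)))), 1,
               tolerance = 1e-9)
  expect_error(fit_plane(cbind(1:5, 1:5, 1:5)), class = "coronoid_degenerate_error")
})

test_that("noisy coplanar points recover the plane normal within a degree", {
  withr::with_seed(3, {
    xy <- cbind(runif(200, -10, 10), runif(200, -10, 10))
    n_true <- coronoid:::unit3(c(0.3, -0.5, 0.81))
    e1 <- coronoid:::unit3(c(1, 0, 0) - 0.3 * n_true)
    e2 <- coronoid:::cross3(n_true, e1)
    pts <- outer(xy[, 1], e1) + outer(xy[, 2], e2) +
      outer(rnorm(200, 0, 0.05), n_true)
  })
  pl <- fit_plane(pts)
  ang <- acos(min(abs(sum(pl$normal * n_true)), 1)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("Taubin circle fit is exact through three points and robust to noise", {
  th <- c(0.3, 1.2, 2.4)
  xy <- cbind(2 + 6.44 * cos(th), -1 + 6.44 * sin(th))
  expect_equal(fit_circle_taubin(xy)$radius, 6.44, tolerance = 1e-9)
  # 50 noisy arc samples of the lateral-facet radius
  radii <- withr::with_seed(5, replicate(20, {
    th <- runif(50, 0, 1.9)
    pts <- cbind(11.84 * cos(th), 11.84 * sin(th)) +
      matrix(rnorm(100, 0, 0.1), 50, 2)
    fit_circle_taubin(pts)$radius
  }))
  expect_lt(max(abs(radii / 11.84 - 1)), 0.02)
  expect_error(fit_circle_taubin(cbind(1:6, 2 * (1:6) + 1)),
               class = "coronoid_degenerate_error")
})

test_that("weighted circle fit ignores zero-weight outliers", {
  withr::with_seed(2, {
    th <- runif(150, 0, 2 * pi)
    ring <- cbind(7 * cos(th), 7 * sin(th))
    junk <- cbind(rnorm(40, 0, 1.5), rnorm(40, 0, 1.5))
  })
  fit <- fit_circle_taubin(rbind(ring, junk),
                           weights = c(rep(1, 150), rep(1e-9, 40)))
  expect_equal(fit$radius, 7, tolerance = 1e-6)
})

test_that("plane and line distances follow signed conventions", {
  pl <- plane3d(c(0, 0, 5), c(0, 0, 2))
  expect_equal(plane_distance(rbind(c(1, 1, 7), c(0, 0, 3)), pl), c(2, -2))
  ln <- line3d(c(0, 0, 0), c(0, 0, 1))
  expect_equal(line_distance(rbind(c(3, 4, 10)), ln), 5)
})
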