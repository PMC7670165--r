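# Analytic fixture surfaces used as oracles for the geometric operations.

# regular-grid cylinder: slab centroids lie exactly on the axis
cylinder_grid <- function(radius = 5, length = 60, n_theta = 72, n_z = 120) {
  g <- expand.grid(th = seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)],
                   z = seq(0, length, length.out = n_z))
  surface_model(cbind(radius * cos(g$th), radius * sin(g$th), g$z))
}

cylinder_cloud <- function(radius = 5, length = 60, n = 5000, sigma = 0, seed = 1) {
  withr::with_seed(seed, {
    th <- stats::runif(n, 0, 2 * pi)
    z <- stats::runif(n, 0, length)
    pts <- cbind(radius * cos(th), radius * sin(th), z)
    if (sigma > 0) pts <- pts + sigma * cbind(cos(th), sin(th), 0) *
        stats::rnorm(n)
    surface_model(pts)
  })
}

sphere_cloud <- function(radius = 10, n = 4000, seed = 1) {
  withr::with_seed(seed, {
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    surface_model(radius * cbind(r * cos(th), r * sin(th), z))
  })
}

random_rigid_motion <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4)
    list(rotation = coronoid:::rotation_from_quaternion(q),
         translation = stats::runif(3, -50, 50))
  })
}

# small synthetic pair shared by several tests (noiseless, symmetric)
small_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- synthetic_ulna_params(noise_sigma = 0, n_points = 5000, seed = 11)
      cache <<- generate_ulna_pair(p)
    }
    cache
  }
})
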