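# Parametric synthetic proximal-ulna pairs with measurement ground truth.
#
# The generator emulates the features every downstream stage relies on:
# a cylindrical shaft (axis = Z), an olecranon with a planar posterior
# facet (the flat spot), a concave greater-sigmoid-notch trough carrying a
# sharp guiding ridge in the sagittal midline, and an anterior coronoid
# process whose articular face has a concave medial band and convex
# lateral band of known radii. The right side is built from the
# parameters; the left is its exact mirror image, optionally perturbed by
# a per-axis scale factor, a low-frequency warp and surface noise.

#' Parameters of the synthetic ulna generator
#'
#' Defaults are scale-realistic for an adult proximal ulna: the coronoid
#' dimensions sit at the population means reported for the upper-40%
#' target fragment (height 12.4 mm at the 40% rule, i.e. total height
#' 31 mm; length 23.8 mm; width 23.1 mm; medial facet radius 6.44 mm;
#' lateral 11.84 mm), with a 7 mm shaft radius and a 13 mm sigmoid-notch
#' radius.
#'
#' @param shaft_radius,shaft_length Shaft cylinder dimensions (mm).
#' @param coronoid_height Total coronoid height H (mm); the upper-40%
#'   fragment height is 0.4 * H.
#' @param coronoid_length,coronoid_width Proximal-distal and
#'   medial-lateral extents of the fragment cross-section at the 40% cut
#'   (mm).
#' @param r_medial,r_lateral Facet arc radii (mm).
#' @param notch_radius Greater-sigmoid-notch trough radius (mm).
#' @param flat_spot_size Axial extent of the posterior flat facet (mm).
#' @param noise_sigma Gaussian surface noise along normals (mm); emulates
#'   CT segmentation jitter.
#' @param asymmetry_scale Scale factor applied to the left side (0.5-2).
#' @param asymmetry_warp Low-frequency warp displacement amplitude applied
#'   to the left side (mm).
#' @param n_points Points per side (>= 1000).
#' @param seed RNG seed; identical seeds give identical surfaces.
#' @return Validated parameter list of class `synthetic_ulna_params`.
#' @export
synthetic_ulna_params <- function(shaft_radius = 7, shaft_length = 34,
                                  coronoid_height = 31,
                                  coronoid_length = 23.8,
                                  coronoid_width = 23.1,
                                  r_medial = 6.44, r_lateral = 11.84,
                                  notch_radius = 13, flat_spot_size = 10,
                                  noise_sigma = 0.15,
                                  asymmetry_scale = 1, asymmetry_warp = 0,
                                  n_points = 8000L, seed = 1L) {
  p <- list(shaft_radius = shaft_radius, shaft_length = shaft_length,
            coronoid_height = coronoid_height, coronoid_length = coronoid_length,
            coronoid_width = coronoid_width, r_medial = r_medial,
            r_lateral = r_lateral, notch_radius = notch_radius,
            flat_spot_size = flat_spot_size, noise_sigma = noise_sigma,
            asymmetry_scale = asymmetry_scale, asymmetry_warp = asymmetry_warp,
            n_points = as.integer(n_points), seed = as.integer(seed))
  lengths_pos <- c("shaft_radius", "shaft_length", "coronoid_height",
                   "coronoid_length", "coronoid_width", "r_medial", "r_lateral",
                   "notch_radius", "flat_spot_size")
  for (nm in lengths_pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      rlang::abort(sprintf("parameter '%s' must be a positive number", nm),
                   class = "coronoid_validation_error")
    }
  }
  if (p$noise_sigma < 0 || p$asymmetry_warp < 0) {
    rlang::abort("noise_sigma and asymmetry_warp must be non-negative",
                 class = "coronoid_validation_error")
  }
  if (p$asymmetry_scale < 0.5 || p$asymmetry_scale > 2) {
    rlang::abort("asymmetry_scale must lie in [0.5, 2]",
                 class = "coronoid_validation_error")
  }
  if (p$n_points < 1000L) {
    rlang::abort("n_points must be at least 1000", class = "coronoid_validation_error")
  }
  structure(p, class = "synthetic_ulna_params")
}

# cubic Hermite interpolation on [y0, y1]
hermite <- function(y, y0, y1, z0, z1, m0, m1) {
  h <- y1 - y0
  s <- (y - y0) / h
  z0 * (2 * s^3 - 3 * s^2 + 1) + h * m0 * (s^3 - 2 * s^2 + s) +
    z1 * (-2 * s^3 + 3 * s^2) + h * m1 * (s^3 - s^2)
}

# geometric constants shared by the patches, derived from the parameters
ulna_geometry <- function(p) {
  g <- list()
  g$y_c <- 8; g$z_c <- 14                      # notch trough centre
  g$R <- p$notch_radius
  g$h_r <- 1.6; g$s_r <- 1.6                   # guiding-ridge bump
  g$r0 <- g$R - g$h_r                          # crest radius
  g$y_floor <- g$y_c - g$r0                    # deepest crest point (base plane)
  g$H <- p$coronoid_height
  g$y_tip <- g$y_floor + g$H
  g$z_tip <- 12
  g$tau <- 0.45                                # facet tilt dz/dy
  g$frac <- 0.40
  g$y_cut <- g$y_tip - g$frac * g$H
  g$y_knee <- g$y_cut - 3
  g$phi_lo <- -25 * pi / 180; g$phi_hi <- 70 * pi / 180
  g$x_med <- min(5, 0.78 * p$r_medial)
  g$x_lat <- min(8, 0.67 * p$r_lateral)
  g$W_half <- p$coronoid_width / 2
  g$L_len <- p$coronoid_length
  g$z_head0 <- 2
  g$z_sh0 <- g$z_head0 - p$shaft_length
  g$y_flat <- -12
  g$z_flat0 <- 19
  # channel end at the distal rim, sagittal midline
  g$y_f0 <- g$y_c - g$r0 * cos(g$phi_lo)
  g$z_f0 <- g$z_c + g$r0 * sin(g$phi_lo)
  g$m_f0 <- cos(g$phi_lo) / sin(g$phi_lo)      # dz/dy at the channel end
  g$B_knee <- g$z_tip - g$tau * (g$y_tip - g$y_knee)
  g$Gmax <- p$r_medial - sqrt(p$r_medial^2 - g$x_med^2)
  g$y_recede <- g$y_cut - 1.2
  g
}

# facet transverse profile: concave medial arc (x < 0), convex lateral arc
facet_profile <- function(x, p, g) {
  ifelse(x < 0,
         p$r_medial - sqrt(pmax(p$r_medial^2 - x^2, 0)),
         sqrt(pmax(p$r_lateral^2 - x^2, 0)) - p$r_lateral)
}

facet_profile_slope <- function(x, p, g) {
  ifelse(x < 0,
         x / sqrt(pmax(p$r_medial^2 - x^2, 1e-9)),
         -x / sqrt(pmax(p$r_lateral^2 - x^2, 1e-9)))
}

# extra trough depth of the channel (relative to the crest) at its distal
# boundary; the facet blends through it so the sheets join continuously
facet_delta <- function(x, p, g) {
  eta <- g$h_r * exp(-x^2 / (2 * g$s_r^2))
  rx <- g$R - eta
  z_end <- g$z_c - sqrt(pmax(rx^2 - (g$y_c - g$y_f0)^2, 0))
  (g$z_f0 + g$tau * facet_profile(x, p, g)) - z_end
}

# sagittal midline height of the coronoid superior (articular) surface
facet_B <- function(y, g) {
  ifelse(y >= g$y_knee,
         g$z_tip - g$tau * (g$y_tip - y),
         hermite(y, g$y_f0, g$y_knee, g$z_f0, g$B_knee, g$m_f0, g$tau))
}

# coronoid half-width and proximal-distal thickness profiles
coronoid_W <- function(y, g) {
  u <- pmax(y - g$y_cut, 0) / (g$y_tip - g$y_cut)
  g$W_half * sqrt(pmax(1 - u^2, 0))
}

coronoid_L <- function(y, g) {
  u <- pmax(y - g$y_cut, 0) / (g$y_tip - g$y_cut)
  g$L_len * sqrt(pmax(1 - u^2, 0))
}

coronoid_zbot <- function(y, g, p) {
  maxz <- facet_B(pmax(y, g$y_recede), g) + g$tau * g$Gmax
  zb <- maxz - coronoid_L(pmax(y, g$y_recede), g)
  zb + pmax(g$y_recede - y, 0) * 1.2
}

# Sample the right-side surface in the construction frame. Returns points,
# (approximate) outward normals used only to direct the noise, a patch
# label and the articular ground-truth flag.
sample_right_ulna <- function(p, g) {
  n <- p$n_points
  frac <- c(shaft = 0.215, heel = 0.075, sides = 0.04,
            flat = 0.075, dome = 0.04, beak = 0.035, channel = 0.19,
            facet = 0.15, body = 0.165, tipcap = 0.015)
  cnt <- pmax(round(frac * n), 5L)
  pts <- list(); nrm <- list(); lab <- list(); art <- list()
  add <- function(name, P, N, articular = FALSE) {
    pts[[name]] <<- P; nrm[[name]] <<- N
    lab[[name]] <<- rep(name, nrow(P)); art[[name]] <<- rep(articular, nrow(P))
  }
  # shaft cylinder
  m <- cnt[["shaft"]]
  th <- stats::runif(m, 0, 2 * pi); z <- stats::runif(m, g$z_sh0, g$z_head0)
  add("shaft", cbind(p$shaft_radius * cos(th), p$shaft_radius * sin(th), z),
      cbind(cos(th), sin(th), 0))
  # posterior heel: slanted dorsal wall from the shaft up to the flat
  # spot, kept well clear of the notch floor
  m <- cnt[["heel"]]
  z <- stats::runif(m, g$z_head0, g$z_flat0 - 1)
  x <- stats::runif(m, -6.5, 6.5)
  y <- -(p$shaft_radius + (z - g$z_head0) / (g$z_flat0 - 1 - g$z_head0) *
           (-g$y_flat - p$shaft_radius)) + 0.8 * (x / 6.5)^2
  add("heel", cbind(x, y, z),
      t(apply(cbind(-0.25 * x / 6.5, -1, -0.45), 1, unit3)))
  # olecranon side walls, kept clear of the channel's lateral margin
  m <- cnt[["sides"]]
  z <- stats::runif(m, 18, 29)
  u_ <- (z - g$z_c) / g$R
  y_edge <- ifelse(abs(u_) < 1, g$y_c - g$R * sqrt(pmax(1 - u_^2, 0)), g$y_c)
  y <- -11.5 + stats::runif(m) * (pmin(y_edge - 3, -2) + 11.5)
  sgn <- sample(c(-1, 1), m, replace = TRUE)
  x <- sgn * (10.2 - 0.02 * (y + 6)^2)
  add("sides", cbind(x, y, z), cbind(sgn, 0.04 * sgn * (y + 6), 0))
  # posterior flat spot (the planar facet)
  m <- cnt[["flat"]]
  x <- stats::runif(m, -5, 5)
  z <- stats::runif(m, g$z_flat0, g$z_flat0 + p$flat_spot_size)
  add("flat", cbind(x, g$y_flat, z), cbind(0, -1, 0)[rep(1, m), , drop = FALSE])
  # olecranon top: polar cap of a flattened ellipsoid
  m <- cnt[["dome"]]
  a <- 7; b <- 8; cc <- 2.2; cz <- 29.3
  u <- stats::runif(m, 0.55, 1); phi <- stats::runif(m, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  P <- cbind(a * s * cos(phi), -4 + b * s * sin(phi), cz + cc * u)
  N <- cbind(P[, 1] / a^2, (P[, 2] + 4) / b^2, (P[, 3] - cz) / cc^2)
  add("dome", P, t(apply(N, 1, unit3)))
  # olecranon beak: tangential continuation of the channel beyond its rim,
  # arching over the notch and turning posteriorly (the olecranon tip)
  m <- cnt[["beak"]]
  x <- stats::runif(m, -8, 8)
  eta <- g$h_r * exp(-x^2 / (2 * g$s_r^2))
  rx <- g$R - eta
  z_rim <- g$z_c + rx * sin(g$phi_hi)
  dz <- stats::runif(m) * 4.4
  z <- z_rim + dz
  slope0 <- tan(g$phi_hi)
  y <- (g$y_c - rx * cos(g$phi_hi)) + slope0 * dz - 0.45 * dz^2
  add("beak", cbind(x, y, z),
      t(apply(cbind(0.342 * g$h_r * x / g$s_r^2 * exp(-x^2 / (2 * g$s_r^2)),
                    1, -(slope0 - 0.9 * dz)), 1, unit3)))
  # greater-sigmoid-notch channel with the guiding ridge; its distal
  # boundary is the constant-y line where the coronoid facet begins
  m <- cnt[["channel"]]
  x <- stats::runif(m, -8.5, 8.5)
  eta <- g$h_r * exp(-x^2 / (2 * g$s_r^2))
  rx <- g$R - eta
  phi_lo_x <- -acos(pmin((g$y_c - g$y_f0) / rx, 1))
  phi <- phi_lo_x + stats::runif(m) * (g$phi_hi - phi_lo_x)
  P <- cbind(x, g$y_c - rx * cos(phi), g$z_c + rx * sin(phi))
  etap <- -g$h_r * x / g$s_r^2 * exp(-x^2 / (2 * g$s_r^2))
  add("channel", P, t(apply(cbind(-etap, cos(phi), -sin(phi)), 1, unit3)))
  # coronoid articular facet (medial concave / lateral convex bands),
  # blending into the channel's off-crest depth over the first 6 mm
  m <- cnt[["facet"]]
  y <- stats::runif(m, g$y_f0, g$y_tip - 0.15)
  wmax <- pmin(0.95 * coronoid_W(y, g), Inf)
  x <- stats::runif(m, -pmin(g$x_med, wmax), pmin(g$x_lat, wmax))
  wj <- pmax(1 - (y - g$y_f0) / 6, 0)
  z <- facet_B(y, g) + g$tau * facet_profile(x, p, g) - wj * facet_delta(x, p, g)
  Bp <- ifelse(y >= g$y_knee, g$tau,
               (facet_B(y + 1e-4, g) - facet_B(y - 1e-4, g)) / 2e-4) +
    ifelse(wj > 0, facet_delta(x, p, g) / 6, 0)
  ddx <- (facet_delta(x + 1e-4, p, g) - facet_delta(x - 1e-4, p, g)) / 2e-4
  add("facet", cbind(x, y, z),
      t(apply(cbind(-(g$tau * facet_profile_slope(x, p, g) - wj * ddx), -Bp, 1),
              1, unit3)),
      articular = TRUE)
  # coronoid body: under/side shell (half-ellipse cross sections)
  m <- cnt[["body"]]
  # 15% of the shell samples concentrate in a collar around the nominal
  # fragment cut, where the length/width cross-section is measured
  y <- ifelse(stats::runif(m) < 0.15,
              stats::runif(m, g$y_cut - 0.8, g$y_cut + 0.8),
              stats::runif(m, 8, g$y_tip - 1.5))
  W <- pmax(coronoid_W(y, g), 0.4)
  z_edge <- facet_B(y, g) - 1.5
  z_bot <- coronoid_zbot(y, g, p)
  bb <- pmax(z_edge - z_bot, 0.2)
  # half uniform, half edge-weighted so the medial/lateral extremes of the
  # cross-section (which set the measured width) are densely sampled
  t_ <- ifelse(stats::runif(m) < 0.5,
               stats::runif(m, 0.02 * pi, 0.98 * pi),
               pmin(pmax(acos(sin(pi / 2 * stats::runif(m, -1, 1))),
                         0.02 * pi), 0.98 * pi))
  x <- W * cos(t_)
  z <- z_edge - bb * sin(t_)
  N <- cbind(cos(t_) / W, 0.15, -sin(t_) / bb)
  add("body", cbind(x, y, z), t(apply(N, 1, unit3)))
  # dense cap at the coronoid tip (facet continuation)
  m <- cnt[["tipcap"]]
  y <- stats::runif(m, g$y_tip - 1, g$y_tip - 0.02)
  wmax <- pmax(0.95 * coronoid_W(y, g), 0.05)
  x <- stats::runif(m, -pmin(g$x_med, wmax), pmin(g$x_lat, wmax))
  z <- facet_B(y, g) + g$tau * facet_profile(x, p, g)
  add("tipcap", cbind(x, y, z),
      t(apply(cbind(-g$tau * facet_profile_slope(x, p, g), -g$tau, 1), 1, unit3)),
      articular = TRUE)
  # the analytic tip itself
  add("tip", matrix(c(0, g$y_tip, g$z_tip), 1, 3),
      matrix(c(0, sin(atan(g$tau)), cos(atan(g$tau))), 1, 3), articular = TRUE)
  list(points = do.call(rbind, pts), normals = do.call(rbind, nrm),
       patch = unlist(lab, use.names = FALSE), articular = unlist(art, use.names = FALSE))
}

ulna_ground_truth <- function(p, g, side, scale = 1) {
  mirror <- function(P) {
    if (side == "left") P[, 1] <- -P[, 1]
    P
  }
  phis <- seq(g$phi_lo, g$phi_hi, length.out = 60)
  crest <- cbind(0, g$y_c - g$r0 * cos(phis), g$z_c + g$r0 * sin(phis))
  ys <- seq(g$y_f0, g$y_tip, length.out = 40)
  crest <- rbind(crest, cbind(0, ys, facet_B(ys, g)))
  dzb <- seq(0, 4.4, length.out = 12)
  crest <- rbind(crest, cbind(0, (g$y_c - g$r0 * cos(g$phi_hi)) +
                                tan(g$phi_hi) * dzb - 0.45 * dzb^2,
                              g$z_c + g$r0 * sin(g$phi_hi) + dzb))
  list(
    side = side,
    tip = scale * c(0, g$y_tip, g$z_tip),
    shaft_axis = line3d(c(0, 0, 0), c(0, 0, 1)),
    notch_plane = plane3d(scale * c(0, g$y_floor, g$z_c), c(0, 1, 0)),
    flat_plane = plane3d(scale * c(0, g$y_flat, 24), c(0, -1, 0)),
    notch_center = scale * c(0, g$y_c, g$z_c),
    crest = scale * mirror(crest),
    # synthetic anchor points spanning the ground-truth notch plane,
    # for testing the TLS branch of fit_base_plane()
    notch_plane_points = scale * mirror(cbind(stats::runif(40, -6, 6),
                                              g$y_floor,
                                              stats::runif(40, g$z_c - 3, g$z_c + 3))),
    measurements = tibble::tibble(
      side = side,
      height_mm = scale * g$frac * g$H,
      total_height_mm = scale * g$H,
      length_mm = scale * p$coronoid_length,
      width_mm = scale * p$coronoid_width,
      r_medial_mm = scale * p$r_medial,
      r_lateral_mm = scale * p$r_lateral),
    scale = scale,
    warp = p$asymmetry_warp
  )
}

# smooth low-frequency warp field (left-side asymmetry)
warp_field <- function(P, amplitude) {
  if (amplitude == 0) return(P * 0)
  amplitude * cbind(sin(2 * pi * P[, 2] / 21 + 1) * cos(2 * pi * P[, 3] / 33),
                    sin(2 * pi * P[, 3] / 17) * cos(2 * pi * P[, 1] / 27 + 2),
                    sin(2 * pi * P[, 1] / 23 + 0.5) * cos(2 * pi * P[, 2] / 29))
}

#' Generate one synthetic proximal ulna
#'
#' Builds the parametric surface, samples it to `n_points`, applies
#' Gaussian surface noise along the outward normals and returns the model
#' together with its ground truth (landmarks, planes, articular labels and
#' the five measurement values). The left side is the exact mirror image of
#' the right at `asymmetry_scale = 1`, `asymmetry_warp = 0`,
#' `noise_sigma = 0`; otherwise it is mirrored, scaled about the origin,
#' warped and independently noised. Identical seeds give identical output.
#'
#' @param params A [synthetic_ulna_params()] list.
#' @param side `"right"` or `"left"`.
#' @param subject_id Subject identifier attached to the model.
#' @param pose Optional list with `rotation` (3 x 3) and `translation`
#'   (length 3) applied to the emitted model and its ground truth,
#'   emulating an arbitrary CT pose.
#' @return List with `model` ([surface_model()]) and `ground_truth`.
#' @export
generate_ulna <- function(params = synthetic_ulna_params(),
                          side = c("right", "left"),
                          subject_id = "synthetic", pose = NULL) {
  side <- match.arg(side)
  if (!inherits(params, "synthetic_ulna_params")) {
    params <- do.call(synthetic_ulna_params, params)
  }
  g <- ulna_geometry(params)
  out <- withr::with_seed(params$seed, {
    base <- sample_right_ulna(params, g)
    n <- nrow(base$points)
    noise_r <- stats::rnorm(n, 0, params$noise_sigma)
    noise_l <- stats::rnorm(n, 0, params$noise_sigma)
    gt_r <- ulna_ground_truth(params, g, "right")
    gt_l <- ulna_ground_truth(params, g, "left", scale = params$asymmetry_scale)
    if (side == "right") {
      P <- base$points + noise_r * base$normals
      gt <- gt_r
      art <- base$articular
    } else {
      P <- base$points
      P[, 1] <- -P[, 1]
      N <- base$normals
      N[, 1] <- -N[, 1]
      P <- P * params$asymmetry_scale
      P <- P + warp_field(P, params$asymmetry_warp)
      P <- P + noise_l * N
      gt <- gt_l
      art <- base$articular
    }
    list(P = P, gt = gt, art = art)
  })
  model <- surface_model(out$P, side = side, subject_id = subject_id)
  gt <- out$gt
  gt$articular <- out$art
  if (!is.null(pose)) {
    R <- pose$rotation %||% diag(3)
    tr <- pose$translation %||% c(0, 0, 0)
    model$points <- apply_rigid(model$points, R, tr)
    gt$tip <- drop(R %*% gt$tip) + tr
    gt$notch_center <- drop(R %*% gt$notch_center) + tr
    gt$crest <- apply_rigid(gt$crest, R, tr)
    gt$notch_plane_points <- apply_rigid(gt$notch_plane_points, R, tr)
    gt$shaft_axis <- line3d(drop(R %*% gt$shaft_axis$point) + tr,
                            drop(R %*% gt$shaft_axis$direction))
    gt$notch_plane <- plane3d(drop(R %*% gt$notch_plane$point) + tr,
                              drop(R %*% gt$notch_plane$normal))
    gt$flat_plane <- plane3d(drop(R %*% gt$flat_plane$point) + tr,
                             drop(R %*% gt$flat_plane$normal))
  }
  list(model = model, ground_truth = gt)
}

#' Generate a bilateral synthetic pair
#'
#' @inheritParams generate_ulna
#' @param pose_left,pose_right Optional poses per side.
#' @return List with `left`, `right` (each as in [generate_ulna()]) and
#'   `params`.
#' @export
generate_ulna_pair <- function(params = synthetic_ulna_params(),
                               subject_id = "synthetic",
                               pose_left = NULL, pose_right = NULL) {
  list(left = generate_ulna(params, "left", subject_id, pose_left),
       right = generate_ulna(params, "right", subject_id, pose_right),
       params = params)
}

#' Generate a synthetic cohort
#'
#' Draws subject-level generator parameters from normal population
#' distributions (defaults centred on the adult means the generator
#' defaults encode), assigns sex and age, and optionally builds the paired
#' surface models. Reproducible by seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param means,sds Named lists overriding the population means / SDs for
#'   `height` (fragment height, mm), `length`, `width`, `r_medial`,
#'   `r_lateral`.
#' @param asymmetry List with `scale_sd` (log-scale SD of the left/right
#'   size ratio) and `warp_mean`, `warp_sd` (mm).
#' @param seed RNG seed.
#' @param surfaces Build the surface pairs (slow) or just the parameter
#'   table.
#' @param n_points Points per side when `surfaces = TRUE`.
#' @return List with `table` (tibble of subject parameters) and `pairs`
#'   (list of [generate_ulna_pair()] results, or `NULL`).
#' @export
generate_cohort <- function(n_subjects, means = list(), sds = list(),
                            asymmetry = list(scale_sd = 0.02, warp_mean = 0.4,
                                             warp_sd = 0.2),
                            seed = 1L, surfaces = FALSE, n_points = 6000L) {
  if (n_subjects < 2L) {
    rlang::abort("a cohort needs at least 2 subjects", class = "coronoid_validation_error")
  }
  mu <- utils::modifyList(list(height = 12.40, length = 23.81, width = 23.12,
                               r_medial = 6.44, r_lateral = 11.84), means)
  sd <- utils::modifyList(list(height = 2.74, length = 2.67, width = 1.92,
                               r_medial = 1.01, r_lateral = 3.71), sds)
  if (any(unlist(sd) <= 0)) {
    rlang::abort("population SDs must be positive", class = "coronoid_validation_error")
  }
  lower <- c(height = 6, length = 15, width = 15, r_medial = 3, r_lateral = 4)
  rtrunc <- function(n, m, s, lo) {
    x <- stats::rnorm(n, m, s)
    while (any(bad <- x < lo)) x[bad] <- stats::rnorm(sum(bad), m, s)
    x
  }
  tbl <- withr::with_seed(seed, {
    out <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      sex = ifelse(stats::runif(n_subjects) < 70 / 128, "male", "female"),
      age = rtrunc(n_subjects, 31.4, 9.3, 18),
      height = rtrunc(n_subjects, mu$height, sd$height, lower[["height"]]),
      length = rtrunc(n_subjects, mu$length, sd$length, lower[["length"]]),
      width = rtrunc(n_subjects, mu$width, sd$width, lower[["width"]]),
      r_medial = rtrunc(n_subjects, mu$r_medial, sd$r_medial, lower[["r_medial"]]),
      r_lateral = rtrunc(n_subjects, mu$r_lateral, sd$r_lateral, lower[["r_lateral"]]),
      asymmetry_scale = pmin(pmax(exp(stats::rnorm(n_subjects, 0, asymmetry$scale_sd)),
                                  0.5), 2),
      asymmetry_warp = abs(stats::rnorm(n_subjects, asymmetry$warp_mean,
                                        asymmetry$warp_sd)),
      pair_seed = sample.int(2^30, n_subjects)
    )
    out
  })
  pairs <- NULL
  if (surfaces) {
    pairs <- purrr::pmap(tbl, function(subject_id, height, length, width,
                                       r_medial, r_lateral, asymmetry_scale,
                                       asymmetry_warp, pair_seed, ...) {
      pr <- synthetic_ulna_params(coronoid_height = height / 0.4,
                                  coronoid_length = length,
                                  coronoid_width = width,
                                  r_medial = r_medial, r_lateral = r_lateral,
                                  asymmetry_scale = asymmetry_scale,
                                  asymmetry_warp = asymmetry_warp,
                                  n_points = n_points, seed = pair_seed)
      generate_ulna_pair(pr, subject_id = subject_id)
    })
  }
  list(table = tbl, pairs = pairs)
}

#' Simulate a measured cohort table
#'
#' Measurement-level simulator for the statistical stage: subject-level
#' true values are drawn from the population distributions and each side's
#' observed value adds independent measurement error, so the bilateral
#' null holds exactly unless a systematic per-side shift is injected.
#' Covering percentage is drawn per subject. This bypasses the geometry
#' pipeline and is meant for calibration studies of the cohort statistics
#' (type-I error, power) at large replicate counts.
#'
#' @param n_subjects Subjects per cohort.
#' @param seed RNG seed.
#' @param right_shift Named numeric vector of systematic additive shifts
#'   applied to the right side (e.g. `c(height_mm = 2)`).
#' @param measurement_sd Per-side measurement error SD (mm).
#' @return Tibble in [build_report()] layout: one row per subject-side.
#' @export
simulate_measurement_cohort <- function(n_subjects = 60L, seed = 1L,
                                        right_shift = numeric(0),
                                        measurement_sd = 0.35) {
  withr::with_seed(seed, {
    base <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      sex = ifelse(stats::runif(n_subjects) < 70 / 128, "male", "female"),
      age = pmax(stats::rnorm(n_subjects, 31.4, 9.3), 18),
      height_mm = stats::rnorm(n_subjects, 12.40, 2.74),
      length_mm = stats::rnorm(n_subjects, 23.81, 2.67),
      width_mm = stats::rnorm(n_subjects, 23.12, 1.92),
      r_medial_mm = stats::rnorm(n_subjects, 6.44, 1.01),
      r_lateral_mm = stats::rnorm(n_subjects, 11.84, 3.71),
      covering_pct = pmin(stats::rnorm(n_subjects, 87.8, 12.1), 100)
    )
    params <- c("height_mm", "length_mm", "width_mm", "r_medial_mm", "r_lateral_mm")
    long <- tidyr::crossing(base, side = c("left", "right"))
    for (pm in params) {
      shift <- if (pm %in% names(right_shift)) right_shift[[pm]] else 0
      long[[pm]] <- long[[pm]] + stats::rnorm(nrow(long), 0, measurement_sd) +
        ifelse(long$side == "right", shift, 0)
    }
    dplyr::arrange(long, .data$subject_id, .data$side)
  })
}
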