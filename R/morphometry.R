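# Target-fragment extraction and the five anatomical parameters: a cutting
# plane parallel to the posterior flat spot of the olecranon trims the upper
# 40% of the coronoid process (the simulated Regan-Morrey type-II fragment),
# which is then measured for height, length, width and the medial/lateral
# facet radii.

#' Find the posterior flat spot of the olecranon
#'
#' Operates on a model already expressed in its local frame. The olecranon
#' region is taken as the proximal half of the positive-Z extent; within it
#' the 10% most posterior points (most negative Y) are screened for the
#' flattest quarter (local quadric curvature magnitude below the 25th
#' percentile) and a total-least-squares plane is fitted to that patch.
#' When the olecranon carries no planar facet the flattest-patch plane is
#' still returned, with a warning.
#'
#' @param model Local-frame [surface_model()].
#' @param k_neighbors Neighbourhood size for the flatness screen.
#' @return A [plane3d()]; attribute `patch` holds the fitted point indices.
#' @export
find_posterior_flat_spot <- function(model, k_neighbors = 20L) {
  stopifnot(inherits(model, "surface_model"))
  if (!isTRUE(attr(model, "local"))) {
    rlang::abort("find_posterior_flat_spot expects a local-frame model",
                 class = "coronoid_precondition_error")
  }
  pts <- model$points
  if (nrow(pts) < 100L) {
    rlang::abort("model too sparse to locate the posterior flat spot",
                 class = "coronoid_flat_spot_error")
  }
  zmax <- max(pts[, 3])
  region <- which(pts[, 3] > 0.5 * zmax)
  if (length(region) < 100L) {
    rlang::abort("olecranon region too sparse", class = "coronoid_flat_spot_error")
  }
  ycut <- stats::quantile(pts[region, 2], 0.10)
  # soft membership in both screens, so the fitted plane is a continuous
  # function of the coordinates (hard cuts would make the whole downstream
  # measurement chain jump when a borderline point flips side)
  w_post <- pmin(pmax((ycut - pts[region, 2]) / 0.3 + 1, 0), 1)
  post <- region[w_post > 0.01]
  w_post <- w_post[w_post > 0.01]
  ck <- estimate_gaussian_curvature(model, k_neighbors, indices = post)
  kabs <- abs(ck$gaussian_curvature)
  flat_thr <- stats::quantile(kabs, 0.25)
  w_flat <- pmin(pmax((flat_thr - kabs) / pmax(0.3 * flat_thr, 1e-9) + 1, 0), 1)
  w <- w_post * w_flat
  patch <- post[w > 0.5]
  if (length(patch) < 10L) {
    rlang::abort("posterior flat patch has fewer than 10 points",
                 class = "coronoid_flat_spot_error")
  }
  sel <- w > 0.01
  pl <- fit_plane(pts[post[sel], , drop = FALSE], weights = w[sel])
  # flatness sanity: warn when even the flattest patch is strongly curved
  # (plane residual well above segmentation-noise scale)
  if (sqrt(mean(plane_distance(pts[patch, , drop = FALSE], pl)^2)) > 0.45) {
    rlang::warn("olecranon shows no planar posterior facet; using flattest patch")
  }
  # orient the normal posteriorly (negative Y) for a stable convention
  if (pl$normal[2] > 0) pl <- plane3d(pl$point, -pl$normal)
  structure(pl, patch = patch)
}

#' Base plane of the greater sigmoid notch
#'
#' Two modes. Given only ridge points, fits their total-least-squares plane
#' (the generic spec'd behaviour). Given additionally the posterior flat
#' spot, anchors the base plane parallel to the flat spot through the
#' deepest (most posterior) ridge point, locally refined against the model:
#' this is the construction the measurement pipeline uses, since the
#' tip-to-base height must be measured along the flat-spot normal.
#'
#' @param model Local-frame [surface_model()].
#' @param ridge_points Matrix of sigmoid-notch ridge points (>= 1 row; >= 3
#'   for the TLS mode).
#' @param flat_spot Optional [plane3d()] from [find_posterior_flat_spot()].
#' @return A [plane3d()].
#' @export
fit_base_plane <- function(model, ridge_points, flat_spot = NULL) {
  ridge_points <- as_points_matrix(ridge_points)
  if (is.null(flat_spot)) {
    return(fit_plane(ridge_points))
  }
  stopifnot(inherits(flat_spot, "plane3d"))
  # anterior direction = opposite the (posterior-pointing) flat normal
  anterior <- -flat_spot$normal
  depth <- drop(ridge_points %*% anterior)
  anchor <- ridge_points[which.min(depth), ]
  # refine: deepest model point along the ridge strip around the anchor,
  # within a narrow depth band so the dorsal cortex cannot capture it
  pts <- model$points
  d_all <- drop(pts %*% anterior)
  d_anchor <- sum(anchor * anterior)
  strip <- which(abs(pts[, 1] - anchor[1]) <= 0.8 &
                   abs(pts[, 3] - anchor[3]) <= 4 &
                   d_all >= d_anchor - 1.5 & d_all <= d_anchor + 0.5)
  if (length(strip) > 0L) {
    anchor <- pts[strip[which.min(d_all[strip])], ]
  }
  plane3d(anchor, anterior)
}

#' Target fragment: the upper 40% of the coronoid process
#'
#' The total coronoid height H is the distance from the tip to the base
#' plane measured along the flat-spot normal; the cutting plane is parallel
#' to the flat spot at `fraction * H` from the tip towards the base, and the
#' fragment is every point strictly on the tip side of it.
#'
#' @param model Local-frame [surface_model()].
#' @param flat_spot Posterior flat-spot [plane3d()].
#' @param base_plane Sigmoid-notch base [plane3d()].
#' @param tip Coronoid tip coordinates in the same (local) frame.
#' @param fraction Fragment fraction of total coronoid height (0, 1).
#' @return An object of class `target_fragment`: fields `points`, `indices`,
#'   `cutting_plane`, `base_plane`, `flat_spot`, `tip`, `total_height`,
#'   `side`, `subject_id`; `articular` is filled by
#'   [extract_articular_surface()].
#' @export
trim_fragment <- function(model, flat_spot, base_plane, tip, fraction = 0.40) {
  stopifnot(inherits(model, "surface_model"), inherits(flat_spot, "plane3d"),
            inherits(base_plane, "plane3d"))
  if (!(fraction > 0 && fraction < 1)) {
    rlang::abort("fraction must lie strictly between 0 and 1",
                 class = "coronoid_precondition_error")
  }
  tip <- as.numeric(tip)
  # direction from base towards tip, along the flat-spot normal
  v <- flat_spot$normal
  if (sum((tip - base_plane$point) * v) < 0) v <- -v
  denom <- sum(base_plane$normal * v)
  if (abs(denom) < 1e-6) {
    rlang::abort("base plane is parallel to the flat-spot normal; height undefined",
                 class = "coronoid_degenerate_error")
  }
  total_height <- abs(sum((tip - base_plane$point) * base_plane$normal) / denom)
  cut_point <- tip - fraction * total_height * v
  cutting_plane <- plane3d(cut_point, v)
  d <- plane_distance(model$points, cutting_plane)
  keep <- which(d > 0)
  if (length(keep) < 10L) {
    rlang::abort("fragment has fewer than 10 points", class = "coronoid_fragment_error")
  }
  structure(list(points = model$points[keep, , drop = FALSE],
                 indices = keep,
                 cutting_plane = cutting_plane,
                 base_plane = base_plane,
                 flat_spot = flat_spot,
                 tip = tip,
                 total_height = total_height,
                 articular = NULL,
                 notch_center = NULL,
                 side = model$side,
                 subject_id = model$subject_id),
            class = "target_fragment")
}

#' @export
print.target_fragment <- function(x, ...) {
  cat(sprintf("<target_fragment> %s %s: %d points, total coronoid height %.2f mm\n",
              x$subject_id, x$side, nrow(x$points), x$total_height))
  invisible(x)
}

#' Fragment height
#'
#' Perpendicular distance from the coronoid tip to the cutting plane (mm).
#'
#' @param fragment A [trim_fragment()] result.
#' @return Height in mm.
#' @export
measure_height <- function(fragment) {
  stopifnot(inherits(fragment, "target_fragment"))
  abs(sum((fragment$tip - fragment$cutting_plane$point) * fragment$cutting_plane$normal))
}

# cross-section of the fragment at its cutting plane
cut_section <- function(fragment, slab_halfwidth) {
  d <- plane_distance(fragment$points, fragment$cutting_plane)
  sel <- which(abs(d) <= slab_halfwidth)
  if (length(sel) < 2L) {
    rlang::abort("cutting-plane cross-section is empty",
                 class = "coronoid_degenerate_error")
  }
  fragment$points[sel, , drop = FALSE]
}

# extent of the cut cross-section along a direction projected into the plane
section_extent <- function(fragment, direction, slab_halfwidth) {
  sec <- cut_section(fragment, slab_halfwidth)
  n <- fragment$cutting_plane$normal
  dir <- direction - sum(direction * n) * n
  dir <- unit3(dir)
  coord <- drop(sec %*% dir)
  diff(range(coord))
}

#' Fragment length (proximal-distal)
#'
#' Extent of the fragment's cutting-plane cross-section (points within
#' `slab_halfwidth` of the plane) along the proximal-distal direction
#' (local Z projected into the plane).
#'
#' @param fragment A [trim_fragment()] result, in the local frame.
#' @param slab_halfwidth Cross-section slab half-width (mm).
#' @return Length in mm.
#' @export
measure_length <- function(fragment, slab_halfwidth = 0.5) {
  section_extent(fragment, c(0, 0, 1), slab_halfwidth)
}

#' Fragment width (medial-lateral)
#'
#' Extent of the cutting-plane cross-section along the medial-lateral
#' direction (local X projected into the plane).
#'
#' @inheritParams measure_length
#' @return Width in mm.
#' @export
measure_width <- function(fragment, slab_halfwidth = 0.5) {
  section_extent(fragment, c(1, 0, 0), slab_halfwidth)
}

#' Facet radius by planar circle fit
#'
#' Projects facet points into the given plane and fits a circle by the
#' Taubin algebraic method; returns the fitted radius. Exact for three
#' points on a circle.
#'
#' @param facet_points Matrix of facet points (>= 3, non-collinear in
#'   projection).
#' @param plane Fitting plane ([plane3d()]), typically a cross-section plane
#'   perpendicular to local Z.
#' @return Radius in mm.
#' @export
fit_facet_radius <- function(facet_points, plane) {
  facet_points <- as_points_matrix(facet_points)
  stopifnot(inherits(plane, "plane3d"))
  n <- plane$normal
  # orthonormal in-plane basis
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(seed - sum(seed * n) * n)
  e2 <- cross3(n, e1)
  rel <- sweep(facet_points, 2, plane$point)
  xy <- cbind(drop(rel %*% e1), drop(rel %*% e2))
  fit_circle_taubin(xy)$radius
}

# Radius of a facet band in the transverse (XY) plane. The articular
# facet is close to a surface swept along the proximal-distal direction,
# so in-plane position obeys y ~ c + beta * z - profile(x): profiling the
# shear beta (chosen to minimise the Taubin circle residual of the
# de-sheared band) collapses the whole band onto a single transverse arc,
# using every facet point instead of a thin slab. Falls back to the plain
# projection when the band has no z extent.
facet_band_radius <- function(fp, xsign = 1, apex_slope = 0,
                              base_weights = NULL) {
  if (nrow(fp) < 8L || diff(range(fp[, 3])) < 0.5) {
    return(fit_facet_radius(fp, plane3d(c(0, 0, mean(fp[, 3])), c(0, 0, 1))))
  }
  # moving-least-squares denoising of the band: the medial arc spans only a
  # half-radius chord, where raw segmentation noise dominates the sagitta
  if (is.null(base_weights)) base_weights <- rep(1, nrow(fp))
  if (nrow(fp) >= 30L) {
    fp <- denoise_points(fp, seq_len(nrow(fp)), min(20L, nrow(fp) - 1L))
  }
  x <- xsign * fp[, 1]
  y <- fp[, 2]
  z <- fp[, 3] - mean(fp[, 3])
  # The shear (proximal-distal drift of the transverse arc) equals the
  # inverse facet tilt, which the surface normals measure directly and
  # independently of the circle parameters; estimating it from the circle
  # residual instead is ill-posed, because for a half-width arc a shear is
  # largely absorbed by a radius change.
  k <- min(20L, nrow(fp) - 1L)
  nn <- knn_indices(fp, fp, k)
  tau <- vapply(seq_len(nrow(fp)), function(i) {
    ev <- eigen(stats::cov(fp[nn[i, ], , drop = FALSE]), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    if (nrm[3] < 0) nrm <- -nrm
    if (abs(nrm[3]) < 1e-6) return(NA_real_)
    -nrm[2] / nrm[3]
  }, numeric(1))
  tau_hat <- stats::median(tau, na.rm = TRUE)
  tau_hat <- min(max(tau_hat, 0.15), 2.5)
  w <- y - z / tau_hat - apex_slope * x
  fit <- tryCatch(fit_circle_taubin(cbind(x, w), weights = base_weights),
                  error = function(e) NULL)
  if (is.null(fit)) {
    rlang::abort("facet band collapsed; circle fit is degenerate",
                 class = "coronoid_degenerate_error")
  }
  # A few-percent error in the normal-based tilt leaves a proximal-distal
  # trend in the de-sheared band and rescales the fitted radius by the
  # same factor. On clean bands (residual scatter below 0.15 mm) the trend
  # is measurable from the circle-fit residuals and removed; on noisy
  # bands this direction is ill-identified and the correction is skipped.
  yc <- y - mean(y)
  for (it in 1:3) {
    rd <- sqrt((x - fit$center[1])^2 + (w - fit$center[2])^2)
    rr0 <- rd - fit$radius
    # blend the correction out smoothly as the band gets noisy: on noisy
    # bands the trend is ill-identified, and a hard on/off gate would make
    # the estimate discontinuous in the input coordinates
    gate <- min(max((0.17 - stats::mad(rr0)) / 0.06, 0), 1)
    if (gate <= 0) break
    # a w-trend of m*yc appears in the radial residual as m*yc*u_w, with
    # u_w the w-component of the radial unit vector
    u_w <- (w - fit$center[2]) / pmax(rd, 1e-9)
    m <- stats::lm.fit(cbind(1, yc * u_w), rr0)$coefficients[2]
    m <- gate * max(min(m, 0.06), -0.06)
    if (!is.finite(m) || abs(m) < 1e-5) break
    # the trend slope measures the relative tilt error 1 - tau/tau_hat;
    # rescale the tilt so both the trend and the profile scaling vanish
    tau_hat <- tau_hat * (1 - m)
    w <- y - z / tau_hat - apex_slope * x
    fit2 <- tryCatch(fit_circle_taubin(cbind(x, w), weights = base_weights),
                     error = function(e) NULL)
    if (is.null(fit2)) break
    fit <- fit2
  }
  # one mild outlier trim guards against stray non-facet points that leak
  # through the articular extraction cone
  rr <- sqrt((x - fit$center[1])^2 + (w - fit$center[2])^2) - fit$radius
  # smooth down-weighting of stray non-facet points that leak through the
  # articular extraction cone
  wscale <- max(0.6, 4 * stats::mad(rr))
  wts <- base_weights * exp(-(rr / wscale)^4)
  fit2 <- tryCatch(fit_circle_taubin(cbind(x, w), weights = wts),
                   error = function(e) NULL)
  if (!is.null(fit2)) {
    fit <- fit2
    rr <- sqrt((x - fit$center[1])^2 + (w - fit$center[2])^2) - fit$radius
  }
  keep <- abs(rr) <= wscale
  # Leading-order noise-bias correction for a short arc: with r ~ c^2/(8 s)
  # the sagitta estimate enters reciprocally, so sagitta variance inflates
  # the fitted radius by ~ 0.5 * r''(s) * var(s), var(s) ~ 11 sigma^2 / n
  # for a quadratic fit over a uniform chord.
  radius <- fit$radius
  sig <- 1.4826 * stats::mad(rr[keep])
  chord <- diff(range(x[keep]))
  sag <- radius - sqrt(max(radius^2 - (chord / 2)^2, 0))
  if (is.finite(sig) && sag > 0.05) {
    var_s <- 11 * sig^2 / sum(keep)
    bias <- 0.5 * (2 * chord^2 / (8 * sag^3)) * var_s
    radius <- radius - min(bias, 0.35 * radius)
  }
  radius
}

# Residual lateral rotation (yaw) of the local frame, measured where it is
# identifiable: the medial and lateral facet arcs join at the apex with
# zero transverse slope, so any common slope of the de-sheared band around
# x = 0 is frame yaw, which would otherwise shear both one-sided arcs and
# bias their radii.
facet_apex_slope <- function(art, xnorm) {
  sel <- which(abs(xnorm) <= 3)
  if (length(sel) < 30L) return(0)
  fp <- art[sel, , drop = FALSE]
  x <- xnorm[sel]
  z <- fp[, 3] - mean(fp[, 3])
  k <- min(15L, nrow(fp) - 1L)
  nn <- knn_indices(fp, fp, k)
  tau <- vapply(seq_len(nrow(fp)), function(i) {
    ev <- eigen(stats::cov(fp[nn[i, ], , drop = FALSE]), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    if (nrm[3] < 0) nrm <- -nrm
    if (abs(nrm[3]) < 1e-6) return(NA_real_)
    -nrm[2] / nrm[3]
  }, numeric(1))
  tau_hat <- min(max(stats::median(tau, na.rm = TRUE), 0.15), 2.5)
  w <- fp[, 2] - z / tau_hat
  # slope at the apex from each side separately (quadratic in x), averaged:
  # the true profile has zero slope at x = 0 on both arcs
  side_slope <- function(keep) {
    if (sum(keep) < 12L) return(NA_real_)
    ft <- tryCatch(stats::lm.fit(cbind(1, x[keep], x[keep]^2), w[keep]),
                   error = function(e) NULL)
    if (is.null(ft) || !is.finite(ft$coefficients[2])) return(NA_real_)
    # blend out smoothly on noisy bands, where the slope is too weakly
    # identified to help
    gate <- min(max((0.25 - sqrt(mean(ft$residuals^2))) / 0.08, 0), 1)
    gate * ft$coefficients[2]
  }
  sl <- mean(c(side_slope(x < 0), side_slope(x >= 0)), na.rm = TRUE)
  if (!is.finite(sl)) return(0)
  max(min(sl, 0.12), -0.12)
}

#' Measure the five fragment parameters
#'
#' Composes height, length, width and the two facet radii. Facet points are
#' the fragment's articular points split at the medio-lateral midline after
#' side normalisation (left-side X is flipped so "medial" is negative X for
#' both sides); each facet's radius is fitted on its mid-facet cross-section
#' perpendicular to local Z.
#'
#' @param fragment A [trim_fragment()] result carrying articular indices
#'   (see [extract_articular_surface()]).
#' @param slab_halfwidth Cross-section slab half-width (mm).
#' @return One-row tibble: `subject_id`, `side`, `height_mm`, `length_mm`,
#'   `width_mm`, `r_medial_mm`, `r_lateral_mm`.
#' @export
measure_fragment <- function(fragment, slab_halfwidth = 0.5) {
  stopifnot(inherits(fragment, "target_fragment"))
  if (is.null(fragment$articular)) {
    rlang::abort("fragment has no articular subset; run extract_articular_surface()",
                 class = "coronoid_precondition_error")
  }
  failures <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", name, conditionMessage(e)))
      NA_real_
    })
  }
  height <- grab("height", measure_height(fragment))
  len <- grab("length", measure_length(fragment, slab_halfwidth))
  wid <- grab("width", measure_width(fragment, slab_halfwidth))
  art <- fragment$points[fragment$articular, , drop = FALSE]
  art_w <- attr(fragment$articular, "weights")
  if (is.null(art_w)) art_w <- rep(1, nrow(art))
  xnorm <- if (identical(fragment$side, "left")) -art[, 1] else art[, 1]
  # soft medial/lateral split: points within the +-0.5 mm apex band carry
  # fractional weight in both facets, so the split is continuous in the
  # coordinates (the apex is genuinely shared by both arcs)
  facet_radius <- function(sel_name, w_side) {
    grab(sel_name, {
      sel <- which(w_side > 0.01)
      fp <- art[sel, , drop = FALSE]
      if (nrow(fp) < 3L) {
        rlang::abort("facet has fewer than 3 points", class = "coronoid_degenerate_error")
      }
      facet_band_radius(fp, if (identical(fragment$side, "left")) -1 else 1,
                        apex_slope, base_weights = art_w[sel] * w_side[sel])
    })
  }
  apex_slope <- facet_apex_slope(art, xnorm)
  r_med <- facet_radius("r_medial", pmin(pmax((0.5 - xnorm), 0), 1))
  r_lat <- facet_radius("r_lateral", pmin(pmax((0.5 + xnorm), 0), 1))
  if (length(failures) > 0) {
    rlang::abort(paste0("fragment measurement failed: ",
                        paste(failures, collapse = "; ")),
                 class = "coronoid_measurement_error")
  }
  tibble::tibble(subject_id = fragment$subject_id, side = fragment$side,
                 height_mm = height, length_mm = len, width_mm = wid,
                 r_medial_mm = r_med, r_lateral_mm = r_lat)
}
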