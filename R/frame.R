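# Construction of the anatomical local coordinate system of the proximal
# ulna: Z = shaft central long axis, P = coronoid tip on the sigmoid-notch
# ridge plane, O = projection of P onto Z, Y = O->P, X completes a
# right-handed triad.

knn_indices <- function(ref, query = ref, k) {
  res <- RANN::nn2(ref, query, k = min(k, nrow(ref)))
  res$nn.idx
}

#' Fit the shaft central long axis
#'
#' Fits the line through the centroids of `n_sections` cross-sections taken
#' at equal spacing through the distal (shaft-like) portion of the model,
#' then orients it distal -> proximal (towards the articular head, detected
#' as the end with the larger radial spread). Cross-section centroids are
#' trimmed once at 1.4x the median in-plane radius so that the anterior
#' coronoid column does not drag the centroid off the shaft centre. The fit
#' is iterated twice so section slabs are taken perpendicular to the
#' current axis estimate.
#'
#' @param model A [surface_model()].
#' @param proximal_fraction Fraction of the whole ulna the model represents;
#'   the model is assumed to *be* the proximal segment.
#' @param n_sections Number of shaft cross-sections (>= 2).
#' @param shaft_fraction Distal fraction of the model's axial extent treated
#'   as shaft-like.
#' @return A [line3d()]; direction points distal -> proximal.
#' @export
fit_shaft_axis <- function(model, proximal_fraction = 0.20, n_sections = 3L,
                           shaft_fraction = 0.5) {
  stopifnot(inherits(model, "surface_model"), n_sections >= 2L,
            proximal_fraction > 0, proximal_fraction <= 1)
  pts <- model$points
  # provisional direction: first principal direction of the whole cloud;
  # the articular head can tilt this substantially, but the trimmed
  # circle-fit section centres below are insensitive to the tilt
  ctr <- colMeans(pts)
  ax <- line3d(ctr, svd(sweep(pts, 2, ctr), nu = 0)$v[, 1])
  ax <- orient_by_end_circularity(ax, pts)
  for (iter in 1:5) {
    t <- line_coordinate(pts, ax)
    t0 <- min(t)
    seg <- (max(t) - t0) * shaft_fraction
    spacing <- seg / n_sections
    centroids <- matrix(NA_real_, n_sections, 3L)
    for (i in seq_len(n_sections)) {
      mid <- t0 + (i - 0.5) * spacing
      sel <- which(abs(t - mid) <= spacing / 2)
      if (length(sel) < 3L) {
        rlang::abort(sprintf("shaft cross-section %d has fewer than 3 points", i),
                     class = "coronoid_degenerate_error")
      }
      prior <- if (i > 1L) list(center = centroids[i - 1L, ], radius = rhat) else NULL
      sc <- section_center(pts[sel, , drop = FALSE], ax, prior)
      centroids[i, ] <- sc$center
      if (i == 1L) rhat <- sc$radius
    }
    cc <- colMeans(centroids)
    dir <- svd(sweep(centroids, 2, cc), nu = 0)$v[, 1]
    if (sum(dir * ax$direction) < 0) dir <- -dir
    ax <- line3d(cc, dir)
  }
  orient_by_end_circularity(ax, pts)
}

# Robust centre of one shaft cross-section: the section of a tubular shaft
# is (close to) a circle/ellipse, so a trimmed algebraic circle fit in the
# section plane rejects the anterior coronoid column, which appears as an
# interior cluster. A radius prior from the previous (more distal, cleaner)
# section anchors the trim when the column contaminates the section.
# Falls back to the plain centroid for tiny sections.
section_center <- function(sub, ax, prior = NULL) {
  cen <- colMeans(sub)
  if (nrow(sub) < 10L) return(list(center = cen, radius = NA_real_))
  n <- ax$direction
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(seed - sum(seed * n) * n)
  e2 <- cross3(n, e1)
  rel <- sweep(sub, 2, cen)
  uv <- cbind(drop(rel %*% e1), drop(rel %*% e2))
  # smooth IRLS weighting (instead of hard trimming): the centre is then a
  # continuous function of the coordinates, so the iterated axis fit stays
  # stable under rigid motion of the input to numerical precision
  w0 <- rep(1, nrow(uv))
  if (!is.null(prior) && is.finite(prior$radius)) {
    pc <- c(sum((prior$center - cen) * e1), sum((prior$center - cen) * e2))
    d0 <- sqrt((uv[, 1] - pc[1])^2 + (uv[, 2] - pc[2])^2)
    w0 <- exp(-((d0 - prior$radius) / 1.8)^2)
    if (sum(w0) < 10) w0 <- rep(1, nrow(uv))
  }
  w <- w0
  fit <- NULL
  for (rep_ in 1:3) {
    fit <- tryCatch(fit_circle_taubin(uv, weights = w),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(center = cen, radius = NA_real_))
    resid <- abs(sqrt((uv[, 1] - fit$center[1])^2 +
                        (uv[, 2] - fit$center[2])^2) - fit$radius)
    scale <- max(0.8, 2.5 * sum(w * resid) / sum(w))
    w <- w0 * exp(-(resid / scale)^2)
    if (sum(w) < 8) return(list(center = cen, radius = NA_real_))
  }
  list(center = cen + fit$center[1] * e1 + fit$center[2] * e2,
       radius = fit$radius)
}

# Distal -> proximal orientation: the distal end is the shaft, whose end
# section is nearly circular; the proximal end is the articular head,
# whose end section fits a circle poorly.
orient_by_end_circularity <- function(ax, pts) {
  t <- line_coordinate(pts, ax)
  span <- max(t) - min(t)
  ends <- list(lo = pts[t <= min(t) + 0.08 * span, , drop = FALSE],
               hi = pts[t >= max(t) - 0.08 * span, , drop = FALSE])
  rms <- vapply(ends, function(sub) {
    if (nrow(sub) < 10L) return(Inf)
    n <- ax$direction
    seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit3(seed - sum(seed * n) * n)
    e2 <- cross3(n, e1)
    rel <- sweep(sub, 2, colMeans(sub))
    uv <- cbind(drop(rel %*% e1), drop(rel %*% e2))
    fit <- tryCatch(fit_circle_taubin(uv), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    sqrt(mean((sqrt((uv[, 1] - fit$center[1])^2 +
                      (uv[, 2] - fit$center[2])^2) - fit$radius)^2))
  }, numeric(1))
  if (rms[["lo"]] > rms[["hi"]]) ax <- line3d(ax$point, -ax$direction)
  ax
}

# Per-query-point Gaussian curvature by local quadric (height-field) fit in
# a PCA-aligned neighbourhood frame. Returns K and a degeneracy flag.
quadric_curvature <- function(pts, query_idx, k_neighbors) {
  nn <- knn_indices(pts, pts[query_idx, , drop = FALSE], k_neighbors)
  K <- numeric(length(query_idx))
  degen <- logical(length(query_idx))
  resid <- numeric(length(query_idx))
  for (i in seq_along(query_idx)) {
    nb <- pts[nn[i, ], , drop = FALSE]
    ctr <- colMeans(nb)
    e <- eigen(stats::cov(nb), symmetric = TRUE)
    # local frame: e1,e2 tangent, e3 normal (smallest variance)
    loc <- sweep(nb, 2, ctr) %*% e$vectors
    q <- sweep(pts[query_idx[i], , drop = FALSE], 2, ctr) %*% e$vectors
    u <- loc[, 1] - q[1]; v <- loc[, 2] - q[2]; w <- loc[, 3]
    X <- cbind(u^2, u * v, v^2, u, v, 1)
    fit <- qr(X)
    if (fit$rank < 6L) {
      K[i] <- 0; degen[i] <- TRUE; resid[i] <- NA_real_
      next
    }
    cf <- qr.coef(fit, w)
    resid[i] <- sqrt(mean((w - drop(X %*% cf))^2))
    # height field w(u,v); derivatives at the query point (u = v = 0)
    fu <- cf[4]; fv <- cf[5]
    fuu <- 2 * cf[1]; fuv <- cf[2]; fvv <- 2 * cf[3]
    K[i] <- (fuu * fvv - fuv^2) / (1 + fu^2 + fv^2)^2
  }
  list(K = K, degenerate = degen, residual = resid)
}

# Moving-least-squares denoising: project each requested point onto the
# quadric fitted over its k nearest neighbours. Reduces coordinate noise by
# ~sqrt(k) so crease detection stays stable on noisy segmentations.
denoise_points <- function(pts, idx, k_neighbors) {
  nn <- knn_indices(pts, pts[idx, , drop = FALSE], k_neighbors)
  out <- pts[idx, , drop = FALSE]
  for (i in seq_along(idx)) {
    nb <- pts[nn[i, ], , drop = FALSE]
    ctr <- colMeans(nb)
    e <- eigen(stats::cov(nb), symmetric = TRUE)
    loc <- sweep(nb, 2, ctr) %*% e$vectors
    q <- drop(sweep(pts[idx[i], , drop = FALSE], 2, ctr) %*% e$vectors)
    u <- loc[, 1] - q[1]; v <- loc[, 2] - q[2]; w <- loc[, 3]
    X <- cbind(u^2, u * v, v^2, u, v, 1)
    fit <- qr(X)
    if (fit$rank < 6L) next
    cf <- qr.coef(fit, w)
    out[i, ] <- pts[idx[i], ] + (cf[6] - q[3]) * e$vectors[, 3]
  }
  out
}

#' Estimate per-point Gaussian curvature
#'
#' Gaussian curvature K (1/mm^2) from a least-squares quadric fitted over
#' each point's k nearest neighbours in a PCA-aligned local frame. Sign
#' convention: sphere positive, saddle negative, plane and cylinder ~ 0.
#' Rank-deficient neighbourhoods yield K = 0 with `degenerate = TRUE`.
#'
#' @param model A [surface_model()].
#' @param k_neighbors Neighbourhood size (>= 6).
#' @param indices Optional subset of point indices to evaluate (the ridge
#'   and flat-spot detectors only need slab-restricted fields).
#' @return Tibble with `index`, `gaussian_curvature`, `degenerate`.
#' @export
estimate_gaussian_curvature <- function(model, k_neighbors = 20L, indices = NULL) {
  stopifnot(inherits(model, "surface_model"), k_neighbors >= 6L)
  if (nrow(model$points) < k_neighbors) {
    rlang::abort("model has fewer points than k_neighbors",
                 class = "coronoid_degenerate_error")
  }
  if (is.null(indices)) indices <- seq_len(nrow(model$points))
  qc <- quadric_curvature(model$points, indices, k_neighbors)
  tibble::tibble(index = as.integer(indices),
                 gaussian_curvature = qc$K,
                 residual_mm = qc$residual,
                 degenerate = qc$degenerate)
}

#' Locate the sigmoid-notch ridge points
#'
#' Places `n_sections` equally spaced cross-section planes perpendicular to
#' the shaft axis across the olecranon/notch span (60th-95th percentile of
#' the axial extent) and returns, per section, the point of maximal
#' absolute Gaussian curvature within a half-spacing slab. On the concave
#' trough of the greater sigmoid notch the guiding ridge is a saddle, so the
#' magnitude (not the signed maximum) identifies the crease.
#'
#' @param model A [surface_model()].
#' @param axis Shaft axis from [fit_shaft_axis()].
#' @param n_sections Number of section planes.
#' @param k_neighbors Neighbourhood size for the curvature field.
#' @param max_residual Quadric-fit RMS residual (mm) above which a
#'   candidate point is rejected: large residuals mark non-manifold
#'   neighbourhoods (close-passing sheets, segmentation steps), which
#'   produce spurious curvature maxima.
#' @param radial_limit Candidates are restricted to points within
#'   `radial_limit` times the shaft radius (estimated from the most distal
#'   sections) of the axis, on the anterior side: the sigmoid-notch ridge
#'   hugs the trochlea centre near the axis, whereas the coronoid tip
#'   margin, the dorsal cortex and the olecranon corners -- which also
#'   carry sharp creases -- lie far off-axis or posteriorly.
#' @return Matrix of ridge points (one row per non-empty section) with
#'   attributes `curvature` (|K| at each) and `weak` (TRUE when no
#'   distinguished curvature maximum was found).
#' @export
find_ridge_points <- function(model, axis, n_sections = 5L, k_neighbors = 20L,
                              max_residual = 0.45, radial_limit = 1.35) {
  stopifnot(inherits(model, "surface_model"), inherits(axis, "line3d"))
  t <- line_coordinate(model$points, axis)
  rad <- line_distance(model$points, axis)
  anterior <- anterior_direction(model, axis)
  # shaft radius from the most distal sections; the ridge search stays
  # within ~1.35 shaft radii of the axis and off the dorsal cortex
  r_shaft <- stats::median(rad[t <= min(t) + 0.12 * (max(t) - min(t))])
  rel <- sweep(model$points, 2, axis$point)
  a_all <- drop((rel - outer(drop(rel %*% axis$direction), axis$direction)) %*% anterior)
  near_axis <- rad <= radial_limit * r_shaft & a_all >= -0.8 * r_shaft
  lo <- stats::quantile(t, 0.60)
  hi <- stats::quantile(t, 0.95)
  centers <- seq(lo, hi, length.out = n_sections)
  halfwidth <- if (n_sections > 1L) diff(centers[1:2]) / 2 else (hi - lo) / 2 + 1e-9
  out <- matrix(NA_real_, n_sections, 3L)
  curv <- rep(NA_real_, n_sections)
  for (i in seq_len(n_sections)) {
    sel <- which(abs(t - centers[i]) <= halfwidth & near_axis)
    if (length(sel) == 0L) next
    # two-pass estimate: denoise the slab and a surrounding halo by MLS
    # projection, then evaluate curvature on the denoised coordinates
    k2 <- max(k_neighbors, 34L) # wider window for the curvature pass only
    halo <- sort(unique(c(sel, as.vector(knn_indices(model$points,
                                                     model$points[sel, , drop = FALSE],
                                                     k2)))))
    dn <- model$points
    dn[halo, ] <- denoise_points(model$points, halo, k_neighbors)
    qc <- quadric_curvature(dn, sel, k2)
    ck <- tibble::tibble(gaussian_curvature = qc$K, residual_mm = qc$residual)
    ok <- which(is.finite(ck$residual_mm) & ck$residual_mm <= max_residual)
    if (length(ok) == 0L) next
    # walk candidates by decreasing |K| and keep the first that shows a
    # genuine transverse crest (strongly convex apex parabola); noise
    # maxima on smooth regions fail this check
    ord <- ok[order(-abs(ck$gaussian_curvature[ok]))]
    ord <- ord[seq_len(min(12L, length(ord)))]
    chosen <- NULL
    for (j in ord) {
      rp <- refine_ridge_point(model$points[sel[j], ], model$points, axis,
                               anterior)
      if (attr(rp, "crest_curv") <= -0.05) {
        chosen <- list(p = rp, j = j)
        break
      }
      if (is.null(chosen)) chosen <- list(p = rp, j = j)
    }
    out[i, ] <- chosen$p
    curv[i] <- abs(ck$gaussian_curvature[chosen$j])
  }
  found <- !is.na(out[, 1])
  if (!all(found)) {
    rlang::warn(sprintf("%d of %d ridge sections were empty",
                        sum(!found), n_sections))
  }
  out <- out[found, , drop = FALSE]
  weak <- all(curv[found] < 1e-3) # no crease anywhere: featureless surface
  if (weak) rlang::warn("no distinguished curvature ridge found")
  structure(out, curvature = curv[found], weak = weak)
}

#' Robust ridge plane
#'
#' The sigmoid-notch ridge plane runs parallel to the shaft axis, so with
#' the axis given the fit reduces to a 2D line in the plane perpendicular
#' to the axis: lateral offset as a function of anterior position,
#' estimated by Theil-Sen (median of pairwise slopes), which tolerates one
#' spurious ridge point. The detected ridge points lie on a shallow arc,
#' where an unconstrained total-least-squares plane can rotate by tens of
#' degrees about the crest chord under sub-millimetre jitter; without an
#' axis the function falls back to [fit_plane()].
#'
#' @param points Ridge points (>= 3 rows).
#' @param axis Optional shaft axis ([line3d()]).
#' @return A [plane3d()].
#' @export
fit_ridge_plane <- function(points, axis = NULL) {
  pts <- as_points_matrix(points)
  if (nrow(pts) < 3L) {
    rlang::abort("ridge plane needs at least 3 ridge points",
                 class = "coronoid_degenerate_error")
  }
  if (is.null(axis)) return(fit_plane(pts))
  ctr <- colMeans(pts)
  rel0 <- ctr - axis$point
  radial <- rel0 - sum(rel0 * axis$direction) * axis$direction
  if (sqrt(sum(radial^2)) < 1e-9) radial <- c(axis$direction[2], -axis$direction[1], 0)
  e_a <- unit3(radial)                       # in-plane "anterior-ish"
  e_l <- unit3(cross3(axis$direction, e_a))  # in-plane lateral
  rel <- sweep(pts, 2, ctr)
  a <- drop(rel %*% e_a)
  l <- drop(rel %*% e_l)
  n <- length(a)
  ij <- utils::combn(n, 2)
  da <- a[ij[2, ]] - a[ij[1, ]]
  dl <- l[ij[2, ]] - l[ij[1, ]]
  keep <- abs(da) > 1e-6
  beta <- if (any(keep)) stats::median(dl[keep] / da[keep]) else 0
  alpha <- stats::median(l - beta * a)
  normal <- unit3(e_l - beta * e_a)
  plane3d(ctr + alpha * e_l, normal)
}

#' Find the coronoid tip (point P)
#'
#' The ridge plane fitted through the sigmoid-notch ridge points intersects
#' the coronoid process at its tip. Among model points on the coronoid
#' (anterior) side -- the side opposite the olecranon mass relative to the
#' shaft axis -- the tip is the point of minimal absolute distance to the
#' ridge plane, with near-ties broken by the greatest distance from the
#' shaft axis.
#'
#' @param model A [surface_model()].
#' @param ridge_plane Plane through the ridge points (see [fit_plane()]).
#' @param axis Shaft axis, used for the anterior-side test and the tie-break.
#' @param tie_tol Near-tie width in mm for the distance-to-plane minimum.
#' @return Length-3 tip coordinates (mm).
#' @export
find_coronoid_tip <- function(model, ridge_plane, axis, tie_tol = 4.0) {
  stopifnot(inherits(model, "surface_model"), inherits(ridge_plane, "plane3d"),
            inherits(axis, "line3d"))
  pts <- model$points
  anterior <- anterior_direction(model, axis)
  rad <- sweep(pts, 2, axis$point)
  rad <- rad - outer(drop(rad %*% axis$direction), axis$direction)
  a_coord <- drop(rad %*% anterior)
  cand <- which(a_coord > 0.5 * max(a_coord))
  if (length(cand) == 0L) {
    rlang::abort("no anterior coronoid candidates found", class = "coronoid_tip_error")
  }
  d <- abs(plane_distance(pts[cand, , drop = FALSE], ridge_plane))
  if (min(d) > 2) {
    rlang::abort("no coronoid point within 2 mm of the ridge plane",
                 class = "coronoid_tip_error")
  }
  near <- cand[d <= pmin(min(d) + tie_tol, 4.5)]
  # the tip is the unique protrusion maximum of the anterior surface:
  # hill-climb on (noise-smoothed) axis distance within the candidate set
  # so neither a tilted ridge plane (jittered crest points) nor a single
  # noise-inflated margin point can strand the pick off the apex
  cand_axd <- line_distance(pts[cand, , drop = FALSE], axis)
  if (length(cand) >= 8L) {
    nn <- RANN::nn2(pts[cand, , drop = FALSE], pts[cand, , drop = FALSE],
                    k = min(6L, length(cand)))$nn.idx
    cand_axd <- rowMeans(matrix(cand_axd[nn], nrow(nn)))
  }
  smooth_near <- cand_axd[match(near, cand)]
  # several spread-out starts so a disconnected local protrusion (e.g. a
  # fragment margin corner) cannot trap the climb away from the apex
  ord <- near[order(-smooth_near)]
  inits <- integer(0)
  for (i in ord) {
    if (length(inits) == 4L) break
    if (length(inits) == 0L ||
        min(rowSums(sweep(pts[inits, , drop = FALSE], 2, pts[i, ])^2)) > 25) {
      inits <- c(inits, i)
    }
  }
  climb <- function(cur) {
    for (step in 1:25) {
      ball <- which(rowSums(sweep(pts[cand, , drop = FALSE], 2,
                                  pts[cur, ])^2) <= 16)
      nxt <- cand[ball[which.max(cand_axd[ball])]]
      if (nxt == cur) break
      cur <- nxt
    }
    cur
  }
  ends <- vapply(inits, climb, integer(1))
  best <- ends[which.max(cand_axd[match(ends, cand)])]
  # the climb ran on the smoothed field; hand back the sharpest protrusion
  # in its immediate neighbourhood
  raw_axd <- line_distance(pts[cand, , drop = FALSE], axis)
  nb <- which(rowSums(sweep(pts[cand, , drop = FALSE], 2, pts[best, ])^2) <= 2.25)
  pts[cand[nb[which.max(raw_axd[nb])]], ]
}

# Anterior unit direction perpendicular to the shaft axis: opposite the
# radial offset of the olecranon mass (most proximal 10% of the extent).
anterior_direction <- function(model, axis) {
  pts <- model$points
  t <- line_coordinate(pts, axis)
  thr <- stats::quantile(t, 0.90)
  ole <- colMeans(pts[t >= thr, , drop = FALSE])
  ole_rad <- ole - (axis$point + sum((ole - axis$point) * axis$direction) * axis$direction)
  -unit3(ole_rad)
}

# Snap a detected ridge point to the crest apex: within a thin axial band
# around the point, the anterior coordinate peaks at the guiding ridge, so
# a parabola over the tangential coordinate relocates the point laterally
# with sub-sample precision.
refine_ridge_point <- function(pstar, pts, axis, anterior) {
  rel <- pstar - axis$point
  radial <- rel - sum(rel * axis$direction) * axis$direction
  if (sqrt(sum(radial^2)) < 1e-6) return(structure(pstar, crest_curv = 0))
  u_r <- unit3(radial)
  u_t <- unit3(cross3(axis$direction, u_r))
  t_all <- line_coordinate(pts, axis)
  t_star <- sum(rel * axis$direction)
  s_coord <- drop(sweep(pts, 2, pstar) %*% u_t)
  a_all <- drop(sweep(pts, 2, axis$point) %*% anterior)
  a_star <- sum((pstar - axis$point) * anterior)
  # stay on the crest sheet: same axial band, same anterior depth band
  near <- which(abs(t_all - t_star) <= 1.2 & abs(s_coord) <= 2.5 &
                  abs(a_all - a_star) <= 3)
  if (length(near) < 12L) return(structure(pstar, crest_curv = 0))
  a_coord <- a_all[near]
  sfit <- s_coord[near]
  tfit <- t_all[near] - t_star
  # axial trend terms absorb the along-crest slope of the trough so the
  # lateral apex position is not biased by the section's axial spread
  cf <- tryCatch(stats::lm.fit(cbind(1, sfit, sfit^2, tfit, tfit^2),
                               a_coord)$coefficients,
                 error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= -1e-6) {
    return(structure(pstar, crest_curv = 0))
  }
  s_hat <- max(min(-cf[2] / (2 * cf[3]), 1.5), -1.5)
  a_hat <- cf[1] + cf[2] * s_hat + cf[3] * s_hat^2
  structure(pstar + s_hat * u_t + max(min(a_hat - a_star, 1), -1) * anterior,
            crest_curv = cf[3])
}

#' Anatomical local frame
#'
#' Builds the local coordinate system from the shaft axis and coronoid tip:
#' origin O is the orthogonal projection of the tip P onto the axis,
#' Z = axis direction (distal -> proximal), Y = unit(P - O) (towards the
#' coronoid tip), X = Y x Z, giving a right-handed orthonormal triad.
#'
#' @param axis Shaft axis ([line3d()]).
#' @param tip Coronoid tip coordinates (mm), off the axis.
#' @return An object of class `local_frame` with fields `origin`, `x_axis`,
#'   `y_axis`, `z_axis`, `tip`.
#' @export
build_local_frame <- function(axis, tip) {
  stopifnot(inherits(axis, "line3d"))
  tip <- as.numeric(tip)
  tproj <- sum((tip - axis$point) * axis$direction)
  origin <- axis$point + tproj * axis$direction
  offset <- tip - origin
  if (sqrt(sum(offset^2)) <= 1e-6) {
    rlang::abort("tip lies on the shaft axis; frame is degenerate",
                 class = "coronoid_degenerate_error")
  }
  z <- axis$direction
  y <- unit3(offset)
  x <- unit3(cross3(y, z))
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z, tip = tip),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat(sprintf("<local_frame> origin (%.2f, %.2f, %.2f) mm, |OP| = %.2f mm\n",
              x$origin[1], x$origin[2], x$origin[3],
              sqrt(sum((x$tip - x$origin)^2))))
  invisible(x)
}

#' @export
tidy.local_frame <- function(x, ...) {
  tibble::tibble(
    element = c("origin", "x_axis", "y_axis", "z_axis", "tip"),
    x = c(x$origin[1], x$x_axis[1], x$y_axis[1], x$z_axis[1], x$tip[1]),
    y = c(x$origin[2], x$x_axis[2], x$y_axis[2], x$z_axis[2], x$tip[2]),
    z = c(x$origin[3], x$x_axis[3], x$y_axis[3], x$z_axis[3], x$tip[3])
  )
}

#' Transform a surface model into its local frame
#'
#' Rigid transform mapping O to the origin and the frame axes to the
#' coordinate axes; pairwise distances are preserved to numerical precision.
#' The result is tagged so downstream stages can require local-frame input.
#'
#' @param model A [surface_model()].
#' @param frame A `local_frame` from [build_local_frame()].
#' @return The transformed [surface_model()], with attributes `local = TRUE`,
#'   `frame`, and `tip_local`.
#' @export
to_local <- function(model, frame) {
  stopifnot(inherits(model, "surface_model"), inherits(frame, "local_frame"))
  R <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  out <- model
  out$points <- sweep(model$points, 2, frame$origin) %*% t(R)
  attr(out, "local") <- TRUE
  attr(out, "frame") <- frame
  attr(out, "tip_local") <- drop(R %*% (frame$tip - frame$origin))
  out
}

#' Invert [to_local()]
#'
#' @param model A local-frame [surface_model()].
#' @param frame The frame used for [to_local()]; defaults to the one stored
#'   on the model.
#' @return The model back in world coordinates.
#' @export
from_local <- function(model, frame = attr(model, "frame")) {
  stopifnot(inherits(model, "surface_model"), inherits(frame, "local_frame"))
  R <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  out <- model
  out$points <- model$points %*% R + matrix(frame$origin, nrow(model$points), 3,
                                            byrow = TRUE)
  attr(out, "local") <- NULL
  attr(out, "frame") <- NULL
  attr(out, "tip_local") <- NULL
  out
}
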