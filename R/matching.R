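# Mirror-image matching of the bilateral coronoid processes: with both
# sides expressed in their own anatomical local frames, mirroring the left
# across X = 0 overlays the shaft axes (Z) and coronoid tip directions (+Y)
# by construction; similarity of the articular sheets is then quantified by
# the 2 mm proximity region and the Delaunay-area covering percentage.

#' Mirror a surface model across the sagittal plane
#'
#' Negates the medio-lateral (X) coordinate, flips the side label and
#' reverses triangle winding when faces are present. Applying it twice
#' restores the input exactly.
#'
#' @param model A [surface_model()], typically in its local frame.
#' @return The mirrored [surface_model()].
#' @export
mirror_surface <- function(model) {
  stopifnot(inherits(model, "surface_model"))
  out <- model
  out$points[, 1] <- -out$points[, 1]
  out$side <- if (identical(model$side, "left")) "right" else "left"
  if (!is.null(out$faces)) out$faces <- out$faces[, c(1, 3, 2), drop = FALSE]
  tl <- attr(out, "tip_local")
  if (!is.null(tl)) {
    tl[1] <- -tl[1]
    attr(out, "tip_local") <- tl
  }
  out
}

#' Align a bilateral pair for matching
#'
#' Both models must already be in their own local frames, where the shaft
#' axis is Z and the tip lies on +Y. The left side is mirrored across X = 0
#' and translated along Z so the two tip points share the same Z (the
#' frame construction places both at Z = 0, so the translation is numerical
#' noise). Tip points then lie on the +Y axis for both sides; a difference
#' in |OP| between sides (size asymmetry) is not scaled away, only logged.
#'
#' @param left,right Local-frame [surface_model()] objects.
#' @return List with `left` (mirrored, aligned), `right`, `tip_offset_mm`
#'   (residual |OP| difference) and `tip_dz_mm` (Z translation applied).
#' @export
align_bilateral <- function(left, right) {
  stopifnot(inherits(left, "surface_model"), inherits(right, "surface_model"))
  if (!isTRUE(attr(left, "local")) || !isTRUE(attr(right, "local"))) {
    rlang::abort("align_bilateral expects both models in their local frames",
                 class = "coronoid_precondition_error")
  }
  lm <- mirror_surface(left)
  tl <- attr(lm, "tip_local")
  tr <- attr(right, "tip_local")
  if (is.null(tl)) tl <- c(0, max(lm$points[, 2]), 0)
  if (is.null(tr)) tr <- c(0, max(right$points[, 2]), 0)
  dz <- tr[3] - tl[3]
  lm$points[, 3] <- lm$points[, 3] + dz
  tip_offset <- abs(tr[2] - tl[2])
  list(left = lm, right = right, tip_offset_mm = tip_offset, tip_dz_mm = dz)
}

#' Extract the articular surface of a target fragment
#'
#' Selects fragment points whose estimated outward normal lies within
#' `cone_deg` of the direction from the fragment centroid towards the
#' greater-sigmoid-notch centre (the trochlea-facing side). Normals are
#' estimated by local PCA and oriented outwards against the running
#' cross-section centroid of the fragment shell. The single best-aligned
#' point is always retained, so `cone_deg = 0` returns exactly one point.
#'
#' @param fragment A [trim_fragment()] result.
#' @param notch_center Greater-sigmoid-notch centre in the same frame;
#'   defaults to the value stored on the fragment by the pipeline.
#' @param k_neighbors Neighbourhood size for normal estimation.
#' @param cone_deg Half-angle of the acceptance cone in degrees.
#' @return Integer indices into `fragment$points`; also stored on the
#'   returned fragment by [run_subject()].
#' @export
extract_articular_surface <- function(fragment, notch_center = fragment$notch_center,
                                      k_neighbors = 20L, cone_deg = 60) {
  stopifnot(inherits(fragment, "target_fragment"))
  if (is.null(notch_center)) {
    rlang::abort("notch_center is required to orient the articular cone",
                 class = "coronoid_precondition_error")
  }
  pts <- fragment$points
  n_pts <- nrow(pts)
  if (n_pts < 3L) {
    rlang::abort("fragment too small for articular extraction",
                 class = "coronoid_articular_error")
  }
  k <- min(k_neighbors, n_pts)
  nn <- knn_indices(pts, pts, k)
  u <- unit3(as.numeric(notch_center) - colMeans(pts))
  # running cross-section centroids along Y orient normals outwards
  ord <- order(pts[, 2])
  normals <- matrix(NA_real_, n_pts, 3L)
  for (i in seq_len(n_pts)) {
    nb <- pts[nn[i, ], , drop = FALSE]
    ev <- eigen(stats::cov(nb), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    sel <- which(abs(pts[, 2] - pts[i, 2]) <= 1.5)
    ctr <- if (length(sel) >= 4L) colMeans(pts[sel, , drop = FALSE]) else colMeans(pts)
    if (sum(nrm * (pts[i, ] - ctr)) < 0) nrm <- -nrm
    normals[i, ] <- nrm
  }
  ang <- acos(pmin(pmax(drop(normals %*% u), -1), 1)) * 180 / pi
  sel <- which(ang <= cone_deg)
  if (length(sel) == 0L) sel <- which.min(ang) # always keep the best-aligned point
  # soft membership near the cone edge, for weight-aware consumers
  structure(sort(sel),
            weights = pmin(pmax((cone_deg - ang[sort(sel)]) / 3 + 1, 0), 1))
}

#' Proximity region between two articular point sets
#'
#' A point of one set is in the proximity region when its nearest neighbour
#' in the other set lies within `d` mm, evaluated symmetrically.
#'
#' @param a,b Point matrices (n x 3, mm).
#' @param d Proximity distance in mm (2 mm articular-proximity convention).
#' @return List of logical vectors `mask_a`, `mask_b`.
#' @export
proximity_region <- function(a, b, d = 2.0) {
  a <- as_points_matrix(a)
  b <- as_points_matrix(b)
  stopifnot(nrow(a) > 0L, nrow(b) > 0L, d > 0)
  da <- RANN::nn2(b, a, k = 1L)$nn.dists[, 1]
  db <- RANN::nn2(a, b, k = 1L)$nn.dists[, 1]
  list(mask_a = da <= d, mask_b = db <= d)
}

#' Covering percentage
#'
#' `2 * S / (S1 + S2) * 100`, where S is the proximity-region area and S1,
#' S2 the articular areas of the two sides; 100% indicates perfect
#' bilateral matching.
#'
#' @param S Proximity-region area (mm^2, >= 0).
#' @param S1,S2 Articular areas of the two fragments (mm^2, > 0).
#' @return Percentage in `[0, 100]` (unclipped value; callers clip).
#' @export
covering_percentage <- function(S, S1, S2) {
  if (!(S1 > 0 && S2 > 0) || S1 + S2 <= 0) {
    rlang::abort("articular areas must be positive", class = "coronoid_degenerate_error")
  }
  if (S < 0) {
    rlang::abort("proximity area must be non-negative", class = "coronoid_degenerate_error")
  }
  2 * S / (S1 + S2) * 100
}

#' Match a bilateral fragment pair
#'
#' Computes the articular Delaunay areas S1 (left) and S2 (right), the
#' proximity masks at distance `d`, the proximity-region area S (mean of
#' the two masked-subset Delaunay areas, which makes the identity case
#' exactly 100% and the statistic symmetric under side swap), and the
#' covering percentage, clipped to `[0, 100]` with a flag when clipping
#' occurred.
#'
#' @param left_frag,right_frag Aligned [trim_fragment()] objects (left
#'   already mirrored) carrying articular indices.
#' @param d Proximity distance in mm.
#' @return Object of class `coronoid_match`: a list with the areas, masks,
#'   covering percentage and bookkeeping fields.
#' @export
match_pair <- function(left_frag, right_frag, d = 2.0) {
  stopifnot(inherits(left_frag, "target_fragment"),
            inherits(right_frag, "target_fragment"))
  if (is.null(left_frag$articular) || is.null(right_frag$articular)) {
    rlang::abort("fragments need articular indices; run extract_articular_surface()",
                 class = "coronoid_precondition_error")
  }
  a <- left_frag$points[left_frag$articular, , drop = FALSE]
  b <- right_frag$points[right_frag$articular, , drop = FALSE]
  S1 <- delaunay_area(a)
  S2 <- delaunay_area(b)
  pr <- proximity_region(a, b, d)
  area_masked <- function(p, mask) {
    if (sum(mask) < 3L) return(0)
    tryCatch(delaunay_area(p[mask, , drop = FALSE]),
             error = function(e) 0)
  }
  S <- mean(c(area_masked(a, pr$mask_a), area_masked(b, pr$mask_b)))
  cov_raw <- covering_percentage(S, S1, S2)
  clipped <- cov_raw > 100 || cov_raw < 0
  structure(list(S1 = S1, S2 = S2, S = S,
                 covering_percentage = min(max(cov_raw, 0), 100),
                 covering_raw = cov_raw, clipped = clipped,
                 proximity_mask_left = pr$mask_a,
                 proximity_mask_right = pr$mask_b,
                 d_mm = d,
                 subject_id = right_frag$subject_id),
            class = "coronoid_match")
}

#' @export
print.coronoid_match <- function(x, ...) {
  cat(sprintf("<coronoid_match> %s: S1 = %.1f, S2 = %.1f, S = %.1f mm^2, covering = %.1f%%%s\n",
              x$subject_id, x$S1, x$S2, x$S, x$covering_percentage,
              if (x$clipped) " (clipped)" else ""))
  invisible(x)
}

#' @export
tidy.coronoid_match <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id,
                 S1_mm2 = x$S1, S2_mm2 = x$S2, S_mm2 = x$S,
                 covering_pct = x$covering_percentage,
                 clipped = x$clipped,
                 n_articular_left = length(x$proximity_mask_left),
                 n_articular_right = length(x$proximity_mask_right),
                 prox_frac_left = mean(x$proximity_mask_left),
                 prox_frac_right = mean(x$proximity_mask_right))
}

#' @export
glance.coronoid_match <- function(x, ...) {
  tibble::tibble(covering_pct = x$covering_percentage,
                 S_mm2 = x$S, S1_mm2 = x$S1, S2_mm2 = x$S2, d_mm = x$d_mm)
}
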