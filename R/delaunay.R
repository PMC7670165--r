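# Delaunay-triangulation surface area on the local XY projection.
# The articular surface is a curved sheet; triangulating its planar
# projection and summing triangle areas with the original 3D vertices gives
# a terrain-style surface area, consistent for both sides of a pair.

#' Delaunay triangulation of the XY projection
#'
#' Triangulates the projection of a 3D point set onto the local XY plane.
#' Duplicate projections are removed keeping the vertex nearest the viewer
#' (largest z) before triangulation.
#'
#' @param points n x 3 matrix (mm), typically in the anatomical local frame.
#' @return List with `triangles` (m x 3 indices into the deduplicated set),
#'   `points` (kept 3D vertices) and `kept` (indices into the input).
#' @export
delaunay_triangulate <- function(points) {
  pts <- as_points_matrix(points)
  if (nrow(pts) < 3L) {
    rlang::abort("triangulation needs at least 3 points",
                 class = "coronoid_degenerate_error")
  }
  # dedup identical XY projections, keep nearest-to-viewer (max z)
  ord <- order(pts[, 3], decreasing = TRUE)
  key <- paste(pts[ord, 1], pts[ord, 2], sep = "|")
  kept <- sort(ord[!duplicated(key)])
  p <- pts[kept, , drop = FALSE]
  if (nrow(p) < 3L) {
    rlang::abort("fewer than 3 distinct projected points",
                 class = "coronoid_degenerate_error")
  }
  sv <- svd(sweep(p[, 1:2, drop = FALSE], 2, colMeans(p[, 1:2, drop = FALSE])), nu = 0)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1e-12)) {
    rlang::abort("projected points are collinear; triangulation is degenerate",
                 class = "coronoid_degenerate_error")
  }
  dd <- tryCatch(
    suppressWarnings(deldir::deldir(p[, 1], p[, 2], round = FALSE)),
    error = function(e) rlang::abort(
      sprintf("Delaunay triangulation failed: %s", conditionMessage(e)),
      class = "coronoid_degenerate_error")
  )
  tri <- deldir::triMat(dd)
  list(triangles = tri, points = p, kept = kept)
}

#' Delaunay-projected surface area
#'
#' Area of a (possibly curved) surface patch given as a point cloud:
#' Delaunay triangulation of the XY projection, with triangle areas computed
#' from the original 3D vertex coordinates and summed.
#'
#' @inheritParams delaunay_triangulate
#' @param use_3d If `FALSE`, sum flat projected (2D) triangle areas instead.
#' @return Total area in mm^2.
#' @export
delaunay_area <- function(points, use_3d = TRUE) {
  tr <- delaunay_triangulate(points)
  p <- if (use_3d) tr$points else cbind(tr$points[, 1:2], 0)
  a <- p[tr$triangles[, 1], , drop = FALSE]
  b <- p[tr$triangles[, 2], , drop = FALSE]
  cc <- p[tr$triangles[, 3], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}
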