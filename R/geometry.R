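# Low-level 3D primitives shared by the frame, morphometry and matching stages.
# Points are n x 3 numeric matrices in mm throughout.

#' Construct a plane
#'
#' A plane is stored as a point on the plane and a unit normal.
#'
#' @param point Numeric length-3 point on the plane (mm).
#' @param normal Numeric length-3 normal; normalised internally.
#' @return An object of class `plane3d`.
#' @export
plane3d <- function(point, normal) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L,
            all(is.finite(point)), all(is.finite(normal)))
  n2 <- sqrt(sum(normal^2))
  if (n2 < 1e-12) {
    rlang::abort("plane normal has zero length", class = "coronoid_degenerate_error")
  }
  structure(list(point = point, normal = normal / n2), class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("<plane3d> point (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Construct a line
#'
#' @param point Numeric length-3 point on the line (mm).
#' @param direction Numeric length-3 direction; normalised internally.
#' @return An object of class `line3d`.
#' @export
line3d <- function(point, direction) {
  point <- as.numeric(point)
  direction <- as.numeric(direction)
  stopifnot(length(point) == 3L, length(direction) == 3L,
            all(is.finite(point)), all(is.finite(direction)))
  n2 <- sqrt(sum(direction^2))
  if (n2 < 1e-12) {
    rlang::abort("line direction has zero length", class = "coronoid_degenerate_error")
  }
  structure(list(point = point, direction = direction / n2), class = "line3d")
}

#' @export
print.line3d <- function(x, ...) {
  cat(sprintf("<line3d> point (%.3f, %.3f, %.3f) mm, direction (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    rlang::abort("cannot normalise a zero vector", class = "coronoid_degenerate_error")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed distances from points to a plane
#'
#' Positive on the side the normal points to.
#'
#' @param points n x 3 matrix (mm).
#' @param plane A [plane3d()].
#' @return Numeric vector of signed distances (mm).
#' @export
plane_distance <- function(points, plane) {
  points <- as_points_matrix(points)
  drop((points - matrix(plane$point, nrow(points), 3, byrow = TRUE)) %*% plane$normal)
}

#' Distances from points to a line
#'
#' @inheritParams plane_distance
#' @param line A [line3d()].
#' @return Numeric vector of orthogonal distances (mm).
#' @export
line_distance <- function(points, line) {
  points <- as_points_matrix(points)
  d <- points - matrix(line$point, nrow(points), 3, byrow = TRUE)
  t <- drop(d %*% line$direction)
  sqrt(pmax(rowSums(d^2) - t^2, 0))
}

# axial coordinate of each point along a line
line_coordinate <- function(points, line) {
  points <- as_points_matrix(points)
  drop((points - matrix(line$point, nrow(points), 3, byrow = TRUE)) %*% line$direction)
}

as_points_matrix <- function(points) {
  if (inherits(points, "surface_model")) points <- points$points
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L)
  points
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising the (optionally weighted) sum of squared
#' orthogonal distances to the points (via SVD of the centred coordinates).
#'
#' @param points At least 3 non-collinear points; n x 3 matrix, data frame
#'   with x/y/z columns, or a `surface_model`.
#' @param weights Optional non-negative observation weights.
#' @return A [plane3d()] through the (weighted) centroid.
#' @export
fit_plane <- function(points, weights = NULL) {
  points <- as_points_matrix(points)
  if (nrow(points) < 3L) {
    rlang::abort("plane fit needs at least 3 points", class = "coronoid_degenerate_error")
  }
  if (is.null(weights)) {
    ctr <- colMeans(points)
    x <- sweep(points, 2, ctr)
  } else {
    ctr <- drop(weights %*% points) / sum(weights)
    x <- sweep(points, 2, ctr) * sqrt(weights / mean(weights))
  }
  sv <- svd(x, nu = 0)
  # collinear: second singular value vanishes relative to the first
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1e-12)) {
    rlang::abort("points are collinear; plane fit is degenerate",
                 class = "coronoid_degenerate_error")
  }
  plane3d(ctr, sv$v[, 3])
}

# Rigid (rotation + translation) map taking world coordinates into a frame
# with origin `origin` and orthonormal axes given as columns of R.
apply_rigid <- function(points, rotation, translation = c(0, 0, 0)) {
  points <- as_points_matrix(points)
  points %*% t(rotation) + matrix(translation, nrow(points), 3, byrow = TRUE)
}

# exactly orthogonal rotation matrix from a unit quaternion
rotation_from_quaternion <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Taubin algebraic circle fit
#'
#' Non-iterative algebraic fit of a circle to 2D points, used for the medial
#' and lateral facet radii. Exact for points lying on a circle.
#'
#' @param xy n x 2 matrix of planar coordinates (mm).
#' @param weights Optional non-negative observation weights.
#' @return List with `center` (length 2), `radius` (mm).
#' @export
fit_circle_taubin <- function(xy, weights = NULL) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  if (nrow(xy) < 3L) {
    rlang::abort("circle fit needs at least 3 points", class = "coronoid_degenerate_error")
  }
  if (!is.null(weights)) {
    w <- weights / mean(weights)
    sw <- sqrt(w)
    ctr <- c(sum(w * xy[, 1]), sum(w * xy[, 2])) / sum(w)
    u <- (xy[, 1] - ctr[1])
    v <- (xy[, 2] - ctr[2])
    # weighted algebraic fit: scale rows by sqrt(w)
    z <- u^2 + v^2
    zm <- sum(w * z) / sum(w)
    sv2 <- svd(cbind((z - zm) / (2 * sqrt(zm)), u, v) * sw, nu = 0)
    a <- sv2$v[, 3]
    A <- a[1] / (2 * sqrt(zm))
    if (abs(A) < 1e-14) {
      rlang::abort("circle fit degenerated to a line", class = "coronoid_degenerate_error")
    }
    cc <- -c(a[2], a[3]) / (2 * A)
    radius <- sqrt(max((a[2]^2 + a[3]^2) / (4 * A^2) + zm, 0))
    return(list(center = cc + ctr, radius = radius))
  }
  ctr <- colMeans(xy)
  u <- xy[, 1] - ctr[1]
  v <- xy[, 2] - ctr[2]
  # collinearity check on the centred coordinates
  sv <- svd(cbind(u, v), nu = 0)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1e-12)) {
    rlang::abort("points are collinear; circle fit is degenerate",
                 class = "coronoid_degenerate_error")
  }
  # Taubin's constraint: smallest singular vector of [(z - zbar)/(2*sqrt(zbar)), u, v]
  # gives A*(u^2+v^2) + B*u + C*v + D = 0 with D = -A*zbar.
  z <- u^2 + v^2
  zm <- mean(z)
  sv2 <- svd(cbind((z - zm) / (2 * sqrt(zm)), u, v), nu = 0)
  a <- sv2$v[, 3]
  A <- a[1] / (2 * sqrt(zm))
  B <- a[2]
  C <- a[3]
  D <- -A * zm
  if (abs(A) < 1e-14) {
    rlang::abort("circle fit degenerated to a line", class = "coronoid_degenerate_error")
  }
  cc <- -c(B, C) / (2 * A)
  radius <- sqrt(max((B^2 + C^2) / (4 * A^2) - D / A, 0))
  list(center = cc + ctr, radius = radius)
}
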