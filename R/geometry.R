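#' Convex-hull volume of a point cloud
#'
#' Computes the exact d-dimensional Lebesgue volume of the convex hull of a
#' set of points, the elementary quantity behind functional richness.
#' Degenerate inputs (fewer than `d + 1` points, or points lying in a lower
#' dimensional affine subspace) have volume 0 by convention.
#'
#' The hull is recovered by exhaustive supporting-hyperplane enumeration and
#' the volume accumulated over a fan triangulation; both steps run in
#' compiled code and are exact up to floating-point rounding.  Intended for
#' the low-dimensional (2--6 axes), moderate-size point clouds that arise as
#' individuals in a PCA functional space.
#'
#' @param points numeric matrix, one row per point, `d >= 2` columns.
#' @return a single nonnegative number, the hull volume in coordinate
#'   units to the power `d`.
#' @seealso [hull_intersection_volume()], [fric()], [fove()]
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' hull_volume(sq) # 1
#' @export
hull_volume <- function(points) {
  points <- as_point_matrix(points)
  .chull_volume_cpp(points)
}

#' Half-space representation of a convex hull
#'
#' Returns the supporting hyperplanes of the convex hull as an
#' outward-oriented system `A x <= b` with unit row normals.  Useful for
#' fast point-in-hull tests (e.g. Monte-Carlo work).
#'
#' @inheritParams hull_volume
#' @return list with matrix `A` (facets x d) and vector `b`.
#' @export
hull_hrep <- function(points) {
  points <- as_point_matrix(points)
  .chull_hrep_cpp(points)
}

#' Indices of the hull vertices of a point cloud
#'
#' @inheritParams hull_volume
#' @return integer vector of row indices of `points` that are vertices of
#'   the convex hull.
#' @export
hull_vertices <- function(points) {
  points <- as_point_matrix(points)
  sort(.chull_vertices_cpp(points))
}

#' Volume of the intersection of two convex hulls
#'
#' Computes the exact volume of the intersection polytope of the convex
#' hulls of two point clouds, the numerator of the functional overlap
#' index.  One hull is triangulated into simplices and each simplex is
#' clipped by the facet half-spaces of the other; the clipped convex cells
#' are re-measured after vertex enumeration.  Disjoint hulls give 0.
#'
#' Arguments are put into a canonical order internally, so the result is
#' exactly symmetric in `a` and `b`.
#'
#' @param a,b numeric matrices of points in the same dimension; both hulls
#'   must be full-dimensional (positive volume), otherwise an error points
#'   the caller to the volume-0 convention used by [fric()].
#' @return a single nonnegative number.
#' @examples
#' s1 <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
#' s2 <- s1 + 1
#' hull_intersection_volume(s1, s2) # 1
#' @export
hull_intersection_volume <- function(a, b) {
  a <- as_point_matrix(a)
  b <- as_point_matrix(b)
  if (ncol(a) != ncol(b)) {
    stop("point sets live in different dimensions (", ncol(a), " vs ", ncol(b), ")")
  }
  if (.chull_volume_cpp(a) <= 0 || .chull_volume_cpp(b) <= 0) {
    stop(
      "degenerate input hull (zero volume); treat the group's functional ",
      "richness as 0 instead of computing an overlap"
    )
  }
  o <- canonical_pair_order(a, b)
  .chull_intersection_cpp(o$first, o$second)
}

#' Test points for hull membership
#'
#' @param x numeric matrix of query points.
#' @param hull either a point matrix defining the hull or the result of
#'   [hull_hrep()].
#' @param tol slack allowed on each facet inequality.
#' @return logical vector, one entry per row of `x`.
#' @export
points_in_hull <- function(x, hull, tol = 1e-8) {
  x <- as_point_matrix(x)
  h <- if (is.list(hull) && all(c("A", "b") %in% names(hull))) hull else hull_hrep(hull)
  if (ncol(h$A) != ncol(x)) stop("query points and hull have different dimensions")
  s <- x %*% t(h$A)
  ok <- rep(TRUE, nrow(x))
  for (j in seq_len(ncol(s))) ok <- ok & (s[, j] <= h$b[j] + tol)
  ok
}

# ---- internal helpers -----------------------------------------------------

as_point_matrix <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) < 2) stop("points must have at least 2 columns (dimensions)")
  if (any(!is.finite(points))) stop("non-finite coordinates in point matrix")
  points
}

# deterministic ordering of a pair of point sets so that symmetric metrics
# are computed identically whichever way the caller passes them
canonical_pair_order <- function(a, b) {
  key <- function(m) {
    v <- as.vector(m[order(m[, 1], m[, if (ncol(m) > 1) 2 else 1]), , drop = FALSE])
    paste(format(v, digits = 17), collapse = ",")
  }
  swap <- if (nrow(a) != nrow(b)) nrow(a) > nrow(b) else key(a) > key(b)
  if (swap) list(first = b, second = a) else list(first = a, second = b)
}
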