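# Low-level polygon primitives.
#
# Polygons are n x 2 numeric matrices of vertices, counter-clockwise, not closed
# (first vertex is not repeated).  Every tan is convex, which is what makes the
# containment and overlap tests below exact: clipping an arbitrary simple
# polygon against a convex window (Sutherland-Hodgman) yields the true
# intersection, and its shoelace area is correct even when the result is a
# degenerate multi-part chain.

#' Signed area of a polygon (shoelace formula)
#'
#' @param poly n x 2 numeric matrix of vertices, not closed.
#' @return Signed area; positive for counter-clockwise vertex order.
#' @keywords internal
poly_signed_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Absolute polygon area
#' @param poly n x 2 vertex matrix.
#' @return Non-negative area.
#' @export
poly_area <- function(poly) abs(poly_signed_area(poly))

#' Force counter-clockwise vertex order
#' @param poly n x 2 vertex matrix.
#' @keywords internal
poly_ccw <- function(poly) {
  if (poly_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Polygon centroid (area-weighted)
#' @param poly n x 2 vertex matrix.
#' @keywords internal
poly_centroid <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  cr <- poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((poly[, 1] + poly[j, 1]) * cr), sum((poly[, 2] + poly[j, 2]) * cr)) / (6 * a)
}

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' The subject polygon may be non-convex (e.g. a puzzle silhouette); the clip
#' polygon must be convex (every tan is).
#'
#' @param subject n x 2 vertex matrix, any simple polygon.
#' @param clip m x 2 vertex matrix, convex, counter-clockwise.
#' @return Vertex matrix of the intersection (possibly 0 rows).
#' @keywords internal
poly_clip <- function(subject, clip) {
  out <- poly_ccw(subject)
  clip <- poly_ccw(clip)
  m <- nrow(clip)
  for (i in seq_len(m)) {
    if (nrow(out) < 3) return(matrix(numeric(0), 0, 2))  # degenerate: zero area
    a <- clip[i, ]
    b <- clip[if (i == m) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance of each subject vertex from clip edge (>= 0 is inside)
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    jn <- c(2:n, 1L)
    keep <- vector("list", n)
    for (k in seq_len(n)) {
      kn <- jn[k]
      dk <- d[k]; dn <- d[kn]
      pts <- NULL
      if (dk >= 0) pts <- rbind(pts, out[k, ])
      if ((dk > 0 && dn < 0) || (dk < 0 && dn > 0)) {
        t <- dk / (dk - dn)
        pts <- rbind(pts, out[k, ] + t * (out[kn, ] - out[k, ]))
      }
      keep[[k]] <- pts
    }
    out <- do.call(rbind, keep)
    if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  }
  out
}

#' Area of intersection between a polygon and a convex polygon
#' @param subject any simple polygon (n x 2).
#' @param clip convex polygon (m x 2).
#' @return Non-negative intersection area.
#' @keywords internal
poly_intersection_area <- function(subject, clip) {
  # cheap bounding-box rejection first
  if (max(subject[, 1]) < min(clip[, 1]) || max(clip[, 1]) < min(subject[, 1]) ||
      max(subject[, 2]) < min(clip[, 2]) || max(clip[, 2]) < min(subject[, 2])) {
    return(0)
  }
  poly_area(poly_clip(subject, clip))
}

#' Test points for inclusion in a polygon
#'
#' Even-odd ray casting; points within `tol` of an edge count as inside, so
#' placements touching the silhouette boundary are not rejected.
#'
#' @param x,y coordinate vectors.
#' @param poly n x 2 vertex matrix.
#' @param tol boundary tolerance in coordinate units.
#' @return Logical vector.
#' @keywords internal
points_in_poly <- function(x, y, poly, tol = 1e-9) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  jn <- c(2:n, 1L)
  inside <- rep(FALSE, length(x))
  ondist2 <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]; x2 <- px[jn[k]]; y2 <- py[jn[k]]
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xi <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- xi > x[crosses]
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    # squared distance from points to the segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / L2)) else 0
    qx <- x1 + t * dx; qy <- y1 + t * dy
    ondist2 <- pmin(ondist2, (x - qx)^2 + (y - qy)^2)
  }
  inside | (ondist2 <= tol * tol)
}

#' Axis-aligned bounding box of a polygon
#' @param poly n x 2 vertex matrix.
#' @return Named vector xmin, ymin, xmax, ymax.
#' @keywords internal
poly_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}
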