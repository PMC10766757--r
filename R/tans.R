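# The seven tans and the placement transform.
#
# Coordinate system: the small triangle has legs of length 1, so the full set
# of pieces has area 8.  Under 45-degree rotations every vertex stays inside
# the ring {a + b*sqrt(2) : a, b rational}, which keeps equality tests stable
# at a 1e-9 tolerance without symbolic arithmetic.

#' Piece-kind identifiers, in heatmap order
#' @return Character vector of the five tan kinds.
#' @export
tan_kinds <- function() {
  c("big_triangle", "mid_triangle", "small_triangle", "square", "parallelogram")
}

.tan_canonical_polys <- function() {
  s2 <- sqrt(2)
  list(
    small_triangle = rbind(c(0, 0), c(1, 0), c(0, 1)),
    mid_triangle   = rbind(c(0, 0), c(s2, 0), c(0, s2)),
    big_triangle   = rbind(c(0, 0), c(2, 0), c(0, 2)),
    square         = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    parallelogram  = rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 1))
  )
}

#' The seven Tangram pieces in canonical pose
#'
#' Two small triangles, one medium triangle, two big triangles, one square and
#' one parallelogram.  Instance ids distinguish the duplicated triangles.
#'
#' @return A list of 7 tans; each tan is a list with elements `kind`,
#'   `instance_id`, `polygon` (vertex matrix) and `area`.
#' @export
canonical_tans <- function() {
  polys <- .tan_canonical_polys()
  defs <- list(
    c("small_triangle", 1L), c("small_triangle", 2L),
    c("mid_triangle", 1L),
    c("big_triangle", 1L), c("big_triangle", 2L),
    c("square", 1L), c("parallelogram", 1L)
  )
  lapply(defs, function(s) {
    kind <- s[[1]]
    poly <- polys[[kind]]
    list(kind = kind, instance_id = as.integer(s[[2]]),
         polygon = poly, area = poly_area(poly))
  })
}

#' Number of instances of each tan kind
#' @return Named integer vector.
#' @keywords internal
tan_instance_counts <- function() {
  c(big_triangle = 2L, mid_triangle = 1L, small_triangle = 2L,
    square = 1L, parallelogram = 1L)
}

#' Place a tan: mirror, rotate, and snap to a grid anchor
#'
#' The piece is optionally mirrored (parallelogram only), rotated by a
#' multiple of 45 degrees about its centroid, and then translated so that the
#' lower-left corner of its bounding box coincides with the anchor point.
#'
#' @param kind Tan kind (see [tan_kinds()]).
#' @param rotation Rotation in degrees, a multiple of 45 in `[0, 315]`.
#' @param anchor Length-2 numeric, the anchor point (bounding-box lower-left).
#' @param mirrored Mirror flag; only meaningful for the parallelogram.
#' @return Vertex matrix of the placed polygon (counter-clockwise).
#' @export
transform_tan <- function(kind, rotation, anchor = c(0, 0), mirrored = FALSE) {
  if (!kind %in% tan_kinds()) stop("unknown tan kind: ", kind)
  rotation <- rotation %% 360
  if (abs(rotation / 45 - round(rotation / 45)) > 1e-9) {
    stop("invalid rotation: must be a multiple of 45 degrees, got ", rotation)
  }
  poly <- .tan_canonical_polys()[[kind]]
  if (isTRUE(mirrored)) {
    if (kind != "parallelogram") stop("only the parallelogram can be mirrored")
    poly[, 1] <- -poly[, 1]
    poly <- poly_ccw(poly)
  }
  th <- rotation * pi / 180
  # snap cos/sin to exact ring values (0, +-1, +-sqrt(1/2)) so 45-degree
  # rotations introduce no trigonometric drift
  ct <- if (abs(cos(th) - sqrt(0.5)) < 1e-9) sqrt(0.5) else if (abs(cos(th) + sqrt(0.5)) < 1e-9) -sqrt(0.5) else round(cos(th))
  st <- if (abs(sin(th) - sqrt(0.5)) < 1e-9) sqrt(0.5) else if (abs(sin(th) + sqrt(0.5)) < 1e-9) -sqrt(0.5) else round(sin(th))
  cen <- poly_centroid(poly)
  rel <- sweep(poly, 2, cen)
  rot <- cbind(rel[, 1] * ct - rel[, 2] * st, rel[, 1] * st + rel[, 2] * ct)
  placed <- sweep(rot, 2, cen, FUN = "+")
  bb <- poly_bbox(placed)
  placed[, 1] <- placed[, 1] - bb["xmin"] + anchor[1]
  placed[, 2] <- placed[, 2] - bb["ymin"] + anchor[2]
  poly_ccw(placed)
}
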