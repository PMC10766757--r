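# Bundled puzzles: House and Monk.
#
# The silhouettes are package-defined, coordinate-exact figures of area 8,
# each tiled exactly by the seven tans; a hand-verified 7-placement solution
# ships with each puzzle.  The Monk keeps the behaviourally relevant
# structure observed in study data: a big triangle placed at rotation 270 one
# anchor above the correct spot ("unrecognized composition" error) makes the
# second big triangle unplaceable once one correct big is down.

.cts_cache <- new.env(parent = emptyenv())

#' Grid anchor lattice for a bounding box
#'
#' Anchors are all points of the form a/2 + (b/2)*sqrt(2) per axis with
#' integer a and b in {-1, 0, 1} (one diagonal offset; the full lattice is
#' dense in the reals), restricted to the bounding box and numbered row-major
#' (by y, then x) from 1.
#'
#' @param xmax,ymax Upper corner of the bounding box (lower corner is 0,0).
#' @return data.frame with columns `index`, `x`, `y`.
#' @keywords internal
build_grid <- function(xmax, ymax) {
  axis_vals <- function(vmax) {
    half <- seq(0, ceiling(vmax * 2)) / 2
    v <- sort(unique(round(c(half, half + sqrt(2) / 2, half - sqrt(2) / 2), 9)))
    v[v >= -1e-9 & v <= vmax + 1e-9]
  }
  xs <- axis_vals(xmax)
  ys <- axis_vals(ymax)
  g <- expand.grid(x = xs, y = ys)
  g <- g[order(g$y, g$x), ]
  data.frame(index = seq_len(nrow(g)), x = g$x, y = g$y)
}

.puzzle_defs <- function() {
  sol <- function(kind, rotation, ax, ay, mirrored = FALSE) {
    data.frame(kind = kind, rotation = rotation, ax = ax, ay = ay,
               mirrored = mirrored, stringsAsFactors = FALSE)
  }
  list(
    house = list(
      # body [0,3]x[0,2], trapezoid roof
      target = rbind(c(0, 0), c(3, 0), c(3, 2), c(2, 3), c(1, 3), c(0, 2)),
      solution = rbind(
        sol("big_triangle", 90, 0, 0),
        sol("big_triangle", 270, 0, 0),
        sol("square", 0, 2, 0),
        sol("small_triangle", 0, 2, 1),
        sol("small_triangle", 180, 2, 1),
        sol("mid_triangle", 225, 0, 2),
        sol("parallelogram", 0, 1, 2)
      ),
      # modal wrong opening: big triangle at rotation 0 in the body corner
      modal_error = sol("big_triangle", 0, 0, 0)
    ),
    monk = list(
      # robe [0,2]x[0,3], head triangle on top, arm parallelogram at right
      target = rbind(c(0, 0), c(2, 0), c(3, 1), c(3, 2), c(2, 1), c(2, 3),
                     c(1, 4), c(0, 3)),
      solution = rbind(
        sol("big_triangle", 90, 0, 0),
        sol("big_triangle", 270, 0, 0),
        sol("square", 0, 0, 2),
        sol("small_triangle", 0, 1, 2),
        sol("small_triangle", 180, 1, 2),
        sol("mid_triangle", 225, 0, 3),
        sol("parallelogram", 270, 2, 0)
      ),
      # modal "unrecognized composition" error: big triangle rotation 270 one
      # unit above the correct anchor (blocks the second big triangle once a
      # correct big is placed)
      modal_error = sol("big_triangle", 270, 0, 1)
    )
  )
}

#' Load a bundled Tangram puzzle
#'
#' @param name `"house"` or `"monk"`.
#' @return An object of class `tangram_puzzle`: list with `name`, `target`
#'   polygon, `grid` (anchor data.frame), `solution` (7-row placement
#'   data.frame with `kind`, `grid_loc`, `rotation`, `mirrored`) and
#'   `modal_error` (single placement, the modal wrong opening).
#' @export
tangram_puzzle <- function(name = c("house", "monk")) {
  name <- match.arg(name)
  key <- paste0("puzzle_", name)
  if (!is.null(.cts_cache[[key]])) return(.cts_cache[[key]])
  def <- .puzzle_defs()[[name]]
  target <- poly_ccw(def$target)
  bb <- poly_bbox(target)
  grid <- build_grid(bb["xmax"], bb["ymax"])
  to_loc <- function(df) {
    idx <- mapply(function(x, y) grid_index_at(grid, x, y), df$ax, df$ay)
    data.frame(kind = df$kind, grid_loc = as.integer(idx),
               rotation = as.integer(df$rotation), mirrored = df$mirrored,
               stringsAsFactors = FALSE)
  }
  pz <- structure(list(
    name = name, target = target, grid = grid,
    solution = to_loc(def$solution),
    modal_error = to_loc(def$modal_error)
  ), class = "tangram_puzzle")
  .cts_cache[[key]] <- pz
  pz
}

#' Grid index of the anchor at (x, y)
#' @param grid Anchor data.frame (`index`, `x`, `y`).
#' @param x,y Coordinates; must match an anchor within 1e-6.
#' @return Integer index.
#' @export
grid_index_at <- function(grid, x, y) {
  hit <- which(abs(grid$x - x) < 1e-6 & abs(grid$y - y) < 1e-6)
  if (length(hit) != 1L) stop("no unique grid anchor at (", x, ", ", y, ")")
  grid$index[hit]
}

#' Coordinates of a grid anchor
#' @param grid Anchor data.frame.
#' @param index Anchor index.
#' @return Length-2 numeric `(x, y)`.
#' @export
grid_anchor_xy <- function(grid, index) {
  row <- match(index, grid$index)
  if (is.na(row)) stop("grid index out of range: ", index)
  c(grid$x[row], grid$y[row])
}

#' @export
print.tangram_puzzle <- function(x, ...) {
  cat("Tangram puzzle:", x$name, "\n")
  cat("  target area:", format(poly_area(x$target)), "square units\n")
  cat("  grid anchors:", nrow(x$grid), "\n")
  cat("  solution placements:", nrow(x$solution), "\n")
  invisible(x)
}

#' Write a puzzle definition to YAML
#'
#' Stores the name, target polygon, grid bounds and the bundled solution /
#' modal-error placements so a puzzle can be inspected or exchanged as plain
#' text.
#' @param puzzle A [tangram_puzzle()].
#' @param path Output YAML file.
#' @return Invisibly `path`.
#' @export
write_puzzle_config <- function(puzzle, path) {
  cfg <- list(
    name = puzzle$name,
    target = lapply(seq_len(nrow(puzzle$target)), function(i)
      as.numeric(puzzle$target[i, ])),
    grid = list(numbering = "row-major from 1",
                lattice = "a/2 + (b/2)*sqrt(2), b in -1..1",
                anchors = nrow(puzzle$grid)),
    solution = as.list(puzzle$solution),
    modal_error = as.list(puzzle$modal_error))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a puzzle definition written by [write_puzzle_config()]
#'
#' Reconstructs the puzzle: the anchor grid is rebuilt deterministically from
#' the target polygon's bounding box.
#' @param path YAML file.
#' @return A `tangram_puzzle` object.
#' @export
read_puzzle_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  target <- poly_ccw(do.call(rbind, cfg$target))
  bb <- poly_bbox(target)
  structure(list(
    name = cfg$name, target = target,
    grid = build_grid(bb["xmax"], bb["ymax"]),
    solution = as.data.frame(cfg$solution, stringsAsFactors = FALSE),
    modal_error = as.data.frame(cfg$modal_error, stringsAsFactors = FALSE)
  ), class = "tangram_puzzle")
}
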