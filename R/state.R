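# Puzzle state: placements, coverage bookkeeping, legality oracle,
# unfeasible-region detection and the canonical state signature.

AREA_TOL <- 1e-6

#' Create an empty puzzle state
#'
#' @param puzzle A [tangram_puzzle()].
#' @return Object of class `puzzle_state`: list with the puzzle, an ordered
#'   list of placements, a step counter and a set of problem tags.
#' @export
new_puzzle_state <- function(puzzle) {
  structure(list(
    puzzle = puzzle,
    placed = list(),   # each: kind, instance_id, grid_loc, rotation, mirrored, polygon
    step = 0L,
    problem_tags = integer(0)  # instance keys flagged as causing an unfeasible region
  ), class = "puzzle_state")
}

#' Total area of the silhouette not yet covered
#' @param state A `puzzle_state`.
#' @return Non-negative area in square units.
#' @export
uncovered_area <- function(state) {
  placed_area <- sum(vapply(state$placed, function(p) poly_area(p$polygon), numeric(1)))
  poly_area(state$puzzle$target) - placed_area
}

#' Is the state solved?
#'
#' Solved means all 7 tans are placed and the uncovered area is below
#' tolerance.
#' @param state A `puzzle_state`.
#' @return Logical.
#' @export
is_state_solved <- function(state) {
  length(state$placed) == 7L && uncovered_area(state) <= AREA_TOL
}

#' Instance ids of a kind still free in a state
#' @keywords internal
free_instances <- function(state, kind) {
  used <- vapply(state$placed, function(p)
    if (p$kind == kind) p$instance_id else NA_integer_, integer(1))
  setdiff(seq_len(tan_instance_counts()[[kind]]), used[!is.na(used)])
}

#' Check one placement for geometric legality
#'
#' Legal means the placed polygon lies inside the silhouette and overlaps
#' every already-placed piece by at most the area tolerance (1e-6), i.e. it
#' fits inside the uncovered region.
#'
#' @param state A `puzzle_state`.
#' @param kind Tan kind.
#' @param grid_loc Anchor index.
#' @param rotation Degrees, multiple of 45.
#' @param mirrored Mirror flag (parallelogram only).
#' @return Logical.
#' @export
is_legal_placement <- function(state, kind, grid_loc, rotation, mirrored = FALSE) {
  anchor <- grid_anchor_xy(state$puzzle$grid, grid_loc)
  poly <- transform_tan(kind, rotation, anchor, mirrored)
  placement_polygon_legal(state, poly)
}

#' @keywords internal
placement_polygon_legal <- function(state, poly, skip_target = FALSE) {
  target <- state$puzzle$target
  if (!skip_target) {
    bbp <- poly_bbox(poly); bbt <- poly_bbox(target)
    if (bbp["xmin"] < bbt["xmin"] - AREA_TOL || bbp["ymin"] < bbt["ymin"] - AREA_TOL ||
        bbp["xmax"] > bbt["xmax"] + AREA_TOL || bbp["ymax"] > bbt["ymax"] + AREA_TOL) {
      return(FALSE)
    }
    # fast vertex screen, then the exact clipped-area test
    if (!all(points_in_poly(poly[, 1], poly[, 2], target, tol = 1e-6))) return(FALSE)
    if (poly_intersection_area(target, poly) < poly_area(poly) - AREA_TOL) return(FALSE)
  }
  for (p in state$placed) {
    if (poly_intersection_area(p$polygon, poly) > AREA_TOL) return(FALSE)
  }
  TRUE
}

#' Enumerate placements of a kind legal on the empty silhouette (cached)
#' @keywords internal
empty_board_placements <- function(puzzle, kind, mirroring = TRUE) {
  key <- paste0("legal_", puzzle$name, "_", kind, "_", mirroring)
  if (!is.null(.cts_cache[[key]])) return(.cts_cache[[key]])
  grid <- puzzle$grid
  empty <- new_puzzle_state(puzzle)
  mirrors <- if (kind == "parallelogram" && mirroring) c(FALSE, TRUE) else FALSE
  rows <- list()
  polys <- list()
  n <- 0L
  for (gi in grid$index) {
    anchor <- c(grid$x[gi], grid$y[gi])
    for (rot in seq(0L, 315L, by = 45L)) {
      for (mir in mirrors) {
        poly <- transform_tan(kind, rot, anchor, mir)
        if (placement_polygon_legal(empty, poly)) {
          n <- n + 1L
          rows[[n]] <- data.frame(kind = kind, grid_loc = gi, rotation = rot,
                                  mirrored = mir, stringsAsFactors = FALSE)
          polys[[n]] <- poly
        }
      }
    }
  }
  res <- list(table = if (n) do.call(rbind, rows) else
                data.frame(kind = character(0), grid_loc = integer(0),
                           rotation = integer(0), mirrored = logical(0)),
              polys = polys)
  .cts_cache[[key]] <- res
  res
}

#' Enumerate all legal placements of a tan kind
#'
#' Brute-force oracle over the anchor grid times the 8 rotations (times the
#' mirror flag for the parallelogram), in deterministic (grid index, rotation,
#' mirror) order.  Used as the ground truth against which vision candidates
#' are screened.
#'
#' @param state A `puzzle_state`.
#' @param kind Tan kind to place.
#' @param mirroring Allow the mirrored parallelogram (default TRUE).
#' @return data.frame with columns `kind`, `grid_loc`, `rotation`, `mirrored`
#'   (possibly 0 rows).
#' @export
legal_placements <- function(state, kind, mirroring = TRUE) {
  base <- empty_board_placements(state$puzzle, kind, mirroring)
  if (nrow(base$table) == 0 || length(state$placed) == 0) return(base$table)
  ok <- vapply(seq_len(nrow(base$table)), function(i) {
    placement_polygon_legal(state, base$polys[[i]], skip_target = TRUE)
  }, logical(1))
  base$table[ok, , drop = FALSE]
}

#' Does any unplaced kind lack a legal placement?
#' @keywords internal
kind_has_legal_placement <- function(state, kind, mirroring = TRUE) {
  base <- empty_board_placements(state$puzzle, kind, mirroring)
  if (nrow(base$table) == 0) return(FALSE)
  if (length(state$placed) == 0) return(TRUE)
  for (i in seq_len(nrow(base$table))) {
    if (placement_polygon_legal(state, base$polys[[i]], skip_target = TRUE)) return(TRUE)
  }
  FALSE
}

#' Detect an unfeasible region
#'
#' The uncovered region is unfeasible when some still-unplaced tan kind has no
#' legal placement at all: its area is necessarily split across sub-regions
#' that cannot accommodate it.
#'
#' @param state A `puzzle_state`.
#' @param mirroring Allow the mirrored parallelogram.
#' @return list with `flag` (logical) and `blocked_kinds` (character vector).
#' @export
detect_unfeasible <- function(state, mirroring = TRUE) {
  blocked <- character(0)
  for (kind in tan_kinds()) {
    if (length(free_instances(state, kind)) == 0) next
    if (!kind_has_legal_placement(state, kind, mirroring)) blocked <- c(blocked, kind)
  }
  list(flag = length(blocked) > 0, blocked_kinds = blocked)
}

#' Place a tan on the board
#'
#' @param state A `puzzle_state`.
#' @param kind,grid_loc,rotation,mirrored Placement.
#' @param instance_id Which instance of the kind to use; default is the
#'   lowest-numbered free instance.
#' @param check Verify geometric legality (default TRUE).
#' @return The updated state.
#' @export
place_tan <- function(state, kind, grid_loc, rotation, mirrored = FALSE,
                      instance_id = NULL, check = TRUE) {
  free <- free_instances(state, kind)
  if (length(free) == 0) stop("no free instance of kind ", kind)
  if (is.null(instance_id)) instance_id <- min(free)
  if (!instance_id %in% free) stop("instance ", instance_id, " of ", kind, " already placed")
  anchor <- grid_anchor_xy(state$puzzle$grid, grid_loc)
  poly <- transform_tan(kind, rotation, anchor, mirrored)
  if (check && !placement_polygon_legal(state, poly)) {
    stop("illegal placement: ", kind, " at grid ", grid_loc, " rotation ", rotation)
  }
  state$placed[[length(state$placed) + 1L]] <- list(
    kind = kind, instance_id = as.integer(instance_id),
    grid_loc = as.integer(grid_loc), rotation = as.integer(rotation %% 360),
    mirrored = isTRUE(mirrored), polygon = poly)
  state$step <- state$step + 1L
  state
}

#' Remove a placed tan from the board
#'
#' @param state A `puzzle_state`.
#' @param kind,grid_loc,rotation Identify the placement to remove (the most
#'   recently placed match, if the two same-kind instances coincide).
#' @return The updated state.
#' @export
remove_tan <- function(state, kind, grid_loc, rotation) {
  rotation <- rotation %% 360
  hits <- which(vapply(state$placed, function(p)
    p$kind == kind && p$grid_loc == grid_loc && p$rotation == rotation, logical(1)))
  if (length(hits) == 0) {
    stop("cannot remove: no placed ", kind, " at grid ", grid_loc,
         " rotation ", rotation)
  }
  state$placed[[max(hits)]] <- NULL
  state$step <- state$step + 1L
  state
}

#' Canonical state signature
#'
#' The sorted list of (kind, grid_loc, rotation) triples of the placed tans;
#' placement order and the identity of same-kind instances do not matter.
#'
#' @param state A `puzzle_state`.
#' @return Character scalar (empty string for the empty state).
#' @export
state_signature <- function(state) {
  if (length(state$placed) == 0) return("")
  keys <- vapply(state$placed, function(p)
    paste(p$kind, p$grid_loc, p$rotation, sep = ":"), character(1))
  paste(sort(keys), collapse = "|")
}

#' @export
print.puzzle_state <- function(x, ...) {
  cat("Puzzle state (", x$puzzle$name, "): ", length(x$placed), " placed, step ",
      x$step, ", uncovered ", format(uncovered_area(x)), "\n", sep = "")
  invisible(x)
}
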