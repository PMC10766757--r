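# Shared fixtures and independent oracles, built in code at test time.

fixture_env <- new.env()

# canonical solution state, optionally leaving one solution row out
h_solution_state <- function(puzzle, skip_row = NULL) {
  st <- new_puzzle_state(puzzle)
  for (i in seq_len(nrow(puzzle$solution))) {
    if (!is.null(skip_row) && i == skip_row) next
    s <- puzzle$solution[i, ]
    st <- place_tan(st, s$kind, s$grid_loc, s$rotation, s$mirrored)
  }
  st
}

# random partial state with k legal placements (uses the current RNG stream)
h_random_state <- function(puzzle, k) {
  st <- new_puzzle_state(puzzle)
  for (i in seq_len(k)) {
    kinds <- Filter(function(kk) length(ctsolver:::free_instances(st, kk)) > 0,
                    tan_kinds())
    kind <- sample(kinds, 1)
    lp <- legal_placements(st, kind)
    if (nrow(lp) == 0) next
    p <- lp[sample.int(nrow(lp), 1), ]
    st <- place_tan(st, p$kind, p$grid_loc, p$rotation, p$mirrored)
  }
  st
}

# cached noise-free canonical trial (expensive; reused across tests)
h_canonical_trial <- function(name, variant = "frequency") {
  key <- paste0("trial_", name, "_", variant)
  if (is.null(fixture_env[[key]])) {
    pz <- tangram_puzzle(name)
    fixture_env[[key]] <- run_trial(pz, variant_params(variant, noise_s = 0),
                                    canonical_frequency_table(pz), seed = 1)
  }
  fixture_env[[key]]
}

# ---- independent polygon-containment backend (no clipping) ----------------
# a convex piece lies inside the simple target iff no piece edge properly
# crosses a target edge and a dense set of piece points is inside the target

h_segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  o1 * o2 < 0 && o3 * o4 < 0
}

h_indep_contained <- function(piece, target) {
  n <- nrow(piece); m <- nrow(target)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (h_segments_cross(piece[i, ], piece[if (i == n) 1 else i + 1, ],
                           target[j, ], target[if (j == m) 1 else j + 1, ])) {
        return(FALSE)
      }
    }
  }
  # vertices, edge mid/quarter points, centroid
  pts <- piece
  nx <- piece[c(2:n, 1), , drop = FALSE]
  for (tfrac in c(0.25, 0.5, 0.75)) pts <- rbind(pts, piece + tfrac * (nx - piece))
  pts <- rbind(pts, colMeans(piece))
  all(ctsolver:::points_in_poly(pts[, 1], pts[, 2], target, tol = 1e-7))
}

h_indep_empty_enumeration <- function(puzzle, kind) {
  grid <- puzzle$grid
  hits <- 0L
  for (gi in grid$index) {
    for (rot in seq(0, 315, by = 45)) {
      mirrors <- if (kind == "parallelogram") c(FALSE, TRUE) else FALSE
      for (mir in mirrors) {
        poly <- transform_tan(kind, rot, c(grid$x[gi], grid$y[gi]), mir)
        if (h_indep_contained(poly, puzzle$target)) hits <- hits + 1L
      }
    }
  }
  hits
}

# cached noisy trial (seeded), reused by cap and reproducibility checks
h_noisy_trial <- function(name, variant = "balanced", seed = 5) {
  key <- paste0("noisy_", name, "_", variant, "_", seed)
  if (is.null(fixture_env[[key]])) {
    pz <- tangram_puzzle(name)
    fixture_env[[key]] <- run_trial(pz, variant_params(variant, noise_s = 0.25),
                                    canonical_frequency_table(pz), seed = seed,
                                    max_steps = 30)
  }
  fixture_env[[key]]
}
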