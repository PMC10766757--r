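# Behavioral traces: data model, CSV readers/writers, phase-conditioned
# frequency tables, per-step choice heatmaps, and the synthetic participant
# generator that stands in for study data.
#
# A cohort of traces is a single data.frame with columns
#   participant_id, step, action (place|remove), kind, grid_loc, rotation, mirror
# steps are 1-based and consecutive within a participant; rotation is in
# degrees.

TRACE_COLUMNS <- c("participant_id", "step", "action", "kind", "grid_loc",
                   "rotation", "mirror")

#' Split a cohort data.frame into per-participant traces
#' @param traces Cohort data.frame.
#' @return Named list of data.frames, in order of first appearance.
#' @export
split_traces <- function(traces) {
  ids <- unique(traces$participant_id)
  stats::setNames(lapply(ids, function(i)
    traces[traces$participant_id == i, , drop = FALSE]), as.character(ids))
}

#' Structural validation of a trace cohort
#'
#' Checks the schema, that steps run consecutively from 1 within each
#' participant, and that every remove refers to a currently-placed
#' (kind, grid_loc, rotation).
#'
#' @param traces Cohort data.frame.
#' @return Invisibly TRUE; stops with a descriptive error otherwise.
#' @export
validate_traces <- function(traces) {
  miss <- setdiff(TRACE_COLUMNS, names(traces))
  if (length(miss)) stop("trace schema violation: missing columns ",
                         paste(miss, collapse = ", "))
  bad <- !traces$action %in% c("place", "remove")
  if (any(bad)) stop("trace validation error: unknown action at row ", which(bad)[1])
  for (tr in split_traces(traces)) {
    if (!identical(as.integer(tr$step), seq_len(nrow(tr)))) {
      stop("trace validation error: steps not consecutive from 1 for participant ",
           tr$participant_id[1])
    }
    board <- character(0)
    for (i in seq_len(nrow(tr))) {
      key <- paste(tr$kind[i], tr$grid_loc[i], tr$rotation[i])
      if (tr$action[i] == "place") {
        board <- c(board, key)
      } else {
        hit <- match(key, board)
        if (is.na(hit)) {
          stop("trace validation error: remove of never-placed piece (participant ",
               tr$participant_id[1], ", step ", tr$step[i], ")")
        }
        board <- board[-hit]
      }
    }
  }
  invisible(TRUE)
}

#' Read traces from CSV
#'
#' @param path CSV file with the trace schema (see [write_traces()]).
#' @param validate Run [validate_traces()] (default TRUE).
#' @return Cohort data.frame (0 rows for an empty file).
#' @export
read_traces <- function(path, validate = TRUE) {
  tr <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(tr) || nrow(tr) == 0) {
    return(data.frame(participant_id = character(0), step = integer(0),
                      action = character(0), kind = character(0),
                      grid_loc = integer(0), rotation = integer(0),
                      mirror = logical(0)))
  }
  miss <- setdiff(TRACE_COLUMNS, names(tr))
  if (length(miss)) stop("parse error in ", path, ": missing columns ",
                         paste(miss, collapse = ", "))
  tr$step <- as.integer(tr$step)
  tr$grid_loc <- as.integer(tr$grid_loc)
  tr$rotation <- as.integer(tr$rotation)
  tr$mirror <- as.logical(tr$mirror)
  if (validate) validate_traces(tr)
  tr
}

#' Write traces to CSV
#' @param traces Cohort data.frame.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces[, TRACE_COLUMNS, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Replay a single trace on a puzzle
#'
#' @param trace Single-participant data.frame.
#' @param puzzle A [tangram_puzzle()].
#' @param signatures Also return the state signature after every step.
#' @return The final `puzzle_state`, with attribute `signatures` (character
#'   vector, one per step) when requested.  Stops with a replay error naming
#'   the offending step if an action is illegal.
#' @export
replay_trace <- function(trace, puzzle, signatures = FALSE) {
  state <- new_puzzle_state(puzzle)
  sigs <- character(nrow(trace))
  for (i in seq_len(nrow(trace))) {
    state <- tryCatch({
      if (trace$action[i] == "place") {
        place_tan(state, trace$kind[i], trace$grid_loc[i], trace$rotation[i],
                  isTRUE(trace$mirror[i]))
      } else {
        remove_tan(state, trace$kind[i], trace$grid_loc[i], trace$rotation[i])
      }
    }, error = function(e) {
      stop("replay error at step ", i, " (participant ", trace$participant_id[1],
           "): ", conditionMessage(e))
    })
    if (signatures) sigs[i] <- state_signature(state)
  }
  if (signatures) attr(state, "signatures") <- sigs
  state
}

#' Phase index of a step
#' @param step Step index (1-based).
#' @param phase_bins Upper edges of phases 1..k-1 (default `c(4, 12)`:
#'   phase 1 = steps 1-4, phase 2 = 5-12, phase 3 = later).
#' @return Integer phase index.
#' @export
phase_of_step <- function(step, phase_bins = c(4, 12)) {
  findInterval(step - 1e-9, phase_bins) + 1L
}

#' Build a phase-conditioned action frequency table
#'
#' Counts place actions per (kind, grid_loc, rotation) within each solution
#' phase and normalizes each phase to sum 1.
#'
#' @param traces Cohort data.frame.
#' @param phase_bins See [phase_of_step()].
#' @return Object of class `cts_freq_table`: data.frame with columns `kind`,
#'   `grid_loc`, `rotation`, `phase`, `f`; attribute `phase_bins`.
#' @export
build_frequency_table <- function(traces, phase_bins = c(4, 12)) {
  pl <- traces[traces$action == "place", , drop = FALSE]
  if (nrow(pl) == 0) {
    ft <- data.frame(kind = character(0), grid_loc = integer(0),
                     rotation = integer(0), phase = integer(0), f = numeric(0))
  } else {
    phase <- phase_of_step(pl$step, phase_bins)
    key <- paste(pl$kind, pl$grid_loc, pl$rotation, phase, sep = "\r")
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    ft <- data.frame(kind = parts[, 1], grid_loc = as.integer(parts[, 2]),
                     rotation = as.integer(parts[, 3]),
                     phase = as.integer(parts[, 4]), f = as.numeric(cnt),
                     stringsAsFactors = FALSE)
    for (ph in unique(ft$phase)) {
      sel <- ft$phase == ph
      ft$f[sel] <- ft$f[sel] / sum(ft$f[sel])
    }
    ft <- ft[order(ft$phase, ft$kind, ft$grid_loc, ft$rotation), ]
    rownames(ft) <- NULL
  }
  structure(ft, phase_bins = phase_bins, class = c("cts_freq_table", "data.frame"))
}

#' Look up phase-conditioned frequencies
#'
#' @param freqs A `cts_freq_table`.
#' @param kind,grid_loc,rotation Vectors identifying placements.
#' @param phase Phase index (scalar).
#' @return Numeric vector of relative frequencies (0 where absent).
#' @export
freq_lookup <- function(freqs, kind, grid_loc, rotation, phase) {
  if (is.null(freqs) || nrow(freqs) == 0) return(rep(0, length(kind)))
  key <- paste(kind, grid_loc, rotation %% 360, phase)
  tab <- paste(freqs$kind, freqs$grid_loc, freqs$rotation %% 360, freqs$phase)
  f <- freqs$f[match(key, tab)]
  f[is.na(f)] <- 0
  f
}

#' Frequency table concentrated on a puzzle's canonical solution
#'
#' Each of the 7 canonical placements gets equal frequency 1/7 in every
#' phase; all other actions have frequency zero.
#'
#' @param puzzle A [tangram_puzzle()].
#' @param phases Phase indices to populate (default 1:3).
#' @return A `cts_freq_table`.
#' @export
canonical_frequency_table <- function(puzzle, phases = 1:3) {
  sol <- puzzle$solution
  ft <- do.call(rbind, lapply(phases, function(ph) {
    data.frame(kind = sol$kind, grid_loc = sol$grid_loc, rotation = sol$rotation,
               phase = as.integer(ph), f = 1 / nrow(sol), stringsAsFactors = FALSE)
  }))
  structure(ft, phase_bins = c(4, 12), class = c("cts_freq_table", "data.frame"))
}

#' Transcribed study frequencies for the Monk big triangle (initial phase)
#'
#' Loads the bundled transcription of published big-triangle action
#' frequencies for the Monk puzzle's initial phase, together with the
#' package-defined (synthetic) mapping of the original grid numbering onto
#' this package's anchor grid.
#'
#' @param as_freq_table Return a phase-1 `cts_freq_table` mapped onto the
#'   package grid (default); otherwise the raw transcription data.frame.
#' @return A `cts_freq_table` or the raw transcription (`grid_value`,
#'   `rotation`, `choice_pct`).
#' @export
monk_table1 <- function(as_freq_table = TRUE) {
  raw <- utils::read.csv(system.file("extdata", "monk_table1.csv",
                                     package = "ctsolver"), comment.char = "#")
  if (!as_freq_table) return(raw)
  map <- utils::read.csv(system.file("extdata", "monk_table1_grid_map.csv",
                                     package = "ctsolver"), comment.char = "#")
  loc <- map$package_grid[match(raw$grid_value, map$study_grid)]
  ft <- data.frame(kind = "big_triangle", grid_loc = as.integer(loc),
                   rotation = as.integer(raw$rotation), phase = 1L,
                   f = raw$choice_pct / 100, stringsAsFactors = FALSE)
  structure(ft, phase_bins = c(4, 12), class = c("cts_freq_table", "data.frame"))
}

#' Per-step piece-choice heatmap
#'
#' `h[p, s]` is the fraction of traces whose s-th place action uses piece
#' kind p, among traces with at least s place actions; populated columns sum
#' to 1.
#'
#' @param traces Cohort data.frame.
#' @return Object of class `cts_heatmap`: a 5 x S matrix (rows in
#'   [tan_kinds()] order).
#' @export
build_heatmap <- function(traces) {
  kinds <- tan_kinds()
  per <- split_traces(traces)
  place_kinds <- lapply(per, function(tr) tr$kind[tr$action == "place"])
  S <- max(c(0L, lengths(place_kinds)))
  h <- matrix(0, nrow = length(kinds), ncol = S,
              dimnames = list(kinds, if (S) paste0("step", seq_len(S)) else NULL))
  for (s in seq_len(S)) {
    at <- vapply(place_kinds, function(k) if (length(k) >= s) k[s] else NA_character_,
                 character(1))
    at <- at[!is.na(at)]
    if (length(at)) h[, s] <- tabulate(factor(at, levels = kinds),
                                       nbins = length(kinds)) / length(at)
  }
  structure(h, class = c("cts_heatmap", class(h)))
}

#' Synthetic participant parameters
#'
#' Defaults follow observed training statistics for the bundled puzzles:
#' perfect-solution ratio 0.43 (House) / 0.27 (Monk); the composition-error
#' probability and exploration rate are package choices emulating the
#' reported right-skewed step counts.
#'
#' @param puzzle A [tangram_puzzle()] or its name.
#' @param p_perfect Probability of a minimal 7-step solution.
#' @param p_composition_error Probability that a non-perfect trace opens with
#'   the modal unrecognized-composition error.
#' @param exploration_geometric_rate Success rate of the geometric number of
#'   exploration actions.
#' @return List of class `synth_params`.
#' @export
synth_params <- function(puzzle, p_perfect = NULL, p_composition_error = NULL,
                         exploration_geometric_rate = 0.3) {
  name <- if (inherits(puzzle, "tangram_puzzle")) puzzle$name else puzzle
  defaults <- list(house = c(0.43, 0.5), monk = c(0.27, 0.65))[[name]]
  if (is.null(p_perfect)) p_perfect <- defaults[1]
  if (is.null(p_composition_error)) p_composition_error <- defaults[2]
  stopifnot(p_perfect >= 0, p_perfect <= 1,
            p_composition_error >= 0, p_composition_error <= 1,
            exploration_geometric_rate > 0, exploration_geometric_rate <= 1)
  structure(list(p_perfect = p_perfect, p_composition_error = p_composition_error,
                 exploration_geometric_rate = exploration_geometric_rate),
            class = "synth_params")
}

#' @keywords internal
.best_fit_order <- function(puzzle) {
  # canonical placements, largest pieces first, random shuffle within equal areas
  sol <- puzzle$solution
  area <- c(big_triangle = 2, mid_triangle = 1, square = 1, parallelogram = 1,
            small_triangle = 0.5)[sol$kind]
  sol[order(-area, stats::runif(nrow(sol))), , drop = FALSE]
}

#' Generate synthetic participant traces
#'
#' Emulates the three-phase structure of observed solutions: a best-fit
#' opening, an exploration phase with an optional modal
#' unrecognized-composition error, random legal placements and removals, and
#' a best-fit final phase completing the canonical solution.  With
#' probability `p_perfect` a trace is a minimal 7-step solution.  Every
#' generated trace replays legally.
#'
#' @param puzzle A [tangram_puzzle()].
#' @param sp A [synth_params()] object.
#' @param n Number of traces.
#' @param seed Optional RNG seed.
#' @param id_prefix Participant id prefix.
#' @return Cohort data.frame.
#' @export
synth_participants <- function(puzzle, sp = synth_params(puzzle), n = 30,
                               seed = NULL, id_prefix = "synth") {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    steps <- .synth_one(puzzle, sp)
    steps$participant_id <- sprintf("%s_%03d", id_prefix, i)
    steps$step <- seq_len(nrow(steps))
    out[[i]] <- steps[, TRACE_COLUMNS]
  }
  do.call(rbind, out)
}

#' @keywords internal
.synth_one <- function(puzzle, sp) {
  rec <- function(action, kind, grid_loc, rotation, mirrored) {
    data.frame(participant_id = "", step = 0L, action = action, kind = kind,
               grid_loc = as.integer(grid_loc), rotation = as.integer(rotation),
               mirror = isTRUE(mirrored), stringsAsFactors = FALSE)
  }
  state <- new_puzzle_state(puzzle)
  rows <- list()
  push_place <- function(k, g, r, m) {
    state <<- place_tan(state, k, g, r, m)
    rows[[length(rows) + 1L]] <<- rec("place", k, g, r, m)
  }
  push_remove <- function(k, g, r) {
    state <<- remove_tan(state, k, g, r)
    rows[[length(rows) + 1L]] <<- rec("remove", k, g, r, FALSE)
  }
  order_all <- .best_fit_order(puzzle)
  if (stats::runif(1) < sp$p_perfect) {
    for (j in seq_len(nrow(order_all))) {
      s <- order_all[j, ]
      push_place(s$kind, s$grid_loc, s$rotation, s$mirrored)
    }
    return(do.call(rbind, rows))
  }
  canon_key <- paste(puzzle$solution$kind, puzzle$solution$grid_loc,
                     puzzle$solution$rotation)
  is_canon <- function(p) paste(p$kind, p$grid_loc, p$rotation) %in% canon_key
  # best-fit opening, possibly the modal composition error
  if (stats::runif(1) < sp$p_composition_error) {
    me <- puzzle$modal_error
    push_place(me$kind, me$grid_loc, me$rotation, me$mirrored)
  } else {
    s <- order_all[1, ]
    push_place(s$kind, s$grid_loc, s$rotation, s$mirrored)
  }
  # exploration: random legal placements and removals
  L <- min(stats::rgeom(1, sp$exploration_geometric_rate), 20L)
  for (t in seq_len(L)) {
    do_remove <- length(state$placed) > 0 && stats::runif(1) < 0.35
    if (!do_remove) {
      kinds <- Filter(function(k) length(free_instances(state, k)) > 0, tan_kinds())
      if (length(kinds) == 0) do_remove <- TRUE
      else {
        k <- sample(kinds, 1)
        lp <- legal_placements(state, k)
        if (nrow(lp) == 0) do_remove <- length(state$placed) > 0
        else {
          pick <- lp[sample.int(nrow(lp), 1), ]
          push_place(pick$kind, pick$grid_loc, pick$rotation, pick$mirrored)
          next
        }
      }
    }
    if (do_remove && length(state$placed) > 0) {
      p <- state$placed[[sample.int(length(state$placed), 1)]]
      push_remove(p$kind, p$grid_loc, p$rotation)
    }
  }
  # aha moment: clear every non-canonical piece, then best-fit completion
  repeat {
    bad <- Filter(Negate(is_canon), state$placed)
    if (length(bad) == 0) break
    push_remove(bad[[1]]$kind, bad[[1]]$grid_loc, bad[[1]]$rotation)
  }
  done <- vapply(state$placed, function(p) paste(p$kind, p$grid_loc, p$rotation),
                 character(1))
  for (j in seq_len(nrow(order_all))) {
    s <- order_all[j, ]
    if (paste(s$kind, s$grid_loc, s$rotation) %in% done) next
    push_place(s$kind, s$grid_loc, s$rotation, s$mirrored)
  }
  do.call(rbind, rows)
}
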