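# Coordinator loop: vision -> scoring -> decision -> state update, with the
# problem queue for unfeasible-region backtracking, batch experiments and
# next-step prediction by prefix replay.

#' @keywords internal
sim_init <- function(puzzle, params, freqs, resolution = 12, max_steps = 50L,
                     participant_id = "model") {
  ctx <- new.env(parent = emptyenv())
  ctx$puzzle <- puzzle
  ctx$params <- params
  ctx$freqs <- freqs
  ctx$resolution <- resolution
  ctx$max_steps <- as.integer(max_steps)
  ctx$participant_id <- participant_id
  ctx$state <- new_puzzle_state(puzzle)
  ctx$store <- new_declarative_store()
  ctx$bank <- build_templates(resolution)
  ctx$problem_queue <- list()
  ctx$unf_was <- FALSE
  ctx$trace <- list()
  ctx$diag <- list(max_context = 0L, max_per_template = 0L)
  ctx
}

#' @keywords internal
sim_phase <- function(ctx) {
  bins <- attr(ctx$freqs, "phase_bins")
  if (is.null(bins)) bins <- c(4, 12)
  phase_of_step(length(ctx$trace) + 1L, bins)
}

# note the current state's feasibility; on a fresh unfeasible flag the most
# recent placement is tagged as uncertain and queued for region backtracking
#' @keywords internal
sim_note_unfeasible <- function(ctx) {
  unf <- detect_unfeasible(ctx$state)
  if (unf$flag && !ctx$unf_was && length(ctx$state$placed) > 0) {
    last <- ctx$state$placed[[length(ctx$state$placed)]]
    key <- paste(last$kind, last$grid_loc, last$rotation)
    have <- vapply(ctx$problem_queue, function(q)
      paste(q$kind, q$grid_loc, q$rotation), character(1))
    if (!key %in% have) ctx$problem_queue <- c(ctx$problem_queue, list(last))
    ctx$state$problem_tags <- unique(c(ctx$state$problem_tags,
                                       length(ctx$state$placed)))
  }
  ctx$unf_was <- unf$flag
  unf
}

#' @keywords internal
sim_prepare <- function(ctx) {
  unf <- sim_note_unfeasible(ctx)
  phase <- sim_phase(ctx)
  options <- data.frame()
  if (!unf$flag) {
    cands <- extract_candidates(ctx$state, ctx$resolution, ctx$bank)
    mpt <- attr(cands, "max_per_template")
    if (!is.null(mpt)) ctx$diag$max_per_template <- max(ctx$diag$max_per_template, mpt)
    options <- filter_candidates(cands, ctx$state, ctx$freqs, phase,
                                 ctx$params$frequency_screen)
    options <- score_options(options, ctx$params)
    ctx$diag$max_context <- max(ctx$diag$max_context,
                                min(ctx$params$context_capacity, nrow(options)))
  }
  decide(ctx$state, options, ctx$params, ctx$store,
         stored_actions = ctx$state$placed, problem_queue = ctx$problem_queue,
         unfeasible = unf, freqs = ctx$freqs, phase = phase)
}

#' @keywords internal
sim_queue_drop <- function(ctx, kind, grid_loc, rotation) {
  keep <- vapply(ctx$problem_queue, function(q)
    !(q$kind == kind && q$grid_loc == grid_loc && q$rotation == rotation),
    logical(1))
  ctx$problem_queue <- ctx$problem_queue[keep]
}

#' @keywords internal
sim_apply <- function(ctx, decision) {
  p <- decision$payload
  if (decision$type == "place") {
    ctx$state <- place_tan(ctx$state, p$kind, p$grid_loc, p$rotation, p$mirrored)
    act <- "place"
  } else {
    ctx$state <- remove_tan(ctx$state, p$kind, p$grid_loc, p$rotation)
    sim_queue_drop(ctx, p$kind, p$grid_loc, p$rotation)
    act <- "remove"
  }
  ctx$trace[[length(ctx$trace) + 1L]] <- data.frame(
    participant_id = ctx$participant_id, step = length(ctx$trace) + 1L,
    action = act, kind = p$kind, grid_loc = as.integer(p$grid_loc),
    rotation = as.integer(p$rotation), mirror = isTRUE(p$mirrored),
    stringsAsFactors = FALSE)
  invisible(ctx)
}

#' @keywords internal
sim_trace_df <- function(ctx) {
  if (length(ctx$trace) == 0) {
    return(data.frame(participant_id = character(0), step = integer(0),
                      action = character(0), kind = character(0),
                      grid_loc = integer(0), rotation = integer(0),
                      mirror = logical(0)))
  }
  do.call(rbind, ctx$trace)
}

#' Run a single solver trial
#'
#' Iterates extract -> score -> decide -> apply until the puzzle is solved or
#' `max_steps` actions (placements and removals both count) have been taken.
#' A dead end (backtrack requested with nothing placed) aborts the trial,
#' which is then recorded as unsolved.
#'
#' @param puzzle A [tangram_puzzle()].
#' @param params A [variant_params()] object.
#' @param freqs A `cts_freq_table` of training frequencies.
#' @param seed RNG seed (drives the activation noise).
#' @param max_steps Step budget (default 50).
#' @param resolution Vision resolution in px/unit.
#' @param participant_id Id written into the emitted trace.
#' @return Object of class `cts_trial`: list with `trace` (data.frame),
#'   `solved`, `n_steps`, `seed`, `final_state`, `diagnostics`.
#' @export
run_trial <- function(puzzle, params = variant_params(), freqs, seed = 1L,
                      max_steps = 50L, resolution = 12,
                      participant_id = sprintf("model_%d", seed)) {
  set.seed(seed)
  ctx <- sim_init(puzzle, params, freqs, resolution, max_steps, participant_id)
  dead_end <- FALSE
  while (length(ctx$trace) < max_steps && !is_state_solved(ctx$state)) {
    decision <- tryCatch(sim_prepare(ctx), error = function(e) {
      if (grepl("dead end", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(decision)) { dead_end <- TRUE; break }
    sim_apply(ctx, decision)
  }
  structure(list(trace = sim_trace_df(ctx), solved = is_state_solved(ctx$state),
                 n_steps = length(ctx$trace), seed = seed,
                 final_state = ctx$state, dead_end = dead_end,
                 diagnostics = ctx$diag), class = "cts_trial")
}

#' @export
print.cts_trial <- function(x, ...) {
  cat("CTS trial (seed ", x$seed, "): ", x$n_steps, " steps, ",
      if (x$solved) "solved" else "unsolved", "\n", sep = "")
  invisible(x)
}

#' Run a batch of independent trials
#'
#' @param puzzle,params,freqs,max_steps,resolution As in [run_trial()].
#' @param n_runs Number of trials (the study aggregated 30 model runs).
#' @param base_seed Seeds `base_seed .. base_seed + n_runs - 1` are used.
#' @return List of `cts_trial` objects.
#' @export
run_batch <- function(puzzle, params = variant_params(), freqs, n_runs = 30L,
                      base_seed = 1L, max_steps = 50L, resolution = 12) {
  lapply(seq_len(n_runs), function(i) {
    run_trial(puzzle, params, freqs, seed = as.integer(base_seed + i - 1L),
              max_steps = max_steps, resolution = resolution)
  })
}

#' Combine batch results into a trace cohort
#' @param trials List of `cts_trial` objects.
#' @return Cohort data.frame.
#' @export
batch_traces <- function(trials) {
  do.call(rbind, lapply(trials, `[[`, "trace"))
}

#' Predict the next action after a trace prefix
#'
#' Replays the prefix onto a fresh state — reconstructing the simulator's
#' bookkeeping: each replayed placement enters the recently-retrieved record
#' exactly as a retrieval would, and unfeasible-region tagging is re-derived
#' from the replayed states — then returns the model's chosen next action
#' without committing it.  With noise off this reproduces the simulator's
#' own choice at every prefix of a model-generated trace.
#'
#' @param trace_prefix Single-participant data.frame of already-taken steps
#'   (may have 0 rows).
#' @param puzzle,params,freqs,resolution As in [run_trial()].
#' @param seed RNG seed for the noisy prediction draw.
#' @return One-row data.frame: `action` (place/remove), `kind`, `grid_loc`,
#'   `rotation`, `mirror`, `type` (decision type).
#' @export
predict_next <- function(trace_prefix, puzzle, params = variant_params(), freqs,
                         seed = 1L, resolution = 12) {
  set.seed(seed)
  ctx <- sim_init(puzzle, params, freqs, resolution, participant_id = "predict")
  for (i in seq_len(nrow(trace_prefix))) {
    sim_note_unfeasible(ctx)
    row <- trace_prefix[i, ]
    ok <- tryCatch({
      if (row$action == "place") {
        ctx$state <- place_tan(ctx$state, row$kind, row$grid_loc, row$rotation,
                               isTRUE(row$mirror))
        chunk <- paste(row$kind, row$grid_loc, row$rotation %% 360,
                       isTRUE(row$mirror), sep = ":")
        ctx$store$recently_retrieved <-
          utils::tail(c(ctx$store$recently_retrieved, chunk), params$finst_span)
      } else {
        ctx$state <- remove_tan(ctx$state, row$kind, row$grid_loc, row$rotation)
        sim_queue_drop(ctx, row$kind, row$grid_loc, row$rotation)
      }
      TRUE
    }, error = function(e) {
      stop("replay error at prefix step ", i, ": ", conditionMessage(e))
    })
    ctx$trace[[length(ctx$trace) + 1L]] <- row  # step counter for phases
  }
  decision <- sim_prepare(ctx)
  p <- decision$payload
  data.frame(action = if (decision$type == "place") "place" else "remove",
             kind = p$kind, grid_loc = as.integer(p$grid_loc),
             rotation = as.integer(p$rotation), mirror = isTRUE(p$mirrored),
             type = decision$type, stringsAsFactors = FALSE)
}
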