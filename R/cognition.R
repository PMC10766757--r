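# Cognitive model: action-option scoring, the limited-capacity context
# buffer, activation-based retrieval with logistic noise and a
# recently-retrieved (finst) exclusion, and the decision rule with its two
# backtracking strategies.

#' Parameters of a solver variant
#'
#' Three variants differ in how an action-option's strength combines the
#' phase-conditioned behavioural frequency `f` and the visual similarity `s`:
#' * `vision`: strength = k_d*f + k_cv*s with a high vision weight,
#' * `frequency`: the same linear form with a high data weight,
#' * `balanced`: the frequency of choice is penalized by the size of the
#'   template-matching error, strength = f * (1 - lambda*(1 - s)).
#'
#' @param name Variant name.
#' @param k_d Data (frequency) weight, >= 0.
#' @param k_cv Vision (similarity) weight, >= 0.
#' @param lambda Error-penalty scale of the balanced variant, in `[0, 1]`.
#' @param noise_s Scale of the logistic activation noise (0 disables noise).
#' @param tau Retrieval threshold.
#' @param context_capacity Context buffer capacity (default 6, near the
#'   7 +/- 2 span of visual working memory).
#' @param spreading_W Total source activation spread from the context buffer.
#' @param finst_span How many recent retrievals stay excluded.
#' @param frequency_screen Drop candidates unseen in the training phase.
#' @return List of class `variant_params`.
#' @export
variant_params <- function(name = c("balanced", "vision", "frequency"),
                           k_d = NULL, k_cv = NULL, lambda = 0.5,
                           noise_s = 0.25, tau = 0, context_capacity = 6L,
                           spreading_W = 1, finst_span = 4L,
                           frequency_screen = NULL) {
  name <- match.arg(name)
  defaults <- list(vision = c(0.2, 0.8), frequency = c(0.8, 0.2),
                   balanced = c(0.5, 0.5))[[name]]
  if (is.null(k_d)) k_d <- defaults[1]
  if (is.null(k_cv)) k_cv <- defaults[2]
  if (k_d < 0 || k_cv < 0) stop("invalid parameter: weights must be non-negative")
  if (k_d + k_cv <= 0) stop("invalid parameter: k_d + k_cv must be positive")
  if (context_capacity < 1) stop("context_capacity must be at least 1")
  if (is.null(frequency_screen)) frequency_screen <- name != "vision"
  structure(list(name = name, k_d = k_d, k_cv = k_cv, lambda = lambda,
                 noise_s = noise_s, tau = tau,
                 context_capacity = as.integer(context_capacity),
                 spreading_W = spreading_W, finst_span = as.integer(finst_span),
                 frequency_screen = frequency_screen),
            class = "variant_params")
}

#' Read variant parameters from a YAML config
#' @param path YAML file whose keys match [variant_params()] arguments.
#' @return A `variant_params` object.
#' @export
read_variant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(variant_params, cfg)
}

#' Action-option strength
#'
#' The linear combination `k_d*f + k_cv*s` for the vision and frequency
#' variants; the balanced variant penalizes the frequency by the template
#' matching error, `f * (1 - lambda*(1 - s))`.
#'
#' @param f Phase-conditioned relative frequency in `[0, 1]`.
#' @param s Visual similarity in `[0, 1]`.
#' @param params A [variant_params()] object.
#' @return Numeric strength (vectorized).
#' @export
compute_strength <- function(f, s, params) {
  if (any(f < -1e-9 | f > 1 + 1e-9) || any(s < -1e-9 | s > 1 + 1e-9)) {
    stop("f and s must lie in [0, 1]")
  }
  if (params$name == "balanced") {
    f * (1 - params$lambda * (1 - s))
  } else {
    params$k_d * f + params$k_cv * s
  }
}

#' Score a set of action-options
#' @param options Action-option data.frame (from [filter_candidates()]).
#' @param params A `variant_params` object.
#' @return The options with the `strength` column filled in.
#' @export
score_options <- function(options, params) {
  options$strength <- if (nrow(options)) compute_strength(options$f, options$s, params)
                      else numeric(0)
  options
}

#' @keywords internal
option_chunk_id <- function(options) {
  paste(options$kind, options$grid_loc, options$rotation, options$mirrored,
        sep = ":")
}

#' Fill the context buffer with the strongest action-options
#'
#' Keeps the `capacity` options with highest strength; ties broken by higher
#' frequency, then lower grid location, then lower rotation.
#'
#' @param options Scored action-option data.frame.
#' @param capacity Buffer capacity (default 6).
#' @return The selected options, strongest first.
#' @export
build_context <- function(options, capacity = 6L) {
  if (nrow(options) == 0) return(options)
  ord <- order(-options$strength, -options$f, options$grid_loc, options$rotation)
  out <- options[ord, , drop = FALSE][seq_len(min(capacity, nrow(options))), ,
                                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Create an empty declarative store
#'
#' Holds the current action-option chunks plus the persistent
#' recently-retrieved (finst) record.
#' @return Environment of class `declarative_store`.
#' @export
new_declarative_store <- function() {
  st <- new.env(parent = emptyenv())
  st$chunks <- NULL             # scored action-option data.frame
  st$recently_retrieved <- character(0)
  class(st) <- "declarative_store"
  st
}

#' Load action-option chunks into the store
#'
#' Replaces the option chunks (one step's extraction); duplicates by
#' (kind, grid_loc, rotation, mirror) are collapsed keeping the stronger.
#' The recently-retrieved record persists across loads.
#'
#' @param store A `declarative_store`.
#' @param options Scored action-option data.frame.
#' @return Invisibly the store.
#' @export
store_load_options <- function(store, options) {
  if (nrow(options)) {
    ids <- option_chunk_id(options)
    ord <- order(ids, -options$strength)
    options <- options[ord, , drop = FALSE]
    options <- options[!duplicated(option_chunk_id(options)), , drop = FALSE]
    rownames(options) <- NULL
  }
  store$chunks <- options
  invisible(store)
}

#' Activation of a chunk
#'
#' `A = B + S + eps`: base-level activation `B` is the option's strength;
#' spreading activation `S` is `spreading_W / |context|` for every context
#' entry matching the chunk; `eps` is logistic noise with scale `noise_s`
#' drawn from the current RNG stream.
#'
#' @param chunk One-row action-option data.frame.
#' @param context Context buffer (from [build_context()]).
#' @param params A `variant_params` object.
#' @return Numeric activation.
#' @export
activation <- function(chunk, context, params) {
  B <- chunk$strength
  S <- 0
  if (nrow(context) > 0) {
    Wj <- params$spreading_W / nrow(context)
    S <- Wj * sum(option_chunk_id(context) == option_chunk_id(chunk))
  }
  eps <- if (params$noise_s > 0) stats::rlogis(1, 0, params$noise_s) else 0
  B + S + eps
}

#' Retrieve the most active chunk
#'
#' Considers chunks not in the recently-retrieved record, computes noisy
#' activations, and returns the most active one if it exceeds the retrieval
#' threshold; otherwise a retrieval failure.  A successful retrieval is
#' appended to the recently-retrieved record (oldest entries evicted beyond
#' `finst_span`).
#'
#' @param store A `declarative_store`.
#' @param context Context buffer.
#' @param params A `variant_params` object.
#' @return The retrieved one-row option data.frame, or NULL on retrieval
#'   failure.
#' @export
retrieve <- function(store, context, params) {
  chunks <- store$chunks
  if (is.null(chunks) || nrow(chunks) == 0) return(NULL)
  ids <- option_chunk_id(chunks)
  avail <- !ids %in% store$recently_retrieved
  if (!any(avail)) return(NULL)
  chunks <- chunks[avail, , drop = FALSE]
  ids <- ids[avail]
  act <- vapply(seq_len(nrow(chunks)), function(i)
    activation(chunks[i, , drop = FALSE], context, params), numeric(1))
  best <- which.max(act)
  if (act[best] <= params$tau) return(NULL)
  store$recently_retrieved <- utils::tail(c(store$recently_retrieved, ids[best]),
                                          params$finst_span)
  out <- chunks[best, , drop = FALSE]
  out$activation <- act[best]
  rownames(out) <- NULL
  out
}

#' Choose the placement to remove under piece backtracking
#'
#' The placed action whose (kind, grid_loc, rotation) has the minimum
#' phase-conditioned frequency in the training data; ties go to the most
#' recently placed action.
#'
#' @param stored_actions List of placements in play order (each with `kind`,
#'   `grid_loc`, `rotation`).
#' @param freqs A `cts_freq_table` (may be NULL: all frequencies 0).
#' @param phase Phase index for the lookup.
#' @return The selected placement (list).
#' @export
piece_backtrack_target <- function(stored_actions, freqs, phase = 1L) {
  if (length(stored_actions) == 0) stop("dead end: no placed action to backtrack")
  f <- freq_lookup(freqs,
                   vapply(stored_actions, `[[`, character(1), "kind"),
                   vapply(stored_actions, `[[`, numeric(1), "grid_loc"),
                   vapply(stored_actions, `[[`, numeric(1), "rotation"),
                   phase)
  cand <- which(f <= min(f) + 1e-12)
  stored_actions[[max(cand)]]
}

#' Next removal under unfeasible-region backtracking
#'
#' Problem placements are removed in the order they were noticed
#' (queue-based); when the queue is exhausted while the state is still
#' unfeasible, the caller falls through to piece backtracking.
#'
#' @param state A `puzzle_state` (flagged unfeasible).
#' @param problem_queue List of tagged placements in notice order.
#' @return The head of the queue, or NULL when the queue is empty.
#' @export
region_backtrack_step <- function(state, problem_queue) {
  if (length(problem_queue) == 0) return(NULL)
  problem_queue[[1]]
}

#' Decide the next action
#'
#' If the state is flagged unfeasible an unfeasible-region chunk preempts
#' retrieval and the decision is a region backtrack (head of the problem
#' queue; piece backtrack when the queue is empty).  Otherwise a successful
#' retrieval places the retrieved option, and a retrieval failure triggers a
#' piece backtrack of the lowest-frequency placed action.
#'
#' @param state A `puzzle_state`.
#' @param options Scored action-option data.frame.
#' @param params A `variant_params` object.
#' @param store A `declarative_store`.
#' @param stored_actions Placements in play order.
#' @param problem_queue Tagged problem placements in notice order.
#' @param unfeasible Result of [detect_unfeasible()] for `state`.
#' @param freqs A `cts_freq_table` for the piece-backtrack lookup.
#' @param phase Current phase index.
#' @return List of class `cts_decision`: `type` in
#'   `place | region_backtrack | piece_backtrack`, and `payload` (the option
#'   to place or the placement to remove).
#' @export
decide <- function(state, options, params, store, stored_actions,
                   problem_queue = list(), unfeasible = NULL, freqs = NULL,
                   phase = 1L) {
  if (is.null(unfeasible)) unfeasible <- detect_unfeasible(state)
  mk <- function(type, payload) structure(list(type = type, payload = payload),
                                          class = "cts_decision")
  if (isTRUE(unfeasible$flag)) {
    head <- region_backtrack_step(state, problem_queue)
    if (!is.null(head)) return(mk("region_backtrack", head))
    # queue exhausted but still unfeasible: combine with piece backtracking
    return(mk("piece_backtrack",
              piece_backtrack_target(stored_actions, freqs, phase)))
  }
  store_load_options(store, options)
  context <- build_context(options, params$context_capacity)
  got <- retrieve(store, context, params)
  if (!is.null(got)) return(mk("place", got))
  mk("piece_backtrack", piece_backtrack_target(stored_actions, freqs, phase))
}
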