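# Evaluation: overall step statistics, per-step heatmap RMSE, step-by-step
# state plausibility, and windowed next-action prediction accuracy.

#' Overall step statistics of a trace cohort
#'
#' @param traces Cohort data.frame.
#' @param puzzle Optional [tangram_puzzle()]; when supplied, each trace is
#'   replayed to determine whether it ends solved (otherwise traces are
#'   assumed solved, as generator cohorts are by construction).
#' @return List: `mean`, `sd` (sample SD of per-trace step counts),
#'   `perfect_ratio` (fraction of solved traces with exactly 7 steps),
#'   `n_steps` (per-trace counts).
#' @export
overall_stats <- function(traces, puzzle = NULL) {
  per <- split_traces(traces)
  if (length(per) == 0) stop("overall_stats: empty trace cohort")
  n_steps <- vapply(per, nrow, integer(1))
  solved <- if (is.null(puzzle)) rep(TRUE, length(per)) else
    vapply(per, function(tr) is_state_solved(replay_trace(tr, puzzle)), logical(1))
  list(mean = mean(n_steps),
       sd = stats::sd(n_steps),
       perfect_ratio = mean(solved & n_steps == 7L),
       n_steps = unname(n_steps))
}

#' Root-mean-square error between two per-step choice heatmaps
#'
#' For each step s, `RMSE_s = sqrt( sum_p (h_model(p,s) - h_data(p,s))^2 / 5 )`
#' over the 5 piece kinds, then averaged over the compared steps.
#'
#' @param model_hm,data_hm `cts_heatmap` matrices (see [build_heatmap()]).
#' @param steps Step range to compare; default the steps both heatmaps cover.
#' @return List: `per_step` RMSE vector, `mean`.
#' @export
heatmap_rmse <- function(model_hm, data_hm, steps = NULL) {
  if (!identical(rownames(model_hm), rownames(data_hm))) {
    stop("heatmap piece-kind axes do not match")
  }
  if (is.null(steps)) steps <- seq_len(min(ncol(model_hm), ncol(data_hm)))
  if (length(steps) == 0) stop("no overlapping steps to compare")
  per <- vapply(steps, function(s)
    sqrt(sum((model_hm[, s] - data_hm[, s])^2) / nrow(model_hm)), numeric(1))
  list(per_step = per, mean = mean(per))
}

#' Default offset schedule for state plausibility
#'
#' The comparison window grows with the step index: offset(s) = 1 +
#' floor((s - 3) / 4).
#' @param s Step index vector.
#' @return Integer offsets.
#' @export
default_offset_schedule <- function(s) 1L + pmax(0L, (as.integer(s) - 3L) %/% 4L)

#' Step-by-step state plausibility
#'
#' Fraction of model states (at steps within `step_range`) whose signature
#' equals some data-trace state at a step within +/- offset(s).  The default
#' range is steps 3 to ceiling(mean + 1 SD) of the data cohort's step counts.
#'
#' @param model_traces,data_traces Cohort data.frames.
#' @param puzzle A [tangram_puzzle()] used for replay.
#' @param step_range Steps of the model runs to evaluate (default as above).
#' @param offset_schedule Function step -> allowed offset.
#' @return Plausibility in `[0, 1]`.
#' @export
states_plausibility <- function(model_traces, data_traces, puzzle,
                                step_range = NULL,
                                offset_schedule = default_offset_schedule) {
  model_per <- split_traces(model_traces)
  data_per <- split_traces(data_traces)
  if (length(model_per) == 0 || length(data_per) == 0) {
    stop("states_plausibility: empty input cohort")
  }
  data_sigs <- lapply(data_per, function(tr)
    attr(replay_trace(tr, puzzle, signatures = TRUE), "signatures"))
  if (is.null(step_range)) {
    n <- vapply(data_per, nrow, integer(1))
    hi <- ceiling(mean(n) + stats::sd(n))
    if (is.na(hi)) hi <- max(n)
    step_range <- 3:max(3, hi)
  }
  total <- 0L; matched <- 0L
  for (tr in model_per) {
    sigs <- attr(replay_trace(tr, puzzle, signatures = TRUE), "signatures")
    for (s in intersect(step_range, seq_along(sigs))) {
      total <- total + 1L
      off <- offset_schedule(s)
      lo <- max(1L, s - off); hi2 <- s + off
      hit <- any(vapply(data_sigs, function(ds)
        any(ds[seq(lo, min(hi2, length(ds)))] == sigs[s]), logical(1)))
      if (hit) matched <- matched + 1L
    }
  }
  if (total == 0L) stop("states_plausibility: no model states in step range")
  matched / total
}

#' @keywords internal
prediction_hit <- function(pred, future, window) {
  if (nrow(future) == 0) return(FALSE)
  future <- future[seq_len(min(window, nrow(future))), , drop = FALSE]
  any(future$action == pred$action & future$kind == pred$kind &
        future$grid_loc == pred$grid_loc &
        (future$rotation %% 360) == (pred$rotation %% 360))
}

#' Windowed next-action prediction accuracy
#'
#' For every prefix of every data trace, [predict_next()] proposes an action;
#' the prediction is a hit when the proposed (action, kind, grid_loc,
#' rotation) occurs among the trace's following `window` steps.
#'
#' @param data_traces Cohort data.frame.
#' @param puzzle,params,freqs,resolution As in [run_trial()].
#' @param window Look-ahead window in steps (default 2).
#' @param seed RNG seed for noisy predictions.
#' @return Hits / predictions, in `[0, 1]`.
#' @export
prediction_accuracy <- function(data_traces, puzzle, params = variant_params(),
                                freqs, window = 2L, seed = 1L, resolution = 12) {
  if (window < 1) stop("window must be at least 1")
  hits <- 0L; total <- 0L
  for (tr in split_traces(data_traces)) {
    for (j in seq_len(nrow(tr)) - 1L) {     # prefix lengths 0 .. n-1
      pred <- predict_next(tr[seq_len(j), , drop = FALSE], puzzle, params, freqs,
                           seed = seed + total, resolution = resolution)
      future <- tr[seq(j + 1L, nrow(tr)), , drop = FALSE]
      total <- total + 1L
      if (prediction_hit(pred, future, window)) hits <- hits + 1L
    }
  }
  hits / total
}

#' Full evaluation report for a model cohort against a data cohort
#'
#' @param model_traces,data_traces Cohort data.frames.
#' @param puzzle,params,freqs As in [run_trial()].
#' @param window Prediction window.
#' @param seed Seed for noisy predictions.
#' @param predict Also compute prediction accuracy (the expensive part).
#' @return List of class `cts_eval`: overall statistics for both cohorts,
#'   per-step heatmap RMSE and its mean, plausibility, and (optionally)
#'   prediction accuracy.
#' @export
evaluate_model <- function(model_traces, data_traces, puzzle,
                           params = variant_params(), freqs = NULL,
                           window = 2L, seed = 1L, predict = FALSE) {
  rm <- heatmap_rmse(build_heatmap(model_traces), build_heatmap(data_traces))
  out <- list(
    model_stats = overall_stats(model_traces, puzzle),
    data_stats = overall_stats(data_traces, puzzle),
    heatmap_rmse_per_step = rm$per_step,
    heatmap_rmse_mean = rm$mean,
    plausibility = states_plausibility(model_traces, data_traces, puzzle),
    prediction_accuracy = if (predict)
      prediction_accuracy(data_traces, puzzle, params, freqs, window, seed)
    else NA_real_)
  class(out) <- "cts_eval"
  out
}

#' @export
print.cts_eval <- function(x, ...) {
  cat("CTS evaluation\n")
  cat(sprintf("  model steps: mean %.2f sd %.2f perfect %.2f\n",
              x$model_stats$mean, x$model_stats$sd, x$model_stats$perfect_ratio))
  cat(sprintf("  data steps:  mean %.2f sd %.2f perfect %.2f\n",
              x$data_stats$mean, x$data_stats$sd, x$data_stats$perfect_ratio))
  cat(sprintf("  heatmap RMSE (mean): %.4f\n", x$heatmap_rmse_mean))
  cat(sprintf("  states plausibility: %.3f\n", x$plausibility))
  if (!is.na(x$prediction_accuracy))
    cat(sprintf("  prediction accuracy: %.3f\n", x$prediction_accuracy))
  invisible(x)
}
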