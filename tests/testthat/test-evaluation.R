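mk_trace <- function(id, actions, pz) {
  data.frame(participant_id = id, step = seq_along(actions$kind),
             action = actions$action, kind = actions$kind,
             grid_loc = actions$grid_loc, rotation = actions$rotation,
             mirror = FALSE, stringsAsFactors = FALSE)
}

test_that("overall statistics summarize step counts and perfect solutions", {
  pz <- tangram_puzzle("house")
  perfect <- synth_participants(pz, synth_params(pz, p_perfect = 1), n = 4, seed = 1)
  st <- overall_stats(perfect, pz)
  expect_equal(st$mean, 7)
  expect_equal(st$sd, 0)
  expect_equal(st$perfect_ratio, 1)
  # mixed 7- and 15-step cohort
  mixed <- synth_participants(pz, synth_params(pz, p_perfect = 0.5), n = 40, seed = 2)
  sm <- overall_stats(mixed, pz)
  counts <- vapply(split_traces(mixed), nrow, integer(1))
  expect_equal(sm$mean, mean(counts))
  expect_equal(sm$perfect_ratio, mean(counts == 7))
  expect_error(overall_stats(mixed[0, ]), "empty")
})

test_that("heatmap RMSE matches hand-computed worked values", {
  kinds <- tan_kinds()
  h1 <- matrix(0, 5, 2, dimnames = list(kinds, NULL))
  h1["big_triangle", 1] <- 1; h1["square", 2] <- 1
  # identical heatmaps -> all zeros
  r0 <- heatmap_rmse(h1, h1)
  expect_equal(r0$per_step, c(0, 0))
  expect_equal(r0$mean, 0)
  # one-hot disagreement: sqrt(2/5)
  h2 <- matrix(0, 5, 2, dimnames = list(kinds, NULL))
  h2["mid_triangle", 1] <- 1; h2["square", 2] <- 1
  r1 <- heatmap_rmse(h1, h2)
  expect_equal(r1$per_step[1], sqrt(2 / 5), tolerance = 1e-6)
  expect_equal(r1$per_step[2], 0)
  # +-0.1 shift on two entries: sqrt(0.02/5)
  h3 <- matrix(0, 5, 1, dimnames = list(kinds, NULL))
  h3[c("big_triangle", "square"), 1] <- 0.5
  h4 <- h3
  h4[c("big_triangle", "square"), 1] <- c(0.6, 0.4)
  expect_equal(heatmap_rmse(h3, h4)$per_step, sqrt(0.02 / 5), tolerance = 1e-6)
  # metric properties: symmetry, non-negativity
  expect_equal(heatmap_rmse(h1, h2)$mean, heatmap_rmse(h2, h1)$mean)
  expect_true(all(heatmap_rmse(h1, h2)$per_step >= 0))
  expect_error(heatmap_rmse(h1, matrix(0, 4, 2)), "axes")
})

test_that("state plausibility matches itself, misses disjoint, honors offsets", {
  pz <- tangram_puzzle("house")
  tr <- synth_participants(pz, synth_params(pz), n = 8, seed = 3)
  expect_equal(states_plausibility(tr, tr, pz), 1)
  # model states disjoint from all data states: perfect traces vs a cohort
  # whose early states never coincide (shift trace by a prepended detour)
  sol <- tangram_puzzle("monk")$solution
  a <- synth_participants(tangram_puzzle("monk"),
                          synth_params("monk", p_perfect = 1), n = 2, seed = 4)
  det <- tangram_puzzle("monk")$modal_error
  shifted <- do.call(rbind, lapply(split_traces(a), function(t) {
    pre <- data.frame(participant_id = t$participant_id[1], step = 0L,
                      action = c("place", "remove"), kind = det$kind,
                      grid_loc = det$grid_loc, rotation = det$rotation,
                      mirror = FALSE)
    out <- rbind(pre, t)
    out$step <- seq_len(nrow(out))
    out
  }))
  # a +2-step shift falls outside offset 1 at early steps but inside larger
  # offsets: plausibility is monotone in the offset schedule
  p_small <- states_plausibility(shifted, a, tangram_puzzle("monk"),
                                 offset_schedule = function(s) 0L)
  p_big <- states_plausibility(shifted, a, tangram_puzzle("monk"),
                               offset_schedule = function(s) 2L)
  expect_lte(p_small, p_big)
  expect_equal(p_big, 1)
})

test_that("prediction windows score near hits and miss late ones", {
  pz <- tangram_puzzle("house")
  p <- variant_params("frequency", noise_s = 0)
  sol <- pz$solution
  # frequency support on a single action A: the model always suggests A
  A <- sol[1, ]  # big triangle, rotation 90
  fq <- structure(data.frame(kind = A$kind, grid_loc = A$grid_loc,
                             rotation = A$rotation, phase = rep(1:3, each = 1),
                             f = 1), phase_bins = c(4, 12),
                  class = c("cts_freq_table", "data.frame"))
  B <- sol[2, ]  # big triangle, rotation 270
  C <- sol[3, ]  # square
  mk <- function(rows) data.frame(participant_id = "t", step = seq_len(nrow(rows)),
                                  action = "place", kind = rows$kind,
                                  grid_loc = rows$grid_loc, rotation = rows$rotation,
                                  mirror = FALSE, stringsAsFactors = FALSE)
  # A two steps after the prefix: hit at every prediction point
  t2 <- mk(rbind(B, A))
  expect_equal(prediction_accuracy(t2, pz, p, fq, window = 2), 1)
  # A three steps ahead at the first point: that point misses
  t3 <- mk(rbind(B, C, A))
  expect_equal(prediction_accuracy(t3, pz, p, fq, window = 2), 2 / 3)
  # accuracy is monotone in the window
  expect_equal(prediction_accuracy(t3, pz, p, fq, window = 3), 1)
})

test_that("noise-free self-prediction accuracy is perfect", {
  pz <- tangram_puzzle("house")
  p <- variant_params("frequency", noise_s = 0)
  fq <- canonical_frequency_table(pz)
  tr <- h_canonical_trial("house")
  expect_equal(prediction_accuracy(tr$trace, pz, p, fq, window = 2, seed = 1), 1)
})
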