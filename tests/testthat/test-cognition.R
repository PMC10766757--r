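opt_row <- function(kind = "square", grid_loc = 1L, rotation = 0L, s = 0.5,
                    f = 0.5, strength = NA_real_) {
  data.frame(kind = kind, grid_loc = grid_loc, rotation = rotation,
             mirrored = FALSE, s = s, f = f, phase = 1L, strength = strength,
             stringsAsFactors = FALSE)
}

test_that("strength combines frequency and similarity per variant", {
  expect_equal(compute_strength(0.3, 0.8, variant_params("vision", k_d = 0, k_cv = 1)),
               0.8)
  expect_equal(compute_strength(0.475, 0.8,
                                variant_params("frequency", k_d = 1, k_cv = 0)),
               0.475)
  expect_equal(compute_strength(0.4, 0.8,
                                variant_params("vision", k_d = 0.5, k_cv = 0.5)),
               0.6)
  # balanced: frequency penalized by the matching error
  expect_equal(compute_strength(0.4, 0.8, variant_params("balanced", lambda = 0.5)),
               0.4 * (1 - 0.5 * 0.2))
  expect_error(variant_params("vision", k_d = -1), "non-negative")
  expect_error(compute_strength(1.5, 0.5, variant_params("vision")), "0, 1")
  # limit cases: pure-similarity / pure-frequency rankings
  f <- c(0.1, 0.6, 0.3); s <- c(0.9, 0.2, 0.5)
  expect_equal(order(-compute_strength(f, s, variant_params("vision", k_d = 0, k_cv = 1))),
               order(-s))
  expect_equal(order(-compute_strength(f, s, variant_params("frequency", k_d = 1, k_cv = 0))),
               order(-f))
})

test_that("the context buffer keeps the strongest options with stated tie-breaks", {
  p <- variant_params("frequency", noise_s = 0)
  few <- score_options(do.call(rbind, lapply(1:3, function(i)
    opt_row(grid_loc = i, s = i / 10))), p)
  expect_equal(nrow(build_context(few, 6)), 3)
  many <- score_options(do.call(rbind, lapply(1:10, function(i)
    opt_row(grid_loc = i, s = i / 20, f = 0.1))), p)
  ctx <- build_context(many, 6)
  expect_equal(nrow(ctx), 6)
  expect_equal(sort(ctx$grid_loc), 5:10)  # top strengths
  # tie at max strength: higher f wins
  tied <- score_options(rbind(opt_row(grid_loc = 1L, s = 1, f = 0.2),
                              opt_row(grid_loc = 2L, s = 0.85, f = 0.8)), p)
  tied$strength <- c(0.5, 0.5)
  expect_equal(build_context(tied, 6)$grid_loc[1], 2L)
})

test_that("activation adds base strength, spreading and seeded noise", {
  p0 <- variant_params("frequency", noise_s = 0, spreading_W = 1)
  chunk <- opt_row(strength = 0.6)
  expect_equal(activation(chunk, chunk, p0), 1.6)              # in context of 1
  other <- opt_row(grid_loc = 99L, strength = 0.3)
  expect_equal(activation(chunk, other, p0), 0.6)              # not in context
  two <- rbind(chunk, other)
  expect_equal(activation(chunk, two, p0), 0.6 + 0.5)          # W split across 2
  pn <- variant_params("frequency", noise_s = 0.25)
  set.seed(7); a1 <- activation(chunk, chunk, pn)
  set.seed(7); a2 <- activation(chunk, chunk, pn)
  expect_identical(a1, a2)
  expect_false(isTRUE(all.equal(a1, 1.6)))
})

test_that("retrieval respects the threshold and the recently-retrieved record", {
  p <- variant_params("frequency", noise_s = 0, finst_span = 2L)
  store <- new_declarative_store()
  expect_null(retrieve(store, opt_row()[0, ], p))              # empty store
  one <- score_options(opt_row(s = 0.9, f = 0.9), p)
  store_load_options(store, one)
  got <- retrieve(store, build_context(one, 6), p)
  expect_equal(got$grid_loc, one$grid_loc)
  # immediately re-querying the same chunk fails until evicted
  store_load_options(store, one)
  expect_null(retrieve(store, build_context(one, 6), p))
  # below-threshold activation is a retrieval failure
  ptau <- variant_params("frequency", noise_s = 0, tau = 10)
  store2 <- new_declarative_store()
  store_load_options(store2, one)
  expect_null(retrieve(store2, build_context(one, 6), ptau))
})

test_that("no chunk is retrieved twice within the finst span", {
  p <- variant_params("frequency", noise_s = 0, finst_span = 3L)
  opts <- score_options(do.call(rbind, lapply(1:5, function(i)
    opt_row(grid_loc = i, s = i / 10, f = i / 10))), p)
  store <- new_declarative_store()
  seen <- character(0)
  for (k in 1:4) {
    store_load_options(store, opts)
    got <- retrieve(store, build_context(opts, 6), p)
    id <- paste(got$kind, got$grid_loc, got$rotation, got$mirrored, sep = ":")
    recent <- utils::tail(seen, 3)
    expect_false(id %in% recent)
    seen <- c(seen, id)
  }
})

test_that("the decision rule covers place and both backtracks", {
  pz <- tangram_puzzle("monk")
  p <- variant_params("frequency", noise_s = 0)
  fq <- canonical_frequency_table(pz)
  # feasible state, one strong option -> place it
  st <- new_puzzle_state(pz)
  opts <- score_options(data.frame(
    kind = "big_triangle", grid_loc = pz$solution$grid_loc[1], rotation = 90L,
    mirrored = FALSE, s = 0.9, f = 1 / 7, phase = 1L, strength = NA_real_,
    stringsAsFactors = FALSE), p)
  d <- decide(st, opts, p, new_declarative_store(), st$placed, freqs = fq)
  expect_equal(d$type, "place")
  expect_equal(d$payload$kind, "big_triangle")
  # engineered unfeasible state -> region backtrack of the queue head
  st2 <- place_tan(st, "big_triangle", pz$modal_error$grid_loc, 270)
  st2 <- place_tan(st2, "big_triangle", pz$solution$grid_loc[1], 90)
  last <- st2$placed[[2]]
  d2 <- decide(st2, opts[0, ], p, new_declarative_store(), st2$placed,
               problem_queue = list(last), freqs = fq)
  expect_equal(d2$type, "region_backtrack")
  expect_equal(d2$payload$grid_loc, last$grid_loc)
  # feasible state, zero options -> piece backtrack of the lowest-f action
  st3 <- place_tan(st, "big_triangle", pz$solution$grid_loc[1], 90)
  st3 <- place_tan(st3, "square", pz$solution$grid_loc[3], 0)
  d3 <- decide(st3, opts[0, ], p, new_declarative_store(), st3$placed,
               freqs = build_frequency_table(data.frame(
                 participant_id = "p", step = 1:2, action = "place",
                 kind = c("big_triangle", "big_triangle"),
                 grid_loc = pz$solution$grid_loc[1], rotation = c(90L, 90L),
                 mirror = FALSE)))
  expect_equal(d3$type, "piece_backtrack")
  expect_equal(d3$payload$kind, "square")  # f = 0 < f(big)
})

test_that("piece backtracking picks the weakest action, most recent on ties", {
  pz <- tangram_puzzle("house")
  fq <- structure(data.frame(kind = c("square", "big_triangle", "mid_triangle"),
                             grid_loc = c(1L, 2L, 3L), rotation = 0L, phase = 1L,
                             f = c(0.4, 0.05, 0.2)),
                  class = c("cts_freq_table", "data.frame"))
  acts <- list(list(kind = "square", grid_loc = 1, rotation = 0),
               list(kind = "big_triangle", grid_loc = 2, rotation = 0),
               list(kind = "mid_triangle", grid_loc = 3, rotation = 0))
  expect_equal(piece_backtrack_target(acts, fq, 1)$kind, "big_triangle")
  # all equal -> most recent
  fq$f <- 0.2
  expect_equal(piece_backtrack_target(acts, fq, 1)$kind, "mid_triangle")
  expect_equal(piece_backtrack_target(acts[1], fq, 1)$kind, "square")
  expect_error(piece_backtrack_target(list(), fq, 1), "dead end")
})

test_that("region backtracking is queue-based (FIFO)", {
  q <- list(list(kind = "a", grid_loc = 1, rotation = 0),
            list(kind = "b", grid_loc = 2, rotation = 0))
  st <- new_puzzle_state(tangram_puzzle("house"))
  expect_equal(region_backtrack_step(st, q)$kind, "a")
  expect_equal(region_backtrack_step(st, q[-1])$kind, "b")
  expect_null(region_backtrack_step(st, list()))
})

test_that("variant configs load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: vision", "k_d: 0.1", "k_cv: 0.9", "noise_s: 0.0",
               "context_capacity: 4"), path)
  p <- read_variant_config(path)
  expect_equal(p$name, "vision")
  expect_equal(p$k_cv, 0.9)
  expect_equal(p$context_capacity, 4L)
  expect_false(p$frequency_screen)
})
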