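test_that("the canonical tan set matches the classical dissection", {
  tans <- canonical_tans()
  expect_length(tans, 7)
  kinds <- vapply(tans, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "big_triangle"), 2)
  expect_equal(sum(kinds == "small_triangle"), 2)
  expect_equal(sum(kinds == "mid_triangle"), 1)
  areas <- vapply(tans, `[[`, numeric(1), "area")
  expect_equal(sum(areas), 8)
  expect_equal(sort(unique(round(areas, 9))), c(0.5, 1, 2))
  # all polygons simple and closed by construction: positive area, >= 3 vertices
  for (t in tans) {
    expect_gte(nrow(t$polygon), 3)
    expect_gt(ctsolver:::poly_signed_area(t$polygon), 0)
  }
})

test_that("the placement transform is exact on the a + b*sqrt(2) ring", {
  # identity and full-turn symmetry
  small0 <- transform_tan("small_triangle", 0, c(0, 0))
  expect_equal(small0, rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(transform_tan("big_triangle", 360 %% 360, c(2, 1)),
               transform_tan("big_triangle", 0, c(2, 1)))
  # hand-rotated big triangle at 45 degrees, anchored at the origin:
  # vertices (sqrt(2),0), (2*sqrt(2),sqrt(2)), (0,sqrt(2))
  s2 <- sqrt(2)
  got <- transform_tan("big_triangle", 45, c(0, 0))
  want <- rbind(c(s2, 0), c(2 * s2, s2), c(0, s2))
  perm <- apply(want, 1, function(v)
    which(abs(got[, 1] - v[1]) < 1e-9 & abs(got[, 2] - v[2]) < 1e-9))
  expect_equal(sort(unlist(perm)), 1:3)
  # area preserved exactly under every rotation and mirroring
  for (rot in seq(0, 315, 45)) {
    expect_equal(poly_area(transform_tan("parallelogram", rot, c(1, 1), TRUE)), 1)
    expect_equal(poly_area(transform_tan("mid_triangle", rot, c(0, 0))), 1)
  }
  expect_error(transform_tan("big_triangle", 30, c(0, 0)), "rotation")
  expect_error(transform_tan("square", 0, c(0, 0), mirrored = TRUE), "parallelogram")
})

test_that("bundled solutions tile both silhouettes exactly", {
  for (nm in c("house", "monk")) {
    pz <- tangram_puzzle(nm)
    expect_equal(poly_area(pz$target), 8)
    st <- h_solution_state(pz)
    expect_true(is_state_solved(st))
    expect_lt(abs(uncovered_area(st)), 1e-6)
    # area conservation along the way
    st2 <- new_puzzle_state(pz)
    for (i in seq_len(nrow(pz$solution))) {
      s <- pz$solution[i, ]
      st2 <- place_tan(st2, s$kind, s$grid_loc, s$rotation, s$mirrored)
      placed_area <- sum(vapply(st2$placed, function(p) poly_area(p$polygon),
                                numeric(1)))
      expect_equal(uncovered_area(st2) + placed_area, 8, tolerance = 1e-9)
    }
  }
})

test_that("legal placement enumeration agrees with an independent backend", {
  pz <- tangram_puzzle("monk")
  lp <- legal_placements(new_puzzle_state(pz), "big_triangle")
  expect_gt(nrow(lp), 0)
  expect_equal(nrow(lp), h_indep_empty_enumeration(pz, "big_triangle"))
  # deterministic order
  expect_equal(lp, lp[order(lp$grid_loc, lp$rotation), ],
               ignore_attr = TRUE)
  # solved state admits nothing
  st <- h_solution_state(pz)
  for (k in tan_kinds()) expect_equal(nrow(legal_placements(st, k)), 0)
})

test_that("an exactly congruent hole admits the exact-fit placement", {
  pz <- tangram_puzzle("house")
  i <- which(pz$solution$kind == "small_triangle")[1]
  st <- h_solution_state(pz, skip_row = i)
  lp <- legal_placements(st, "small_triangle")
  s <- pz$solution[i, ]
  expect_true(any(lp$grid_loc == s$grid_loc & lp$rotation == s$rotation))
  # every legal placement fits inside the hole area
  expect_true(all(vapply(seq_len(nrow(lp)), function(j)
    is_legal_placement(st, lp$kind[j], lp$grid_loc[j], lp$rotation[j],
                       lp$mirrored[j]), logical(1))))
})

test_that("unfeasible regions are detected and clear states are not flagged", {
  for (nm in c("house", "monk")) {
    pz <- tangram_puzzle(nm)
    u <- detect_unfeasible(new_puzzle_state(pz))
    expect_false(u$flag)
    expect_length(u$blocked_kinds, 0)
    u2 <- detect_unfeasible(h_solution_state(pz))
    expect_false(u2$flag)
  }
  # engineered: modal error + one correct big leaves a 1/sqrt(2)-wide strip
  pz <- tangram_puzzle("monk")
  st <- new_puzzle_state(pz)
  me <- pz$modal_error
  st <- place_tan(st, me$kind, me$grid_loc, me$rotation)
  st <- place_tan(st, "big_triangle", pz$solution$grid_loc[1], 90)
  u <- detect_unfeasible(st)
  expect_true(u$flag)
  expect_true("square" %in% u$blocked_kinds)
  # the oracle agrees: no legal placement for the blocked kind
  for (k in u$blocked_kinds) expect_equal(nrow(legal_placements(st, k)), 0)
})

test_that("state signatures are order-independent and instance-agnostic", {
  pz <- tangram_puzzle("house")
  expect_equal(state_signature(new_puzzle_state(pz)), "")
  sol <- pz$solution
  a <- new_puzzle_state(pz)
  a <- place_tan(a, "big_triangle", sol$grid_loc[1], 90)
  a <- place_tan(a, "square", sol$grid_loc[3], 0)
  b <- new_puzzle_state(pz)
  b <- place_tan(b, "square", sol$grid_loc[3], 0)
  b <- place_tan(b, "big_triangle", sol$grid_loc[1], 90, instance_id = 2L)
  expect_identical(state_signature(a), state_signature(b))
  # swapping the two small triangles between two slots leaves it unchanged
  i <- which(sol$kind == "small_triangle")
  c1 <- new_puzzle_state(pz)
  c1 <- place_tan(c1, "small_triangle", sol$grid_loc[i[1]], sol$rotation[i[1]],
                  instance_id = 1L)
  c1 <- place_tan(c1, "small_triangle", sol$grid_loc[i[2]], sol$rotation[i[2]],
                  instance_id = 2L)
  c2 <- new_puzzle_state(pz)
  c2 <- place_tan(c2, "small_triangle", sol$grid_loc[i[2]], sol$rotation[i[2]],
                  instance_id = 1L)
  c2 <- place_tan(c2, "small_triangle", sol$grid_loc[i[1]], sol$rotation[i[1]],
                  instance_id = 2L)
  expect_identical(state_signature(c1), state_signature(c2))
})

test_that("puzzle configs round-trip through YAML", {
  pz <- tangram_puzzle("house")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_puzzle_config(pz, path)
  back <- read_puzzle_config(path)
  expect_equal(back$name, pz$name)
  expect_equal(back$target, pz$target, ignore_attr = TRUE)
  expect_equal(nrow(back$grid), nrow(pz$grid))
  expect_equal(back$solution$grid_loc, pz$solution$grid_loc)
})
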