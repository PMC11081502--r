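test_that("sample_path returns self-avoiding Von Neumann paths", {
  set.seed(1)
  for (i in 1:20) {
    p <- sample_path(9)
    expect_equal(nrow(p), 9L)
    # consecutive cells Manhattan distance 1
    expect_true(all(abs(diff(p[, 1])) + abs(diff(p[, 2])) == 1L))
    # exhaustive pairwise self-avoidance check
    for (a in 1:8) for (b in (a + 1):9)
      expect_false(all(p[a, ] == p[b, ]))
  }
})

test_that("sample_path respects the occupied exclusion zone", {
  set.seed(2)
  occ <- sample_path(9)
  for (i in 1:10) {
    p <- sample_path(9, occupied = occ)
    d <- outer(seq_len(9), seq_len(9), Vectorize(function(a, b)
      abs(p[a, 1] - occ[b, 1]) + abs(p[a, 2] - occ[b, 2])))
    expect_true(min(d) >= 2L)  # no shared or 4-adjacent cells
  }
})

test_that("degenerate path requests fail cleanly", {
  expect_error(sample_path(226), class = "vr_placement_failure")
  expect_error(sample_path(1), "at least 2")
  set.seed(3)
  p <- sample_path(2)
  expect_equal(unname(abs(p[1, 1] - p[2, 1]) + abs(p[1, 2] - p[2, 2])), 1L)
})

test_that("trace stimuli have the prescribed color composition", {
  set.seed(4)
  s2 <- make_trace_stimulus(2, n_distractors = 0)
  cols <- table(factor(s2$cells[, 3], levels = 1:4))
  expect_equal(unname(cols[["1"]]), 1L)  # one red
  expect_equal(unname(cols[["3"]]), 1L)  # one blue
  expect_equal(unname(cols[["4"]]), 0L)
  expect_equal(unname(abs(s2$target_path[1, 1] - s2$target_path[2, 1]) +
                      abs(s2$target_path[1, 2] - s2$target_path[2, 2])), 1L)

  s9 <- make_trace_stimulus(9, n_distractors = 1)
  cols <- table(factor(s9$cells[, 3], levels = 1:4))
  expect_equal(unname(cols[["1"]]), 1L)   # red = 1
  expect_equal(unname(cols[["3"]]), 2L)   # blue = 1 + n_distractors
  expect_equal(unname(cols[["4"]]), 15L)  # green = (9-2) + (9-1)
  expect_equal(s9$correct_action,
               unname((s9$target_path[9, 1] - 1L) * 15L + s9$target_path[9, 2]))
})

test_that("multi-distractor stimuli form disjoint non-adjacent components", {
  set.seed(5)
  s <- make_trace_stimulus(9, n_distractors = 10)
  expect_equal(length(s$distractor_paths), 10L)
  comp <- brute_components(s$cells[, 1:2], s$grid)
  expect_equal(length(unique(comp)), 11L)
  # each component is one declared path
  paths <- c(list(s$target_path), s$distractor_paths)
  starts <- cumsum(c(0, rep(9, 10)))
  for (k in seq_along(paths))
    expect_equal(length(unique(comp[starts[k] + 1:9])), 1L)
})

test_that("spiral targets support lengths up to 25", {
  set.seed(6)
  s <- make_trace_stimulus(25, n_distractors = 0, spiral = TRUE)
  expect_equal(s$length, 25L)
  p <- s$target_path
  expect_true(all(abs(diff(p[, 1])) + abs(diff(p[, 2])) == 1L))
  expect_equal(anyDuplicated(p), 0L)
})

test_that("search-then-trace stimuli follow the cue", {
  set.seed(7)
  s <- make_search_then_trace_stimulus(9)
  expect_equal(sum(s$cue_activation), 1)  # one-hot cue
  first_colors <- sort(c(s$cells[1, 3], s$cells[10, 3]))
  expect_equal(unname(first_colors), c(1L, 2L))   # one red and one brown marker
  expect_equal(unname(s$cells[9, 3]), 3L) # both curves end blue
  expect_equal(unname(s$cells[18, 3]), 3L)
  # swapping the cue color flips the correct action to the other blue end
  set.seed(42); s_red <- make_search_then_trace_stimulus(9, cue_color = "red")
  set.seed(42); s_brown <- make_search_then_trace_stimulus(9, cue_color = "brown")
  ends <- rbind(s_red$target_path[9, ], s_red$distractor_paths[[1]][9, ])
  expect_false(s_red$correct_action == s_brown$correct_action)
  expect_setequal(c(s_red$correct_action, s_brown$correct_action),
                  (ends[, 1] - 1L) * 15L + ends[, 2])
})

test_that("trace-then-search stimuli target the matching extra unit", {
  set.seed(8)
  s <- make_trace_then_search_stimulus(9, end_color = "brown")
  expect_equal(s$correct_action, 225L + 2L)  # brown extra unit
  expect_equal(sum(s$cells[, 3] == 3L), 1L)  # exactly one blue pixel
  expect_equal(s$extras, c(1, 1))
  # pre-stage variant: eye movement to the end marker on the grid
  s0 <- make_trace_then_search_stimulus(9, with_external = FALSE,
                                        end_color = "red")
  expect_equal(s0$extras, c(0, 0))
  expect_equal(s0$correct_action,
               unname((s0$target_path[9, 1] - 1L) * 15L + s0$target_path[9, 2]))
  # end-marker color is balanced
  set.seed(9)
  ends <- replicate(400, make_trace_then_search_stimulus(4)$correct_action)
  expect_gt(mean(ends == 226L), 0.45)
  expect_lt(mean(ends == 226L), 0.55)
})

test_that("encoding is one-hot with cue and extras appended", {
  set.seed(10)
  s <- make_search_then_trace_stimulus(5, cue_color = "red")
  tens <- input_tensor(s)
  sums <- apply(tens$grid, c(1, 2), sum)
  expect_true(all(sums %in% c(0, 1)))          # per-cell channel sum
  expect_equal(sum(sums), nrow(s$cells))
  expect_equal(tens$extras, c(1, 0))
  for (i in seq_len(nrow(s$cells)))
    expect_equal(tens$grid[s$cells[i, 1], s$cells[i, 2], s$cells[i, 3]], 1)
  # blank cells carry no color anywhere
  blank <- which(sums == 0, arr.ind = TRUE)[1, ]
  expect_equal(sum(tens$grid[blank[1], blank[2], ]), 0)
})

test_that("reward is 1 for the correct action and 0 elsewhere", {
  set.seed(11)
  s <- make_trace_stimulus(5)
  expect_equal(stimulus_reward(s, s$correct_action), 1.0)
  wrong <- if (s$correct_action == 1L) 2L else 1L
  expect_equal(stimulus_reward(s, wrong), 0.0)
  expect_equal(sum(vapply(1:227, function(a) stimulus_reward(s, a),
                          numeric(1))), 1.0)
  expect_error(stimulus_reward(s, 228), "out of range")
  expect_error(stimulus_reward(s, 0), "out of range")
})

test_that("stimulus generation is reproducible under a fixed seed", {
  set.seed(123); a <- make_trace_stimulus(9)
  set.seed(123); b <- make_trace_stimulus(9)
  expect_identical(a$cells, b$cells)
  expect_identical(a$correct_action, b$correct_action)
})
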