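test_that("modulation index matches the closed form", {
  expect_equal(modulation_index(2, 1), (2 - 1) / ((2 + 1) / 2))
  expect_equal(modulation_index(2, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(modulation_index(1, 1), 0)
  expect_equal(modulation_index(3, 0), 2)   # upper bound
  expect_equal(modulation_index(0, 3), -2)  # lower bound
  expect_true(is.na(modulation_index(0, 0)))
  # vectorized, bounded
  t <- runif(50); d <- runif(50)
  mi <- modulation_index(t, d)
  expect_true(all(mi >= -2 & mi <= 2))
  expect_error(modulation_index(-1, 1))
})

test_that("modulation latency implements the 70%-of-maximum rule", {
  expect_equal(modulation_latency(c(0, 1, 3, 8, 10, 10)), 3L)
  expect_true(is.na(modulation_latency(rep(0, 10))))
  expect_true(is.na(modulation_latency(c(-3, -1, 0))))
  expect_equal(modulation_latency(c(10, 1, 1)), 0L)
  # scale invariance under positive rescaling
  x <- c(0, 0.5, 1, 4, 9, 9.5)
  for (k in c(0.01, 1, 250)) {
    expect_equal(modulation_latency(k * x), modulation_latency(x))
  }
  # custom threshold fraction
  expect_equal(modulation_latency(c(0, 4, 6, 10), frac = 0.5), 2L)
})

test_that("evaluation batches accumulate target/distractor records correctly", {
  net <- small_net(seed = 90)
  set.seed(90)
  b <- evaluate_batch(net, "trace", length = 4, n_stimuli = 40,
                      max_timesteps = 20)
  expect_s3_class(b, "vr_eval_batch")
  expect_equal(b$n_timesteps, 21L)
  expect_equal(dim(b$Tt), c(100, 4, 21))
  # counts match between sum over units and number of correct trials
  expect_true(all(colSums(b$Tcnt) == b$n_correct))
  expect_true(all(colSums(b$Dcnt) == b$n_correct))
  expect_lte(b$n_correct, 40L)
  m <- batch_modulation(b)
  expect_true(all(m$mi >= -2 & m$mi <= 2))
  # MI recomputed by brute force from the stored sums
  if (nrow(m) > 0) {
    u <- m$unit[1]
    tbar <- sum(b$Tt[u, , 21]) / sum(b$Tcnt[u, ])
    dbar <- sum(b$Dt[u, , 21]) / sum(b$Dcnt[u, ])
    expect_equal(m$mi[1], (tbar - dbar) / ((tbar + dbar) / 2))
  }
})

test_that("min_timesteps_to_criterion returns the sentinel for untrained nets", {
  set.seed(91)
  net <- init_network(network_config())
  mt <- min_timesteps_to_criterion(net, "trace", length = 5,
                                   criterion = 0.85, n_trials = 30,
                                   t_max = 4)
  expect_true(is.na(mt))
  curve <- attr(mt, "accuracy_curve")
  expect_equal(nrow(curve), 4L)
  expect_true(all(curve$accuracy < 0.85))
})

test_that("credit propagation profile separates the two curves", {
  net <- small_net(seed = 92)
  set.seed(92)
  s <- make_trace_stimulus(4, grid = small_grid())
  prof <- credit_propagation_profile(net, s)
  expect_setequal(unique(prof$curve), c("selected", "non-selected"))
  expect_equal(max(prof$distance_from_target), 3L)
  # step 0 is the all-zero seed of the accessory relaxation
  expect_true(all(prof$activity[prof$step == 0] == 0))
})

test_that("population MI summary pools batches and reports exclusions", {
  net <- small_net(seed = 93)
  set.seed(93)
  b1 <- evaluate_batch(net, "trace", 4, n_stimuli = 30, max_timesteps = 15)
  b2 <- evaluate_batch(net, "trace", 4, n_stimuli = 30, max_timesteps = 15)
  s <- population_mi_summary(list(b1, b2))
  expect_equal(s$n_units,
               nrow(batch_modulation(b1)) + nrow(batch_modulation(b2)))
  expect_equal(sum(s$histogram$count), s$n_units)
  expect_equal(s$mean_mi, mean(s$per_unit$mi))
})

test_that("untrained networks show no systematic modulation", {
  # compare mean fixed-point activity on target vs distractor positions
  # directly (an untrained network is almost never correct, so the
  # correct-trials-only batch machinery would have nothing to average)
  set.seed(94)
  net <- init_network(network_config())
  grid <- grid_spec(15, 15)
  tsum <- 0; dsum <- 0
  for (i in 1:80) {
    s <- make_trace_stimulus(5)
    st <- relax_network(net, s)
    tu <- (cell_id(s$target_path[, 1], s$target_path[, 2], grid) - 1) * 4 +
      s$cells[1:5, 3]
    du <- (cell_id(s$distractor_paths[[1]][, 1],
                   s$distractor_paths[[1]][, 2], grid) - 1) * 4 +
      s$cells[6:10, 3]
    tsum <- tsum + mean(st$Y0[tu]); dsum <- dsum + mean(st$Y0[du])
  }
  expect_lt(abs(modulation_index(tsum / 80, dsum / 80)), 0.1)
})
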