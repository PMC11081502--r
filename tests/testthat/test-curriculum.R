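test_that("curriculum stage plans follow the task protocols", {
  cc <- curriculum_config("trace")
  expect_equal(cc$stages$length, 2:9)
  expect_equal(cc$stages$n_distractors, c(0L, rep(1L, 7)))
  expect_equal(cc$criterion, 0.85)
  expect_equal(cc$test_trials, 500L)

  cc <- curriculum_config("search_then_trace")
  expect_equal(cc$stages$task[1], "trace")       # blue-red pair first
  expect_equal(cc$stages$length[1], 2L)
  expect_true(all(cc$stages$task[-1] == "search_then_trace"))
  expect_equal(cc$stages$length[-1], 3:9)

  cc <- curriculum_config("trace_then_search")
  expect_equal(cc$stages$length, c(2:9, 9L))
  expect_equal(cc$stages$with_external, c(rep(FALSE, 8), TRUE))
})

test_that("test_phase is frozen: weights bit-identical before and after", {
  net <- small_net(seed = 100)
  w0 <- network_weights(net)
  set.seed(100)
  acc <- test_phase(net, "trace", length = 3, n_trials = 50)
  expect_identical(network_weights(net), w0)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_equal(attr(acc, "n"), 50L)
})

test_that("untrained networks score near chance on long curves", {
  set.seed(101)
  net <- init_network(network_config())
  acc <- test_phase(net, "trace", length = 9, n_trials = 100)
  expect_lt(acc, 0.3)  # 227 actions, two of them blue ends
})

test_that("curriculum bookkeeping: stage order, trial conservation, budget", {
  set.seed(102)
  net <- init_network(network_config())
  # tiny budget forces a clean failure, never an error
  cc <- curriculum_config("trace", max_total_trials = 1500L,
                          block_trials = 400L, test_trials = 60L)
  log <- run_curriculum(net, cc, learning_config())
  expect_false(log$learned)
  expect_lte(log$total_trials, 1500L)
  expect_equal(log$total_trials, sum(log$blocks$block_trials))
  # stages are visited in order and never skipped
  expect_true(all(diff(log$blocks$stage) %in% c(0L, 1L)))
  expect_equal(log$blocks$stage[1], 1L)
  # a stage is only left after a passing test
  advanced_after <- which(diff(log$blocks$stage) == 1L)
  expect_true(all(log$blocks$passed[advanced_after]))
  # tidy/glance accessors
  expect_s3_class(tidy(log), "tbl_df")
  g <- glance(log)
  expect_equal(g$total_trials, log$total_trials)
  expect_false(g$learned)
})

test_that("the first curriculum stage is learned quickly", {
  # red-blue pixel pairs: the network should pass the criterion within a
  # few thousand trials for most seeds
  passed <- 0L
  for (seed in 1:3) {
    set.seed(seed)
    net <- init_network(network_config())
    cc <- curriculum_config("trace", max_total_trials = 5000L)
    cc$stages <- cc$stages[1, ]
    log <- run_curriculum(net, cc, learning_config())
    passed <- passed + log$learned
  }
  expect_gte(passed, 2L)
})

test_that("generalization probe evaluates the requested lengths", {
  net <- small_net(seed = 103)
  set.seed(103)
  gen <- evaluate_generalization(net, "trace", trained_length = 3L,
                                 offsets = 0:1, n_trials = 30L)
  expect_equal(gen$length, c(3L, 4L))
  expect_true(all(gen$accuracy >= 0 & gen$accuracy <= 1))
})
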