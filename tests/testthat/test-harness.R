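test_that("checkpoints round-trip bit-exactly", {
  net <- small_net(seed = 110)
  path <- tempfile(fileext = ".json")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  w1 <- network_weights(net)
  w2 <- network_weights(net2)
  for (nm in names(w1)) expect_identical(w2[[nm]], w1[[nm]], label = nm)
  expect_equal(net2$config, net$config)
  # identical dynamics after the round trip
  set.seed(110)
  s <- make_trace_stimulus(4, grid = small_grid())
  expect_identical(network_q(net2, s), network_q(net, s))
  unlink(path)
})

test_that("corrupt or truncated checkpoints raise clean errors", {
  net <- small_net(seed = 111)
  path <- tempfile(fileext = ".json")
  save_checkpoint(net, path)
  txt <- readLines(path, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 500), path)
  expect_error(load_checkpoint(path), "corrupt|parse|unexpected")
  writeLines('{"format": "something-else"}', path)
  expect_error(load_checkpoint(path), "not a visroutines checkpoint")
  unlink(path)
})

test_that("bundles store networks, logs and a manifest that ties them", {
  net <- small_net(seed = 112)
  dir <- tempfile("bundle")
  logs <- list(trials = tibble::tibble(trial = 1:3, reward = c(1, 0, 1)))
  save_bundle(list(net_a = net), logs = logs,
              info = list(seeds = c(112L), task = "trace"), path = dir)
  b <- load_bundle(dir)
  expect_equal(names(b$nets), "net_a")
  expect_equal(b$manifest$info$seeds, 112L)
  expect_equal(nrow(b$logs$trials), 3L)
  expect_identical(network_weights(b$nets$net_a), network_weights(net))
  expect_error(load_bundle(tempfile()), "manifest")
  unlink(dir, recursive = TRUE)
})

test_that("reports compare obtained statistics against reference bands", {
  refs <- reference_values()
  expect_true(all(c("trace_trials", "mean_mi") %in% refs$quantity))
  expect_true(all(refs$band_lo < refs$reference & refs$reference < refs$band_hi))
})

test_that("experiment recipes run end to end and report against references", {
  rep1 <- reproduce_experiment("trace_training", scale = 1L, seed = 5L,
                               max_total_trials = 1500L)
  expect_s3_class(rep1, "vr_report")
  expect_true("trace_trials" %in% rep1$quantity)
  expect_equal(rep1$reference[rep1$quantity == "trace_trials"], 19000)
  expect_false(is.na(rep1$within_band[1]))
  expect_length(attr(rep1, "seeds"), 1L)
  # same seed, same report
  rep2 <- reproduce_experiment("trace_training", scale = 1L, seed = 5L,
                               max_total_trials = 1500L)
  expect_equal(rep1$value, rep2$value)
})

test_that("network tidiers summarize weights and architecture", {
  net <- small_net(seed = 113)
  g <- glance(net)
  expect_equal(g$n_actions, 27L)
  expect_equal(g$height, 5L)
  td <- tidy(net)
  expect_equal(sum(td$tensor == "Win"), 27L * 102L)
  expect_equal(g$n_weights, nrow(td))
})
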