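test_that("weight initialization follows the prescribed ranges", {
  cfg <- network_config()
  set.seed(1)
  w <- init_weights(cfg)
  for (nm in c("V1", "V2", "T0", "T1", "U1", "U2", "Hg")) {
    expect_true(all(w[[nm]] >= 0 & w[[nm]] <= 0.1), info = nm)
  }
  # last hidden -> output: same-RF positive, cross-RF negative
  A <- 227L; C <- 4L
  wh <- matrix(w$Whid, nrow = A)  # column k = hidden unit, row = action
  cells <- rep(1:225, each = C)
  same <- wh[cbind(cells, seq_len(900))]
  expect_true(all(same >= 0 & same <= 0.1))
  cross <- wh[cbind(ifelse(cells == 1L, 2L, 1L), seq_len(900))]
  expect_true(all(cross >= -0.01 & cross <= 0))
})

test_that("per-position kernels with tied values reproduce shared dynamics", {
  cfg_s <- network_config(height = 7, width = 7)
  cfg_n <- network_config(height = 7, width = 7, weight_sharing = FALSE)
  set.seed(3)
  ws <- init_weights(cfg_s)
  wn <- init_weights(cfg_n)
  for (nm in c("V1", "V2", "T0", "T1", "U1", "U2", "Hg"))
    wn[[nm]] <- rep(ws[[nm]], times = 49)  # tie every position to one kernel
  for (nm in c("Hx2g", "Hg2x", "Fskip", "Whid", "Win")) wn[[nm]] <- ws[[nm]]
  net_s <- init_network(cfg_s, weights = ws)
  net_n <- init_network(cfg_n, weights = wn)
  set.seed(4)
  s <- make_trace_stimulus(6, grid = grid_spec(7, 7))
  st_s <- relax_network(net_s, s)
  st_n <- relax_network(net_n, s)
  expect_equal(st_n$q, st_s$q, tolerance = 1e-14)
  expect_equal(st_n$Y0, st_s$Y0, tolerance = 1e-14)
  expect_equal(st_n$t_converged, st_s$t_converged)
})

test_that("blank input converges immediately to the all-zero state", {
  net <- small_net()
  blank <- list(cells = matrix(integer(0), 0, 3), values = numeric(0),
                extras = c(0, 0), correct = 0L)
  st <- relax_network(net, blank)
  expect_true(st$converged)
  expect_equal(st$t_converged, 1L)
  expect_true(all(st$Y0 == 0) && all(st$Y1 == 0) && all(st$Y2 == 0))
  expect_true(all(st$q == 0))
})

test_that("relaxation is deterministic and settled states are fixed points", {
  net <- small_net()
  set.seed(5)
  s <- make_trace_stimulus(5, grid = small_grid())
  a <- relax_network(net, s)
  b <- relax_network(net, s)
  expect_identical(a$Y0, b$Y0)
  expect_identical(a$q, b$q)
  expect_true(a$converged)
  # one extra step changes nothing beyond the tolerance
  again <- relax_network(net, s, max_timesteps = a$t_converged + 1)
  expect_equal(again$Y0, a$Y0, tolerance = 1e-8)
})

test_that("gating confines recurrent activity to stimulated units", {
  cfg <- network_config()
  set.seed(6)
  net <- init_network(cfg)
  for (i in 1:10) {
    s <- make_trace_stimulus(sample(2:9, 1),
                             n_distractors = sample(0:2, 1))
    st <- relax_network(net, s, record_traj = TRUE)
    # at every timestep, zero feedforward activity implies zero recurrent
    expect_true(all(st$traj[, st$X0 == 0] == 0))
    expect_true(all(st$Y1[st$X1 == 0] == 0))
    expect_true(all(st$Y2[st$X2 == 0] == 0))
    expect_true(all(st$Y0 >= 0) && all(st$Y1 >= 0) && all(st$Y2 >= 0))
  }
})

test_that("Q readout is linear in the recurrent activities", {
  net <- small_net()
  set.seed(7)
  s <- make_trace_stimulus(4, grid = small_grid())
  st <- relax_network(net, s)
  expect_length(st$q, 27L)  # 5*5 grid + 2 extra actions
  # doubling all readout weights doubles Q
  w <- network_weights(net)
  w2 <- w; w2$Win <- 2 * w2$Win; w2$Whid <- 2 * w2$Whid
  set_network_weights(net, w2)
  st2 <- relax_network(net, s)
  expect_equal(st2$q, 2 * st$q, tolerance = 1e-12)
  set_network_weights(net, w)
})

test_that("action selection is greedy, tie-broken low, and Boltzmann-explores", {
  expect_equal(select_action(c(0.1, 0.9, 0.3), epsilon = 0)$action, 2L)
  expect_equal(select_action(c(0.5, 0.9, 0.9), epsilon = 0)$action, 2L)
  expect_equal(select_action(c(0.7, 0.7), epsilon = 0)$action, 1L)
  expect_equal(select_action(c(0.1, 0.9, 0.3), epsilon = 0)$q_a, 0.9)
  # epsilon = 1, equal Q: uniform over actions
  set.seed(8)
  draws <- replicate(3000, select_action(c(0, 0, 0), epsilon = 1)$action)
  expect_true(all(abs(table(draws) / 3000 - 1 / 3) < 0.05))
  # epsilon = 1, Q = (1, 0): P(a1) = e/(e+1)
  draws <- replicate(4000, select_action(c(1, 0), epsilon = 1)$action)
  expect_equal(mean(draws == 1L), exp(1) / (exp(1) + 1), tolerance = 0.03)
})

test_that("relaxation converges on random stimuli at random weights", {
  # the damped dynamics settle reliably, though often later than the
  # 50-timestep behavioral cap at which actions are selected
  set.seed(9)
  net <- init_network(network_config())
  n_conv <- 0L
  for (i in 1:100) {
    s <- make_trace_stimulus(sample(2:9, 1))
    st <- relax_network(net, s, max_timesteps = 300)
    n_conv <- n_conv + st$converged
  }
  expect_gte(n_conv, 99L)
})
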