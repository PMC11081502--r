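test_that("reward-prediction error is r minus the chosen Q-value", {
  expect_equal(reward_prediction_error(1, 0.2), 0.8)
  expect_equal(reward_prediction_error(0, 0.5), -0.5)
  expect_equal(reward_prediction_error(0.3, 0.3), 0)
})

test_that("accessory activities equal finite-difference fixed-point gradients", {
  # feedforward-stream credit: perturb x_i at the fixed point, re-relax,
  # and compare dQ_a/dx_i with the accessory activity of unit i
  lcfg <- learning_config(acc_steps = 500, acc_tol = 1e-13)
  set.seed(20)
  for (rep in 1:3) {
    net <- small_net(seed = 20 + rep)
    s <- make_trace_stimulus(4, grid = small_grid())
    enc <- encode_stimulus(s)
    st <- relax_network(net, s)
    a <- which.max(st$q)
    acc <- accessory_state(net, s, a, lcfg)
    h <- 1e-6
    for (layer in 1:2) {
      X <- if (layer == 1) st$X1 else st$X2
      accX <- if (layer == 1) acc$accX1 else acc$accX2
      units <- order(abs(accX), decreasing = TRUE)[1:5]
      units <- units[X[units] > 0]
      for (u in units) {
        qp <- cpp_relax(net$ptr, enc$cells, enc$values, enc$extras, 400,
                        1e-12, FALSE, FALSE, FALSE,
                        c(layer, u - 1L, h), numeric(0))$q[a]
        qm <- cpp_relax(net$ptr, enc$cells, enc$values, enc$extras, 400,
                        1e-12, FALSE, FALSE, FALSE,
                        c(layer, u - 1L, -h), numeric(0))$q[a]
        fd <- (qp - qm) / (2 * h)
        expect_equal(accX[u], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("recurrent-stream credit matches an injected-current oracle", {
  # add a constant current h to a recurrent unit's pre-activation during
  # relaxation; dQ_a/dh equals sigma'(pre) times the adjoint S of that unit
  lcfg <- learning_config(acc_steps = 500, acc_tol = 1e-13)
  net <- small_net(seed = 31)
  set.seed(31)
  s <- make_trace_stimulus(5, grid = small_grid())
  enc <- encode_stimulus(s)
  st <- relax_network(net, s)
  a <- which.max(st$q)
  acc <- accessory_state(net, s, a, lcfg)
  h <- 1e-6
  for (layer in 0:2) {
    S <- list(acc$S0, acc$S1, acc$S2)[[layer + 1]]
    pre <- list(st$preY0, st$preY1, st$preY2)[[layer + 1]]
    phi <- switch(layer + 1, st$X0, st$X1, st$X2)
    units <- order(abs(S), decreasing = TRUE)[1:4]
    units <- units[phi[units] > 0]
    for (u in units) {
      qp <- cpp_relax(net$ptr, enc$cells, enc$values, enc$extras, 400, 1e-12,
                      FALSE, FALSE, FALSE, numeric(0), c(layer, u - 1L, h))$q[a]
      qm <- cpp_relax(net$ptr, enc$cells, enc$values, enc$extras, 400, 1e-12,
                      FALSE, FALSE, FALSE, numeric(0), c(layer, u - 1L, -h))$q[a]
      fd <- (qp - qm) / (2 * h)
      expect_equal(sigma_prime(pre[u]) * S[u], fd, tolerance = 1e-4)
    }
  }
})

test_that("per-weight gradients equal finite differences in every family", {
  lcfg <- learning_config(acc_steps = 500, acc_tol = 1e-13)
  net <- small_net(seed = 40)
  set.seed(40)
  s <- make_trace_stimulus(4, grid = small_grid())
  st <- relax_network(net, s)
  a <- which.max(st$q)
  gr <- q_gradients(net, s, a, lcfg)
  for (nm in c("V1", "V2", "T0", "T1", "U1", "U2", "Hg", "Whid", "Win")) {
    g <- gr[[nm]]
    nz <- which(g != 0)
    if (length(nz) == 0L) next
    idx <- nz[order(abs(g[nz]), decreasing = TRUE)][1:min(4, length(nz))]
    fd <- fd_weight_grad(net, s, a, nm, idx)
    expect_equal(g[idx], fd, tolerance = 1e-3, info = nm)
  }
  # the dense skip projection participates when enabled
  net2 <- init_network(network_config(height = 5, width = 5,
                                      dense_skip_feedback = TRUE,
                                      convergence_tol = 1e-12,
                                      max_timesteps = 400), seed = 41)
  set.seed(41)
  s2 <- make_trace_stimulus(4, grid = small_grid())
  st2 <- relax_network(net2, s2)
  a2 <- which.max(st2$q)
  gr2 <- q_gradients(net2, s2, a2, lcfg)
  nz <- which(gr2$Fskip != 0)
  idx <- nz[order(abs(gr2$Fskip[nz]), decreasing = TRUE)][1:4]
  fd <- fd_weight_grad(net2, s2, a2, "Fskip", idx)
  expect_equal(gr2$Fskip[idx], fd, tolerance = 1e-3)
})

test_that("gradients stay exact without weight sharing and through the cue links", {
  lcfg <- learning_config(acc_steps = 500, acc_tol = 1e-13)
  # per-position kernels
  net <- small_net(seed = 45, weight_sharing = FALSE)
  set.seed(45)
  s <- make_trace_stimulus(4, grid = small_grid())
  st <- relax_network(net, s)
  a <- which.max(st$q)
  gr <- q_gradients(net, s, a, lcfg)
  for (nm in c("V1", "Hg", "U2")) {
    nz <- which(gr[[nm]] != 0)
    idx <- nz[order(abs(gr[[nm]][nz]), decreasing = TRUE)][1:3]
    fd <- fd_weight_grad(net, s, a, nm, idx)
    expect_equal(gr[[nm]][idx], fd, tolerance = 1e-3, info = nm)
  }
  # extra-unit color links, active in the cued search task
  net2 <- small_net(seed = 46)
  set.seed(46)
  s2 <- make_search_then_trace_stimulus(3, grid = small_grid())
  st2 <- relax_network(net2, s2)
  a2 <- which.max(st2$q)
  gr2 <- q_gradients(net2, s2, a2, lcfg)
  for (nm in c("Hx2g", "Hg2x")) {
    nz <- which(gr2[[nm]] != 0)
    expect_gt(length(nz), 0)
    idx <- nz[order(abs(gr2[[nm]][nz]), decreasing = TRUE)][1:3]
    fd <- fd_weight_grad(net2, s2, a2, nm, idx)
    expect_equal(gr2[[nm]][idx], fd, tolerance = 1e-3, info = nm)
  }
})

test_that("update equals learning_rate * delta * gradient (four factors only)", {
  net <- small_net(seed = 50)
  set.seed(50)
  s <- make_trace_stimulus(4, grid = small_grid())
  lcfg <- learning_config(epsilon = 0, acc_steps = 300, acc_tol = 1e-12)
  st <- relax_network(net, s)
  a <- which.max(st$q)
  gr <- q_gradients(net, s, a, lcfg)
  w0 <- network_weights(net)
  rec <- learning_trial(net, s, lcfg)
  expect_equal(rec$action, a)
  w1 <- network_weights(net)
  f <- lcfg$learning_rate * rec$delta
  excit <- c("Hg", "Hx2g", "Hg2x", "T0", "T1", "U1", "U2")
  for (nm in names(w0)) {
    expected <- w0[[nm]] + f * gr[[nm]]
    if (nm %in% excit) expected <- pmax(expected, 0)
    expect_equal(w1[[nm]], expected, tolerance = 1e-10, info = nm)
  }
  # the update direction is the (negative) gradient of 1/2 delta^2
  expect_equal(-rec$delta * gr$Win, (w0$Win - w1$Win) / lcfg$learning_rate,
               tolerance = 1e-10)
})

test_that("no credit means no change, and learn = FALSE changes nothing", {
  net <- small_net(seed = 60)
  set.seed(60)
  s <- make_trace_stimulus(4, grid = small_grid())
  w0 <- network_weights(net)
  rec <- learning_trial(net, s, learn = FALSE)
  expect_identical(network_weights(net), w0)
  st <- relax_network(net, s)
  a <- which.max(st$q)
  gr <- q_gradients(net, s, a)
  # synapses whose postsynaptic accessory activity is zero receive no update
  acc <- accessory_state(net, s, a)
  zero_post <- which(acc$acc0 == 0)
  if (length(zero_post) > 0) {
    NG <- 5 * 5 * 4
    rows <- zero_post[zero_post <= NG + 2]
    idx <- as.vector(outer((rows - 1) * NG, 1:NG, "+"))
    expect_true(all(gr$Fskip[idx] == 0))
  }
})

test_that("repeated training on one stimulus drives Q toward the reward", {
  net <- small_net(seed = 70)
  set.seed(70)
  s <- make_trace_stimulus(2, n_distractors = 0, grid = small_grid())
  lcfg <- learning_config(epsilon = 0)
  deltas <- numeric(200)
  for (i in 1:200) deltas[i] <- learning_trial(net, s, lcfg)$delta
  q <- network_q(net, s)
  expect_equal(which.max(q), s$correct_action)
  expect_lt(abs(deltas[200]), 0.05)
  expect_gt(q[s$correct_action], 0.9)
})

test_that("accessory credit enters through the transposed readout", {
  net <- small_net(seed = 80)
  w <- network_weights(net)
  # the accessory sweep runs top-down; after one step the top hidden
  # layer's accessory activity is exactly the (damped, gated) transposed
  # readout weight of the chosen action — the seed of the credit flow
  set.seed(80)
  s <- make_trace_stimulus(3, grid = small_grid())
  st <- relax_network(net, s)
  a <- which.max(st$q)
  acc1 <- accessory_state(net, s, a, learning_config(acc_steps = 1))
  A <- 27L
  damp <- net$config$relax_damping
  active2 <- which(st$X2 > 0)
  for (u in active2) {
    gate <- gate_phi(st$X2[u], monotone = net$config$monotone_gate)
    expect_equal(acc1$acc2[u], damp * gate * w$Whid[(u - 1) * A + a],
                 tolerance = 1e-12)
  }
  # units with no stimulus support carry no credit at any point
  expect_true(all(acc1$acc0[st$X0 == 0] == 0))
  expect_true(all(acc1$acc2[st$X2 == 0] == 0))
})
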