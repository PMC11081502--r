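#' Piecewise activation function of the network
#'
#' Identity for inputs between 0 and the knee at 6, zero below 0, and
#' logarithmic above the knee: `log(1.5 x + 1) + 6 - log(10)` (natural
#' logarithm; the constant makes the function continuous at the knee).
#' Unbounded growth keeps long target and distractor curves distinguishable
#' while the shrinking slope keeps the recurrent dynamics convergent.
#'
#' @param x Pre-activation (numeric vector).
#' @return Activity, same shape as `x`.
#' @examples
#' sigma(c(-3, 3, 6, 10))
#' @export
sigma <- function(x) {
  out <- pmax(x, 0)
  hi <- which(x > 6)
  out[hi] <- log(1.5 * x[hi] + 1) + 6 - log(10)
  out
}

#' Derivative of the activation function
#'
#' Zero for `x <= 0` (the value at exactly 0 is defined as 0), one on the
#' identity branch, and `1.5 / (1.5 x + 1)` beyond the knee.
#'
#' @inheritParams sigma
#' @return Derivative, same shape as `x`.
#' @export
sigma_prime <- function(x) {
  out <- as.numeric(x > 0)
  hi <- which(x > 6)
  out[hi] <- 1.5 / (1.5 * x[hi] + 1)
  out
}

#' Gating function applied to feedforward activity
#'
#' `phi(x) = 100 x / (1 + (100 x)^2)`, a continuous step approximation that
#' is exactly zero for silent feedforward units and positive for active
#' ones, so response modulation cannot spread to units whose feature is
#' absent from the image. As printed the function is non-monotone (peak 0.5
#' at x = 0.01); `monotone = TRUE` selects the saturating alternative
#' `100 x / (1 + 100 x)`.
#'
#' @param x Feedforward activity (non-negative numeric vector).
#' @param monotone Use the monotone saturating variant.
#' @return Gate value, same shape as `x`.
#' @examples
#' gate_phi(c(0, 0.01, 1))
#' @export
gate_phi <- function(x, monotone = FALSE) {
  u <- 100 * x
  if (monotone) u / (1 + u) else u / (1 + u^2)
}

#' Derivative of the gating function
#'
#' @inheritParams gate_phi
#' @return Derivative, same shape as `x`.
#' @export
gate_phi_prime <- function(x, monotone = FALSE) {
  u <- 100 * x
  if (monotone) 100 / (1 + u)^2 else 100 * (1 - u^2) / (1 + u^2)^2
}

#' Network configuration
#'
#' Architecture and dynamics parameters of the two-stream network: a
#' feedforward group that registers features and a recurrent group, gated
#' multiplicatively by the feedforward group, that carries the task-driven
#' response modulation. Two hidden layers of four features sit between the
#' input layer (four color channels per cell plus two extra units) and a
#' 227-action readout (225 grid positions + 2 extra units on the default
#' grid). All 3x3 kernels are masked to the Von Neumann neighborhood.
#'
#' @param height,width Grid dimensions (default 15 x 15).
#' @param max_timesteps Relaxation cap; the action is selected once activity
#'   settles, but never later than this (default 50).
#' @param convergence_tol Maximum absolute activity change below which the
#'   state counts as settled (default 1e-5).
#' @param epsilon Exploration rate of the epsilon-greedy policy (default
#'   0.05); exploratory actions are drawn from the Boltzmann distribution of
#'   the Q-values.
#' @param weight_sharing Share convolution kernels across grid positions
#'   (default `TRUE`); with `FALSE` every position owns its kernel taps.
#' @param dense_skip_feedback Dense feedback from the last hidden layer to
#'   the recurrent input layer (default `FALSE`). The last hidden layer is
#'   always fully connected to the output layer, and the recurrent input
#'   layer projects fully to the output layer; with this flag it also feeds
#'   back densely onto the recurrent input layer. The dense feedback gives
#'   every grid position one-step access to global context, which lets
#'   networks bypass the serial spread of enhanced activity, so it is off by
#'   default.
#' @param grid_lateral Include the masked 3x3 lateral kernel within the
#'   recurrent input layer, in addition to the dense color links between the
#'   extra units and the grid (default `TRUE`).
#' @param monotone_gate Gate form. `TRUE` (default) uses the monotone step
#'   approximation `100x / (1 + 100x)`, which passes active units' recurrent
#'   input at full strength; `FALSE` uses the non-monotone bump
#'   `100x / (1 + (100x)^2)`, which attenuates it roughly 100-fold at
#'   one-hot inputs — networks then solve the tasks through minute activity
#'   differences amplified by large readout weights instead of through the
#'   pronounced response modulation the step gate produces.
#' @param excitatory_recurrent Keep all recurrent-stream kernels (lateral H,
#'   recurrent feedforward T, feedback U, and the extra-unit color links)
#'   non-negative by clipping them at zero after every update (default
#'   `TRUE`). Purely facilitatory recurrent coupling means task-driven
#'   modulation can only enhance activity above the base representation —
#'   the labeling scheme observed in visual cortex — while the competition
#'   between eye-movement targets is carried by the signed readout weights.
#'   With `FALSE` learning reliably discovers the mirror-image solution that
#'   labels the target curve by suppression.
#' @param relax_damping Leaky update factor `alpha` in `(0, 1]` for both
#'   relaxations: `y <- (1 - alpha) y + alpha sigma(pre)` (default 0.5).
#'   Damping leaves every fixed point unchanged but removes the period-2
#'   flip-flops that the delayed winner-take-all feedback otherwise
#'   develops in trained networks; `1` recovers the undamped map.
#' @param feedforward_drive Additive drive from each feedforward unit to its
#'   recurrent twin: `"input"` (default) drives only the recurrent input
#'   layer, so the hidden recurrent stream carries pure task-driven
#'   modulation on top of the retinotopic base representation; `"all"`
#'   drives every layer; `"none"` is the purely multiplicative reading, in
#'   which the all-zero recurrent state is the attractor at small initial
#'   weights, no activity survives relaxation, and no learning signal
#'   exists. Logical values are accepted (`TRUE` = `"all"`, `FALSE` =
#'   `"none"`).
#' @param readout_stream Which stream the linear Q readout taps:
#'   `"recurrent"` (default; the modulated activity) or `"feedforward"`.
#' @return A `vr_network_config` object.
#' @export
network_config <- function(height = 15L, width = 15L, max_timesteps = 50L,
                           convergence_tol = 1e-5, epsilon = 0.05,
                           weight_sharing = TRUE, dense_skip_feedback = FALSE,
                           grid_lateral = TRUE, monotone_gate = TRUE,
                           feedforward_drive = "input",
                           excitatory_recurrent = TRUE, relax_damping = 0.5,
                           readout_stream = c("recurrent", "feedforward")) {
  stopifnot(epsilon >= 0, epsilon <= 1, max_timesteps >= 1L,
            convergence_tol > 0, relax_damping > 0, relax_damping <= 1)
  readout_stream <- match.arg(readout_stream)
  if (is.logical(feedforward_drive))
    feedforward_drive <- if (feedforward_drive) "all" else "none"
  feedforward_drive <- match.arg(feedforward_drive,
                                 c("input", "all", "none"))
  grid <- grid_spec(height, width)
  structure(
    list(height = grid$height, width = grid$width, n_colors = grid$n_colors,
         n_hidden_layers = 2L, features_per_layer = grid$n_colors,
         max_timesteps = as.integer(max_timesteps),
         convergence_tol = convergence_tol, epsilon = epsilon,
         weight_sharing = isTRUE(weight_sharing),
         dense_skip_feedback = isTRUE(dense_skip_feedback),
         grid_lateral = isTRUE(grid_lateral),
         monotone_gate = isTRUE(monotone_gate),
         feedforward_drive = feedforward_drive,
         excitatory_recurrent = isTRUE(excitatory_recurrent),
         relax_damping = relax_damping,
         readout_stream = readout_stream),
    class = "vr_network_config"
  )
}

#' @export
print.vr_network_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<vr_network_config> %dx%d grid, 2 hidden layers x %d features\n",
    "  max_timesteps=%d, tol=%g, epsilon=%g, weight_sharing=%s,\n",
    "  dense_skip_feedback=%s, grid_lateral=%s, readout=%s\n"),
    x$height, x$width, x$features_per_layer, x$max_timesteps,
    x$convergence_tol, x$epsilon, x$weight_sharing, x$dense_skip_feedback,
    x$grid_lateral, x$readout_stream))
  invisible(x)
}

n_actions <- function(cfg) cfg$height * cfg$width + 2L

kernel_length <- function(cfg) {
  k <- 5L * cfg$n_colors^2
  if (cfg$weight_sharing) k else cfg$height * cfg$width * k
}

#' Initialize network weights
#'
#' All convolution kernel taps (feedforward V, recurrent-stream feedforward
#' T, feedback U, lateral H) are drawn from U(0, 0.1); the corner taps of
#' every 3x3 kernel are structurally zero (Von Neumann mask). The dense
#' projections (last hidden to output and to the recurrent input layer, and
#' the input-layer readout) use U(0, 0.1) between units sharing a receptive
#' field and U(-0.01, 0) across receptive fields, biasing a winner-take-all
#' competition in the output layer.
#'
#' @param cfg A [network_config()].
#' @return Named list of weight vectors (a `vr_weights` object).
#' @export
init_weights <- function(cfg) {
  C <- cfg$n_colors; P <- cfg$height * cfg$width
  NG <- P * C; N0 <- NG + 2L; A <- n_actions(cfg)
  klen <- kernel_length(cfg)
  kern <- function() runif(klen, 0, 0.1)
  w <- list(V1 = kern(), V2 = kern(), T0 = kern(), T1 = kern(),
            U1 = kern(), U2 = kern(), Hg = kern(),
            Hx2g = runif(2L * NG, 0, 0.1), Hg2x = runif(NG * 2L, 0, 0.1))
  # dense projections: same-RF entries positive, cross-RF entries negative
  cells <- rep(0:(P - 1L), each = C)           # cell of each grid unit
  # last hidden -> recurrent input layer [j * NG + k], j in layer 0
  fs <- runif(N0 * NG, -0.01, 0)
  j_grid <- rep(0:(NG - 1L), each = C)
  k_same <- cells[j_grid + 1L] * C + rep(0:(C - 1L), times = NG)
  fs[j_grid * NG + k_same + 1L] <- runif(NG * C, 0, 0.1)
  w$Fskip <- fs
  # last hidden -> output [k * A + a]
  wh <- runif(NG * A, -0.01, 0)
  idx <- (0:(NG - 1L)) * A + cells + 1L
  wh[idx] <- runif(NG, 0, 0.1)
  w$Whid <- wh
  # recurrent input layer -> output [j * A + a]
  wi <- runif(N0 * A, -0.01, 0)
  idx <- (0:(NG - 1L)) * A + cells + 1L
  wi[idx] <- runif(NG, 0, 0.1)
  wi[NG * A + P + 1L] <- runif(1L, 0, 0.1)          # red extra unit
  wi[(NG + 1L) * A + P + 2L] <- runif(1L, 0, 0.1)   # brown extra unit
  w$Win <- wi
  structure(w, class = "vr_weights")
}

#' Create a network
#'
#' Builds the simulation engine for a gated two-stream recurrent network.
#' The returned object has reference semantics: learning functions such as
#' [learning_trial()] and [run_curriculum()] update its weights in place,
#' while evaluation functions ([test_phase()], [relax_network()]) leave them
#' untouched.
#'
#' @param cfg A [network_config()].
#' @param weights Optional `vr_weights`; drawn by [init_weights()] when
#'   omitted.
#' @param seed Optional integer seed applied before drawing the weights.
#' @return A `relearnn_network` object.
#' @examples
#' net <- init_network(seed = 1)
#' net
#' @export
init_network <- function(cfg = network_config(), weights = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- init_weights(cfg)
  ptr <- cpp_net_create(cfg, weights)
  structure(list(ptr = ptr, config = cfg, seed = seed),
            class = "relearnn_network")
}

#' @export
print.relearnn_network <- function(x, ...) {
  cat(sprintf(
    "<relearnn_network> %dx%d grid, %d actions, readout=%s, sharing=%s\n",
    x$config$height, x$config$width, n_actions(x$config),
    x$config$readout_stream, x$config$weight_sharing))
  invisible(x)
}

#' Extract or replace network weights
#'
#' @param net A `relearnn_network`.
#' @return `network_weights()` returns a `vr_weights` list.
#' @export
network_weights <- function(net) {
  stopifnot(inherits(net, "relearnn_network"))
  structure(cpp_net_weights(net$ptr), class = "vr_weights")
}

#' @rdname network_weights
#' @param weights A `vr_weights` list of matching shapes.
#' @export
set_network_weights <- function(net, weights) {
  stopifnot(inherits(net, "relearnn_network"))
  cpp_net_set_weights(net$ptr, weights)
  invisible(net)
}

#' Relax the network to its fixed point on a stimulus
#'
#' The input activities are clamped, the feedforward sweep runs once, the
#' recurrent activities are seeded at the base representation (Y = X) and
#' then iterate until the largest absolute change drops below the
#' convergence tolerance or the timestep cap is hit. Non-convergence is
#' reported through the `converged` flag, never as an error.
#'
#' @param net A `relearnn_network`.
#' @param stim A `vr_stimulus` (or the result of [encode_stimulus()]).
#' @param max_timesteps,tol Override the configured relaxation cap and
#'   tolerance.
#' @param record_traj Keep the recurrent input-layer activity at every
#'   timestep (matrix `timesteps x units`, row 1 = the base representation).
#' @param record_q Keep the readout (Q) trajectory alongside.
#' @return A `vr_fixed_point` list: `q` (one value per action), `converged`,
#'   `t_converged`, the activity vectors of both streams in all layers, and
#'   optionally `traj` / `q_traj`.
#' @export
relax_network <- function(net, stim, max_timesteps = NULL, tol = NULL,
                          record_traj = FALSE, record_q = FALSE) {
  stopifnot(inherits(net, "relearnn_network"))
  enc <- if (inherits(stim, "vr_stimulus")) encode_stimulus(stim) else stim
  cfg <- net$config
  out <- cpp_relax(net$ptr, enc$cells, enc$values, enc$extras,
                   max_timesteps %||% cfg$max_timesteps,
                   tol %||% cfg$convergence_tol,
                   isTRUE(record_traj), isTRUE(record_q), TRUE,
                   numeric(0), numeric(0))
  structure(out, class = "vr_fixed_point")
}

#' Q-values of a stimulus
#'
#' Linear readout over the settled activities: the last hidden layer and the
#' recurrent input layer project densely onto one output unit per selectable
#' position (grid cells in row-major order, then the red and brown extra
#' units).
#'
#' @inheritParams relax_network
#' @return Numeric vector of Q-values, one per action.
#' @export
network_q <- function(net, stim, max_timesteps = NULL, tol = NULL) {
  relax_network(net, stim, max_timesteps, tol)$q
}

#' Select an action from Q-values
#'
#' With probability `1 - epsilon` the action with the highest Q-value is
#' chosen (ties broken towards the lowest index); with probability `epsilon`
#' an action is sampled from the Boltzmann distribution
#' `P(a) = exp(Q_a) / sum_k exp(Q_k)` (computed with max subtraction).
#'
#' @param q Numeric vector of Q-values.
#' @param epsilon Exploration rate in `[0, 1]`.
#' @return List with `action` (index into `q`) and `q_a` (its Q-value).
#' @examples
#' select_action(c(0.1, 0.9, 0.3), epsilon = 0)
#' @export
select_action <- function(q, epsilon = 0) {
  stopifnot(is.numeric(q), length(q) >= 1L, all(is.finite(q)),
            epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && runif(1L) < epsilon) {
    w <- exp(q - max(q))
    a <- sample.int(length(q), 1L, prob = w)
  } else {
    a <- which.max(q)
  }
  list(action = a, q_a = q[a])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
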