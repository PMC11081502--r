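#' Learning configuration for RELEARNN
#'
#' RELEARNN runs three phases per trial: (1) the stimulus is presented and
#' the regular network relaxes to a fixed point; (2) an action is selected
#' and the corresponding accessory output unit initiates a relaxation of the
#' accessory (credit-assignment) network, whose connections are the
#' transposed regular connections, so each accessory activity converges to
#' the influence of its regular unit on the chosen Q-value; (3) the reward
#' arrives, the globally broadcast reward-prediction error `delta = r - Q_a`
#' gates a four-factor Hebbian update
#' `dw_ij = lr * delta * x_i * acc_j * sigma'(pre_j)`.
#'
#' @param learning_rate Step size of the weight update (default 0.02).
#' @param acc_steps Accessory relaxation steps (default 50; the relaxation
#'   exits early once the largest change drops below `acc_tol`).
#' @param acc_tol Early-exit tolerance of the accessory relaxation.
#' @param include_gate_path Let credit flow into the feedforward stream
#'   through the gate derivative (default `TRUE`; without it the feedforward
#'   kernels receive no learning signal under the recurrent readout).
#' @param epsilon Exploration rate used during learning trials.
#' @return A `vr_learning_config` object.
#' @export
learning_config <- function(learning_rate = 0.02, acc_steps = 50L,
                            acc_tol = 1e-8, include_gate_path = TRUE,
                            epsilon = 0.05) {
  stopifnot(learning_rate > 0, acc_steps >= 1L, epsilon >= 0, epsilon <= 1)
  structure(
    list(learning_rate = learning_rate, acc_steps = as.integer(acc_steps),
         acc_tol = acc_tol, include_gate_path = isTRUE(include_gate_path),
         epsilon = epsilon),
    class = "vr_learning_config"
  )
}

#' Reward-prediction error
#'
#' `delta = r - Q_a`: the difference between the obtained reward and the
#' Q-value of the chosen action, broadcast to every synapse as the
#' neuromodulatory factor of the update.
#'
#' @param r Reward (0 or 1 in these tasks).
#' @param q_a Q-value of the chosen action.
#' @return `r - q_a`.
#' @examples
#' reward_prediction_error(1, 0.2)
#' @export
reward_prediction_error <- function(r, q_a) r - q_a

#' Accessory (credit-assignment) state for a chosen action
#'
#' Relaxes the stimulus, seeds the accessory output unit of `action` with 1,
#' and iterates the accessory network: every regular connection j -> k is
#' mirrored by an accessory connection k -> j of identical strength, each
#' hop is weighted by the derivative of the target unit's activation at its
#' fixed-point pre-activation and, for recurrent units, by the gate value
#' that scaled the connection. At convergence the accessory activity of each
#' unit is proportional to the influence of that unit's fixed-point activity
#' on the chosen Q-value.
#'
#' @param net A `relearnn_network`.
#' @param stim A `vr_stimulus` or encoded stimulus.
#' @param action Chosen action (1-based).
#' @param lcfg A [learning_config()].
#' @param record Keep the accessory activity of the recurrent input layer at
#'   every accessory timestep.
#' @param max_timesteps,tol Relaxation overrides for phase 1.
#' @return A `vr_accessory` list: `acc0`, `acc1`, `acc2` (recurrent-stream
#'   accessory activities per layer), `accX0`, `accX1`, `accX2`
#'   (feedforward-stream credit), `n_steps`, `diverged`, and optionally
#'   `acc_traj`.
#' @export
accessory_state <- function(net, stim, action, lcfg = learning_config(),
                            record = FALSE, max_timesteps = NULL,
                            tol = NULL) {
  stopifnot(inherits(net, "relearnn_network"))
  enc <- if (inherits(stim, "vr_stimulus")) encode_stimulus(stim) else stim
  cfg <- net$config
  out <- cpp_accessory(net$ptr, enc$cells, enc$values, enc$extras,
                       as.integer(action) - 1L,
                       max_timesteps %||% cfg$max_timesteps,
                       tol %||% cfg$convergence_tol,
                       lcfg$acc_steps, lcfg$acc_tol,
                       lcfg$include_gate_path, isTRUE(record))
  structure(out, class = "vr_accessory")
}

#' Exact per-weight gradients of a chosen Q-value
#'
#' Returns `dQ_a / dw` for every weight tensor, assembled from the same
#' four local factors the update uses (presynaptic fixed-point activity,
#' postsynaptic accessory activity, and the postsynaptic activation
#' derivative); per-position contributions to shared kernel taps are summed.
#' The weight update of a trial equals `learning_rate * delta` times these
#' gradients.
#'
#' @inheritParams accessory_state
#' @return Named list of gradient vectors matching [network_weights()]
#'   shapes.
#' @export
q_gradients <- function(net, stim, action, lcfg = learning_config(),
                        max_timesteps = NULL, tol = NULL) {
  stopifnot(inherits(net, "relearnn_network"))
  enc <- if (inherits(stim, "vr_stimulus")) encode_stimulus(stim) else stim
  cfg <- net$config
  cpp_gradients(net$ptr, enc$cells, enc$values, enc$extras,
                as.integer(action) - 1L,
                max_timesteps %||% cfg$max_timesteps,
                tol %||% cfg$convergence_tol,
                lcfg$acc_steps, lcfg$acc_tol, lcfg$include_gate_path)
}

#' Run one RELEARNN trial
#'
#' Executes the full three-phase protocol on one stimulus: relax, select an
#' action (epsilon-greedy with Boltzmann exploration), propagate credit
#' through the accessory network, compute the reward-prediction error and
#' update the weights in place. With `learn = FALSE` the plasticity phases
#' are skipped and the weights stay untouched.
#'
#' @param net A `relearnn_network` (modified in place when `learn = TRUE`).
#' @param stim A `vr_stimulus` or encoded stimulus.
#' @param lcfg A [learning_config()].
#' @param learn Apply the weight update.
#' @param epsilon Override the exploration rate (e.g. 0 for test trials).
#' @param max_timesteps,tol Relaxation overrides.
#' @param record_traj Keep the recurrent input-layer trajectory.
#' @return A one-row [tibble::tibble()] (the trial record): `action`,
#'   `q_a`, `reward`, `delta`, `correct`, `explored`, `t_converged`,
#'   `converged`, `update_skipped`; the trajectory, when recorded, is
#'   attached as attribute `"traj"`.
#' @export
learning_trial <- function(net, stim, lcfg = learning_config(), learn = TRUE,
                           epsilon = NULL, max_timesteps = NULL, tol = NULL,
                           record_traj = FALSE) {
  stopifnot(inherits(net, "relearnn_network"))
  enc <- if (inherits(stim, "vr_stimulus")) encode_stimulus(stim) else stim
  cfg <- net$config
  out <- cpp_trial(net$ptr, enc$cells, enc$values, enc$extras, enc$correct,
                   epsilon %||% lcfg$epsilon, isTRUE(learn),
                   lcfg$learning_rate, lcfg$acc_steps, lcfg$acc_tol,
                   lcfg$include_gate_path,
                   max_timesteps %||% cfg$max_timesteps,
                   tol %||% cfg$convergence_tol, isTRUE(record_traj))
  rec <- tibble::tibble(
    action = out$action + 1L, q_a = out$q_a, reward = out$reward,
    delta = out$delta, correct = out$correct, explored = out$explored,
    t_converged = out$t_converged, converged = out$converged,
    update_skipped = out$update_skipped)
  if (!is.null(out$traj)) attr(rec, "traj") <- out$traj
  rec
}
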