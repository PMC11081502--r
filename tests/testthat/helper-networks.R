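# Shared fixtures.  Trained networks are expensive, so they are built once
# per test session and reused by every file that needs them.

options(testthat.progress.max_fails = Inf)

the_cache <- new.env(parent = emptyenv())

# a small randomly initialized network on a 5x5 grid for exact/oracle tests
small_net <- function(seed = 7, ...) {
  cfg <- network_config(height = 5, width = 5, convergence_tol = 1e-12,
                        max_timesteps = 400, ...)
  set.seed(seed)
  init_network(cfg)
}

small_grid <- function() grid_spec(5, 5)

# brute-force connected components of occupied cells under Von Neumann
# adjacency (independent oracle for stimulus-geometry invariants)
brute_components <- function(cells, grid) {
  n <- nrow(cells)
  if (n == 0L) return(integer(0))
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] &&
          abs(cells[i, 1L] - cells[j, 1L]) +
          abs(cells[i, 2L] - cells[j, 2L]) == 1L) {
        m <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# finite-difference d Q_a / d w via re-relaxation (central differences)
fd_weight_grad <- function(net, stim, action, name, idx, h = 1e-6) {
  w <- network_weights(net)
  vapply(idx, function(i) {
    wp <- w
    wp[[name]][i] <- wp[[name]][i] + h
    set_network_weights(net, wp)
    qp <- network_q(net, stim)[action]
    wp[[name]][i] <- wp[[name]][i] - 2 * h
    set_network_weights(net, wp)
    qm <- network_q(net, stim)[action]
    set_network_weights(net, w)
    (qp - qm) / (2 * h)
  }, numeric(1))
}

# Curriculum-trained networks, built once and cached for the whole run.
# Budgets are desk scale: a single CPU cannot afford the full trial counts,
# so the curricula run under bounded learning-trial budgets.
trained_runs <- function(task = "trace", seeds = 1L, budget = 15000L) {
  key <- paste(task, paste(seeds, collapse = "_"), budget, sep = "_")
  if (is.null(the_cache[[key]])) {
    the_cache[[key]] <- lapply(seeds, function(s)
      train_network(task, seed = s,
                    ccfg = curriculum_config(task,
                                             max_total_trials = budget)))
  }
  the_cache[[key]]
}

# evaluation batches for the desk-scale trace networks, cached
trace_batches <- function(runs, n_stimuli = 400L) {
  key <- paste0("batches_", n_stimuli, "_", length(runs))
  if (is.null(the_cache[[key]])) {
    the_cache[[key]] <- lapply(seq_along(runs), function(i) {
      set.seed(5000L + i)
      evaluate_batch(runs[[i]]$net, "trace", length = 9L,
                     n_stimuli = n_stimuli)
    })
  }
  the_cache[[key]]
}
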