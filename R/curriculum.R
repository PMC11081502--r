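#' Curriculum configuration
#'
#' Staged training mirrors how the monkeys were trained: curves grow by one
#' pixel whenever the network passes a frozen-weights test phase (exploration
#' off) at the accuracy criterion.
#'
#' Stage plans per task:
#' * `trace`: a red-blue pixel pair (length 2, no distractor), then target +
#'   distractor curves of lengths 3..9.
#' * `search_then_trace`: the same red-blue pair first, then cued red/brown
#'   marker curves of lengths 3..9.
#' * `trace_then_search`: blue-start curve pairs ending in red/brown markers
#'   (lengths 2..9, eye movement to the end marker), then a final stage that
#'   adds the two external colored pixels as the selectable targets.
#'
#' @param task One of `"trace"`, `"search_then_trace"`,
#'   `"trace_then_search"`.
#' @param max_length Final curve length (default 9).
#' @param criterion Test accuracy required to advance (default 0.85).
#' @param test_trials Trials per frozen test phase (default 500).
#' @param block_trials Learning trials between test phases (default 500).
#' @param max_total_trials Learning-trial budget before training is declared
#'   failed (default 500,000).
#' @return A `vr_curriculum_config` with a `stages` tibble.
#' @export
curriculum_config <- function(task = c("trace", "search_then_trace",
                                       "trace_then_search"),
                              max_length = 9L, criterion = 0.85,
                              test_trials = 500L, block_trials = 500L,
                              max_total_trials = 500000L) {
  task <- match.arg(task)
  stopifnot(criterion > 0, criterion < 1, max_length >= 3L)
  stages <- switch(task,
    trace = tibble::tibble(
      task = "trace", length = 2:max_length,
      n_distractors = c(0L, rep(1L, max_length - 2L)),
      with_external = FALSE),
    search_then_trace = tibble::tibble(
      task = c("trace", rep("search_then_trace", max_length - 2L)),
      length = 2:max_length,
      n_distractors = c(0L, rep(1L, max_length - 2L)),
      with_external = FALSE),
    trace_then_search = tibble::tibble(
      task = "trace_then_search",
      length = c(2:max_length, max_length),
      n_distractors = 1L,
      with_external = c(rep(FALSE, max_length - 1L), TRUE)))
  stages$stage <- seq_len(nrow(stages))
  structure(
    list(task = task, stages = stages, criterion = criterion,
         test_trials = as.integer(test_trials),
         block_trials = as.integer(block_trials),
         max_total_trials = as.integer(max_total_trials)),
    class = "vr_curriculum_config"
  )
}

stage_sampler <- function(stage_row, grid) {
  stimulus_sampler(stage_row$task, length = stage_row$length,
                   n_distractors = stage_row$n_distractors,
                   with_external = stage_row$with_external, grid = grid)
}

encode_batch <- function(sampler, n) {
  lapply(seq_len(n), function(i) encode_stimulus(sampler()))
}

#' Frozen-weights test phase
#'
#' Runs `n_trials` fresh stimuli with the weights fixed and exploration
#' switched off, and returns the fraction answered correctly. The network is
#' left bit-identical.
#'
#' @param net A `relearnn_network`.
#' @param sampler A zero-argument stimulus generator (see
#'   [stimulus_sampler()]), or a task name (then `length`, `n_distractors`,
#'   `with_external` apply).
#' @param length,n_distractors,with_external Stimulus parameters used when
#'   `sampler` is a task name.
#' @param n_trials Number of test trials (default 500).
#' @param max_timesteps Optional relaxation cap (e.g. when probing the
#'   minimal number of processing timesteps).
#' @return Accuracy in `[0, 1]`, with attribute `"n"`.
#' @export
test_phase <- function(net, sampler, length = NULL, n_distractors = 1L,
                       with_external = TRUE, n_trials = 500L,
                       max_timesteps = NULL) {
  stopifnot(inherits(net, "relearnn_network"))
  if (is.character(sampler))
    sampler <- stimulus_sampler(sampler, length = length,
                                n_distractors = n_distractors,
                                with_external = with_external,
                                grid = grid_spec(net$config$height,
                                                 net$config$width))
  stims <- encode_batch(sampler, n_trials)
  res <- cpp_batch_greedy(net$ptr, stims,
                          max_timesteps %||% net$config$max_timesteps,
                          net$config$convergence_tol)
  acc <- mean(res$correct)
  attr(acc, "n") <- as.integer(n_trials)
  acc
}

#' Train a network through a staged curriculum
#'
#' Alternates learning blocks (epsilon-greedy exploration, plasticity on)
#' with frozen test phases; a stage is left once the test accuracy reaches
#' the criterion, and the network counts as trained when the final stage
#' passes. Exhausting the trial budget declares failure (`learned = FALSE`),
#' never an error. The network is updated in place.
#'
#' @param net A `relearnn_network` (modified in place).
#' @param ccfg A [curriculum_config()].
#' @param lcfg A [learning_config()].
#' @param verbose Print per-block progress.
#' @return A `vr_training_log`: tibbles of per-block and per-stage records,
#'   `total_trials` (learning trials only), and the `learned` flag.
#' @export
run_curriculum <- function(net, ccfg = curriculum_config("trace"),
                           lcfg = learning_config(), verbose = FALSE) {
  stopifnot(inherits(net, "relearnn_network"),
            inherits(ccfg, "vr_curriculum_config"))
  grid <- grid_spec(net$config$height, net$config$width)
  cfg <- net$config
  blocks <- list()
  total <- 0L
  learned <- FALSE
  for (si in seq_len(nrow(ccfg$stages))) {
    stage_row <- ccfg$stages[si, ]
    sampler <- stage_sampler(stage_row, grid)
    passed <- FALSE
    while (!passed && total < ccfg$max_total_trials) {
      n_block <- min(ccfg$block_trials, ccfg$max_total_trials - total)
      ncorr <- 0L; nexp <- 0L; dsum <- 0
      for (i in seq_len(n_block)) {
        rec <- learning_trial(net, sampler(), lcfg)
        ncorr <- ncorr + as.integer(rec$correct)
        nexp <- nexp + as.integer(rec$explored)
        dsum <- dsum + abs(rec$delta)
      }
      total <- total + n_block
      acc <- test_phase(net, sampler, n_trials = ccfg$test_trials)
      passed <- acc >= ccfg$criterion
      blocks[[base::length(blocks) + 1L]] <- tibble::tibble(
        stage = stage_row$stage, task = stage_row$task,
        length = stage_row$length, block_trials = n_block,
        train_accuracy = ncorr / n_block, mean_abs_delta = dsum / n_block,
        test_accuracy = as.numeric(acc), passed = passed,
        total_trials = total)
      if (verbose)
        message(sprintf(
          "stage %d (len %d): %d trials, train %.2f, test %.2f%s",
          stage_row$stage, stage_row$length, total, ncorr / n_block, acc,
          if (passed) " -> advance" else ""))
    }
    if (!passed) break
    if (si == nrow(ccfg$stages)) learned <- TRUE
  }
  blocks <- dplyr::bind_rows(blocks)
  stages <- blocks |>
    dplyr::group_by(.data$stage, .data$task, .data$length) |>
    dplyr::summarise(
      trials = sum(.data$block_trials),
      n_blocks = dplyr::n(),
      final_test_accuracy = .data$test_accuracy[dplyr::n()],
      .groups = "drop")
  structure(
    list(task = ccfg$task, blocks = blocks, stages = stages,
         total_trials = total, learned = learned,
         criterion = ccfg$criterion),
    class = "vr_training_log"
  )
}

#' @export
print.vr_training_log <- function(x, ...) {
  cat(sprintf(
    "<vr_training_log> task=%s, %s after %d learning trials (%d stages)\n",
    x$task, if (x$learned) "learned" else "NOT learned", x$total_trials,
    nrow(x$stages)))
  invisible(x)
}

#' Generalization to longer curves
#'
#' Freezes the weights, switches exploration off, and measures accuracy for
#' curves longer than the longest training length.
#'
#' @param net A trained `relearnn_network`.
#' @param task Task name.
#' @param trained_length Longest curve length seen in training.
#' @param offsets Length increments to probe (default 1..4; 0 reproduces the
#'   final test phase).
#' @param n_trials Trials per probed length (default 500).
#' @param with_external For `trace_then_search`, probe the full task.
#' @return Tibble with `length` and `accuracy`.
#' @export
evaluate_generalization <- function(net, task = "trace", trained_length = 9L,
                                    offsets = 1:4, n_trials = 500L,
                                    with_external = TRUE) {
  acc <- vapply(offsets, function(off) {
    as.numeric(test_phase(net, task, length = trained_length + off,
                          with_external = with_external,
                          n_trials = n_trials))
  }, numeric(1))
  tibble::tibble(length = trained_length + offsets, accuracy = acc)
}
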