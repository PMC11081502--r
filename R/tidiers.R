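#' Tidy a training log
#'
#' One row per learning block with the stage, trial counts and accuracies.
#'
#' @param x A `vr_training_log`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.vr_training_log <- function(x, ...) x$blocks

#' Summarize a training log in one row
#'
#' @param x A `vr_training_log`.
#' @param ... Ignored.
#' @return A one-row tibble: task, learned flag, learning-trial total,
#'   number of stages passed, final test accuracy.
#' @export
glance.vr_training_log <- function(x, ...) {
  tibble::tibble(
    task = x$task, learned = x$learned, total_trials = x$total_trials,
    n_stages = nrow(x$stages),
    final_test_accuracy = x$stages$final_test_accuracy[nrow(x$stages)])
}

#' Tidy network weights into a long tibble
#'
#' @param x A `relearnn_network`.
#' @param ... Ignored.
#' @return A tibble with `tensor`, `index`, `weight`.
#' @export
tidy.relearnn_network <- function(x, ...) {
  w <- network_weights(x)
  purrr::imap_dfr(w, function(v, nm)
    tibble::tibble(tensor = nm, index = seq_along(v), weight = as.numeric(v)))
}

#' Summarize a network in one row
#'
#' @param x A `relearnn_network`.
#' @param ... Ignored.
#' @return A one-row tibble with the architecture and weight statistics.
#' @export
glance.relearnn_network <- function(x, ...) {
  w <- network_weights(x)
  n <- sum(purrr::map_int(w, base::length))
  tibble::tibble(
    height = x$config$height, width = x$config$width,
    n_actions = n_actions(x$config), n_weights = n,
    weight_sharing = x$config$weight_sharing,
    readout = x$config$readout_stream,
    mean_abs_weight = mean(abs(unlist(w, use.names = FALSE))))
}
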