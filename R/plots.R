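#' Plot a stimulus
#'
#' Draws the pixel grid with its colored curves; the correct eye-movement
#' target is circled. Extra units, when active, are shown beside the grid.
#'
#' @param object A `vr_stimulus`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vr_stimulus <- function(object, ...) {
  s <- object
  pal <- c(red = "#d62728", brown = "#8c564b", blue = "#1f77b4",
           green = "#2ca02c")
  df <- tibble::tibble(
    row = s$cells[, 1L], col = s$cells[, 2L],
    color = names(vr_colors)[s$cells[, 3L]])
  P <- s$grid$height * s$grid$width
  if (any(s$extras > 0)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      row = c(3, 5), col = -1.5, color = c("red", "brown"))[s$extras > 0, ])
  }
  corr <- if (s$correct_action <= P)
    tibble::tibble(row = (s$correct_action - 1L) %/% s$grid$width + 1L,
                   col = (s$correct_action - 1L) %% s$grid$width + 1L)
  else tibble::tibble(row = c(3, 5)[s$correct_action - P], col = -1.5)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$color), width = 0.9,
                       height = 0.9) +
    ggplot2::geom_point(data = corr, shape = 1, size = 5) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_y_reverse(limits = c(s$grid$height + 0.5, 0.5)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s stimulus, length %d", s$task,
                                  s$length),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.vr_stimulus <- function(x, ...) print(autoplot.vr_stimulus(x, ...))

#' Plot a training log
#'
#' Test accuracy over learning trials, one panel row per curriculum stage.
#'
#' @param object A `vr_training_log`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vr_training_log <- function(object, ...) {
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(x = .data$total_trials,
                               y = .data$test_accuracy,
                               color = factor(.data$length))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$criterion, linetype = 2) +
    ggplot2::labs(x = "learning trials", y = "test accuracy",
                  color = "curve length",
                  title = sprintf("%s curriculum", object$task)) +
    ggplot2::theme_minimal()
}

#' @export
plot.vr_training_log <- function(x, ...) print(autoplot.vr_training_log(x, ...))

#' Plot a modulation-index distribution
#'
#' @param object A `vr_mi_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vr_mi_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 0.09) +
    ggplot2::geom_vline(xintercept = object$mean_mi, linetype = 2) +
    ggplot2::labs(x = "modulation index", y = "units",
                  title = sprintf("mean MI = %.2f", object$mean_mi)) +
    ggplot2::theme_minimal()
}

#' Plot modulation latencies by distance
#'
#' @param object A `vr_latency_comparison`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vr_latency_comparison <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$latency,
                               fill = factor(.data$distance))) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6,
                            binwidth = 1) +
    ggplot2::labs(x = "modulation latency (timesteps)", y = "units",
                  fill = "distance (pixels)") +
    ggplot2::theme_minimal()
}

#' Plot routine-stage time courses
#'
#' @param object The tibble returned by [routine_stage_timecourse()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_routine_timecourse <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$step, y = .data$normalized,
                               group = interaction(.data$element,
                                                   .data$distance),
                               color = .data$element)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "timestep", y = "normalized modulation") +
    ggplot2::theme_minimal()
}
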