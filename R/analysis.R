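#' Modulation index
#'
#' `MI = (Target - Distractor) / ((Target + Distractor) / 2)`: the response
#' difference between target- and distractor-elicited activity, divided by
#' their mean. Positive values signify an enhancement of the target
#' representation; since activities are non-negative the index is bounded
#' between -2 and 2. Pairs where both activities are zero are undefined and
#' returned as `NA` (callers report the excluded count).
#'
#' @param target_act,distractor_act Mean activities (non-negative, same
#'   length).
#' @return Numeric vector of modulation indices.
#' @examples
#' modulation_index(2, 1)
#' @export
modulation_index <- function(target_act, distractor_act) {
  stopifnot(all(target_act >= 0, na.rm = TRUE),
            all(distractor_act >= 0, na.rm = TRUE))
  s <- target_act + distractor_act
  ifelse(s == 0, NA_real_, (target_act - distractor_act) / (s / 2))
}

#' Modulation latency
#'
#' First timestep at which a target-minus-distractor activity difference
#' exceeds `frac` (default 70%) of its maximum. Timesteps are counted from 0
#' (the base representation). If the series never becomes positive the
#' latency is undefined (`NA`).
#'
#' @param diff_timeseries Per-timestep target-distractor difference.
#' @param frac Fraction of the maximum (default 0.7).
#' @return Integer timestep (0-based) or `NA`.
#' @examples
#' modulation_latency(c(0, 1, 3, 8, 10, 10))
#' @export
modulation_latency <- function(diff_timeseries, frac = 0.7) {
  stopifnot(length(diff_timeseries) >= 1L)
  m <- max(diff_timeseries)
  if (!is.finite(m) || m <= 0) return(NA_integer_)
  as.integer(which(diff_timeseries > frac * m)[1L] - 1L)
}

#' Evaluate a trained network on a batch of frozen-weights trials
#'
#' Presents `n_stimuli` randomly generated stimuli with weights frozen and
#' exploration off, keeps the correct trials, and accumulates the activity
#' of recurrent input-layer units on target- and distractor-curve positions,
#' per unit, per along-curve distance from the curve start, and per
#' timestep. This is the raw material for the modulation-index,
#' modulation-latency and routine-time-course analyses.
#'
#' @param net A trained `relearnn_network`.
#' @param task Task name.
#' @param length Curve length (default 9).
#' @param n_stimuli Number of stimuli presented (default 1000).
#' @param with_external For `trace_then_search`: full task with external
#'   targets.
#' @param max_timesteps Trajectory length (default the configured cap; the
#'   trajectory is extended at the settled value after convergence).
#' @return A `vr_eval_batch` object.
#' @export
evaluate_batch <- function(net, task = "trace", length = 9L,
                           n_stimuli = 1000L, with_external = TRUE,
                           max_timesteps = NULL) {
  stopifnot(inherits(net, "relearnn_network"))
  cfg <- net$config
  grid <- grid_spec(cfg$height, cfg$width)
  sampler <- stimulus_sampler(task, length = length,
                              with_external = with_external, grid = grid)
  C <- cfg$n_colors
  NG <- cfg$height * cfg$width * C
  Tm1 <- (max_timesteps %||% cfg$max_timesteps) + 1L
  L <- as.integer(length)
  Tt <- array(0, dim = c(NG, L, Tm1)); Dt <- array(0, dim = c(NG, L, Tm1))
  Tcnt <- matrix(0L, NG, L); Dcnt <- matrix(0L, NG, L)
  ext_t <- numeric(Tm1); ext_d <- numeric(Tm1); ext_n <- 0L
  n_correct <- 0L
  unit_of <- function(path, colors) (cell_id(path[, 1L], path[, 2L], grid) - 1L) * C +
    as.integer(colors)
  for (i in seq_len(n_stimuli)) {
    s <- sampler()
    st <- relax_network(net, s, max_timesteps = Tm1 - 1L, record_traj = TRUE)
    a <- which.max(st$q)
    if (a != s$correct_action) next
    n_correct <- n_correct + 1L
    traj <- st$traj
    nr <- nrow(traj)
    idx <- c(seq_len(nr), rep(nr, Tm1 - nr))
    traj <- traj[idx, , drop = FALSE]
    tu <- unit_of(s$target_path, s$cells[seq_len(L), 3L])
    du <- unit_of(s$distractor_paths[[1L]],
                  s$cells[L + seq_len(L), 3L])
    for (d in seq_len(L)) {
      Tt[tu[d], d, ] <- Tt[tu[d], d, ] + traj[, tu[d]]
      Tcnt[tu[d], d] <- Tcnt[tu[d], d] + 1L
      Dt[du[d], d, ] <- Dt[du[d], d, ] + traj[, du[d]]
      Dcnt[du[d], d] <- Dcnt[du[d], d] + 1L
    }
    if (task == "trace_then_search" && with_external) {
      e_t <- s$correct_action - grid$height * grid$width  # 1 = red, 2 = brown
      ext_t <- ext_t + traj[, NG + e_t]
      ext_d <- ext_d + traj[, NG + (3L - e_t)]
      ext_n <- ext_n + 1L
    }
  }
  structure(
    list(task = task, length = L, n_stimuli = as.integer(n_stimuli),
         n_correct = n_correct, accuracy = n_correct / n_stimuli,
         Tt = Tt, Dt = Dt, Tcnt = Tcnt, Dcnt = Dcnt,
         ext_target = if (ext_n > 0L) ext_t / ext_n else NULL,
         ext_other = if (ext_n > 0L) ext_d / ext_n else NULL,
         n_timesteps = Tm1, n_colors = C, grid = grid),
    class = "vr_eval_batch"
  )
}

#' @export
print.vr_eval_batch <- function(x, ...) {
  cat(sprintf(
    "<vr_eval_batch> task=%s, length=%d, %d/%d correct (%.1f%%)\n",
    x$task, x$length, x$n_correct, x$n_stimuli, 100 * x$accuracy))
  invisible(x)
}

#' Per-unit modulation indices of an evaluation batch
#'
#' Computes, for every recurrent input-layer unit that appeared on both
#' target and distractor curves, the modulation index of its mean
#' fixed-point activity. Units observed in only one role or with undefined
#' index are excluded and counted, not silently dropped.
#'
#' @param batch A [evaluate_batch()] result.
#' @return Tibble with `unit`, `cell`, `channel`, `n_target`,
#'   `n_distractor`, `target_act`, `distractor_act`, `mi`; the number of
#'   excluded units is attached as attribute `"n_excluded"`.
#' @export
batch_modulation <- function(batch) {
  stopifnot(inherits(batch, "vr_eval_batch"))
  Tm1 <- batch$n_timesteps
  tsum <- rowSums(batch$Tt[, , Tm1, drop = FALSE][, , 1L])
  dsum <- rowSums(batch$Dt[, , Tm1, drop = FALSE][, , 1L])
  tn <- rowSums(batch$Tcnt); dn <- rowSums(batch$Dcnt)
  seen <- tn > 0L | dn > 0L
  both <- tn > 0L & dn > 0L
  units <- which(both)
  mi <- modulation_index(tsum[units] / tn[units], dsum[units] / dn[units])
  out <- tibble::tibble(
    unit = units,
    cell = (units - 1L) %/% batch$n_colors + 1L,
    channel = (units - 1L) %% batch$n_colors + 1L,
    n_target = tn[units], n_distractor = dn[units],
    target_act = tsum[units] / tn[units],
    distractor_act = dsum[units] / dn[units],
    mi = mi)
  n_undefined <- sum(is.na(mi))
  out <- out[!is.na(out$mi), ]
  attr(out, "n_excluded") <- sum(seen) - nrow(out)
  attr(out, "n_undefined") <- n_undefined
  out
}

#' Modulation latencies by along-curve distance
#'
#' For each recurrent input-layer unit and along-curve distance, averages
#' its activity time course over the trials where it sat on the target vs.
#' the distractor curve at that distance, and applies the 70%-of-maximum
#' latency rule to the difference. Units at pixel distances 2 and 7 from the
#' curve start (the near and far groups of the neurophysiology analysis) are
#' compared with a Mann-Whitney rank test.
#'
#' @param batch A [evaluate_batch()] result (length-9 stimuli).
#' @param distances Two along-curve distances to compare (default `c(2, 7)`,
#'   pixels from the curve start).
#' @param frac Latency threshold fraction (default 0.7).
#' @return List with `records` (per-unit latencies), `medians`, and `test`
#'   (the `htest`), of class `vr_latency_comparison`.
#' @export
latency_vs_distance <- function(batch, distances = c(2L, 7L), frac = 0.7) {
  stopifnot(inherits(batch, "vr_eval_batch"), length(distances) == 2L)
  recs <- unit_latencies(batch, distances, frac)
  if (nrow(recs) < 4L || length(unique(recs$distance)) < 2L)
    stop("not enough defined modulation latencies to compare groups")
  med <- recs |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(median_latency = stats::median(.data$latency),
                     n = dplyr::n(), .groups = "drop")
  test <- stats::wilcox.test(latency ~ distance, data = recs, exact = FALSE)
  structure(list(records = recs, medians = med, test = test),
            class = "vr_latency_comparison")
}

#' @export
print.vr_latency_comparison <- function(x, ...) {
  cat("<vr_latency_comparison>\n")
  print(x$medians)
  cat(sprintf("  Mann-Whitney p = %.3g\n", x$test$p.value))
  invisible(x)
}

# per-(unit, distance) latencies of the mean modulation time course
unit_latencies <- function(batch, distances, frac = 0.7) {
  out <- list()
  for (d in distances) {
    di <- d + 1L  # distance d pixels from the start = path index d + 1
    if (di > batch$length) next
    units <- which(batch$Tcnt[, di] > 0L & batch$Dcnt[, di] > 0L)
    for (u in units) {
      diff <- batch$Tt[u, di, ] / batch$Tcnt[u, di] -
        batch$Dt[u, di, ] / batch$Dcnt[u, di]
      lat <- modulation_latency(diff, frac)
      if (!is.na(lat))
        out[[base::length(out) + 1L]] <-
          tibble::tibble(unit = u, distance = d, latency = lat)
    }
  }
  if (base::length(out) == 0L)
    return(tibble::tibble(unit = integer(), distance = integer(),
                          latency = integer()))
  dplyr::bind_rows(out)
}

#' Minimal relaxation timesteps for criterion accuracy
#'
#' Evaluates frozen-weights accuracy on a fixed set of fresh stimuli while
#' capping the recurrent relaxation at T = 1, 2, ... timesteps, and returns
#' the smallest cap reaching the accuracy criterion. Longer curves need more
#' timesteps: the signature of serial propagation of enhanced activity.
#'
#' @param net A trained `relearnn_network`.
#' @param task Task name.
#' @param length Curve length.
#' @param criterion Accuracy criterion (default 0.85).
#' @param n_trials Test trials per cap (default 500).
#' @param t_max Largest cap probed (default 50).
#' @return Smallest sufficient cap as integer, or `NA` if the criterion is
#'   never reached; the accuracy-vs-cap tibble is attached as attribute
#'   `"accuracy_curve"`.
#' @export
min_timesteps_to_criterion <- function(net, task = "trace", length = 9L,
                                       criterion = 0.85, n_trials = 500L,
                                       t_max = 50L) {
  stopifnot(inherits(net, "relearnn_network"))
  grid <- grid_spec(net$config$height, net$config$width)
  sampler <- stimulus_sampler(task, length = length, grid = grid)
  stims <- encode_batch(sampler, n_trials)
  curve <- list()
  t_star <- NA_integer_
  for (tcap in seq_len(t_max)) {
    res <- cpp_batch_greedy(net$ptr, stims, tcap, net$config$convergence_tol)
    acc <- mean(res$correct)
    curve[[tcap]] <- tibble::tibble(max_timesteps = tcap, accuracy = acc)
    if (acc >= criterion) { t_star <- tcap; break }
  }
  structure(t_star, accuracy_curve = dplyr::bind_rows(curve))
}

#' Credit propagation through the accessory network
#'
#' Runs one frozen trial, selects the greedy action, records the accessory
#' relaxation, and returns the accessory activity of the recurrent input
#' layer on both curves as a function of accessory timestep and along-curve
#' distance from the selected eye-movement target. The credit signal starts
#' at the selected target and travels backwards along the selected curve; it
#' is absent from the non-selected curve.
#'
#' @param net A `relearnn_network`.
#' @param stim A `vr_stimulus` (length >= 2, two curves).
#' @param lcfg A [learning_config()].
#' @return Tibble with `curve` (`"selected"`/`"non-selected"`),
#'   `distance_from_target` (pixels along the curve from the selected end),
#'   `step`, and `activity`; the chosen action and its correctness are
#'   attached as attributes.
#' @export
credit_propagation_profile <- function(net, stim, lcfg = learning_config()) {
  stopifnot(inherits(net, "relearnn_network"), inherits(stim, "vr_stimulus"))
  st <- relax_network(net, stim)
  a <- which.max(st$q)
  acc <- accessory_state(net, stim, a, lcfg, record = TRUE)
  traj <- acc$acc_traj
  grid <- stim$grid; C <- grid$n_colors
  L <- stim$length
  correct <- a == stim$correct_action
  sel <- if (correct) stim$target_path else stim$distractor_paths[[1L]]
  nonsel <- if (correct) stim$distractor_paths[[1L]] else stim$target_path
  selcol <- if (correct) stim$cells[seq_len(L), 3L] else
    stim$cells[L + seq_len(L), 3L]
  nonselcol <- if (correct) stim$cells[L + seq_len(L), 3L] else
    stim$cells[seq_len(L), 3L]
  grab <- function(path, cols, label) {
    units <- (cell_id(path[, 1L], path[, 2L], grid) - 1L) * C +
      as.integer(cols)
    purrr::map_dfr(seq_len(L), function(d) tibble::tibble(
      curve = label,
      distance_from_target = L - d,
      step = seq_len(nrow(traj)) - 1L,
      activity = traj[, units[d]]))
  }
  out <- dplyr::bind_rows(grab(sel, selcol, "selected"),
                          grab(nonsel, nonselcol, "non-selected"))
  attr(out, "action") <- a
  attr(out, "correct") <- correct
  out
}

#' Normalized modulation time courses of the routine stages
#'
#' For the composite tasks, extracts the modulation time course of each
#' stimulus element (the color marker, the curve segments, and for
#' trace-then-search the external eye-movement targets), normalizes each
#' trace by its own maximum, and reports the element latencies. In the
#' search-then-trace task the marker modulation (search operation) precedes
#' the curve modulation (trace operation); in the trace-then-search task the
#' curve-end modulation (trace operation) precedes the external-target
#' modulation (search operation).
#'
#' @param batch A [evaluate_batch()] result for a composite task.
#' @param frac Latency threshold fraction (default 0.7).
#' @return Tibble with `element`, `distance`, `step`, `modulation`,
#'   `normalized`; per-element latencies as attribute `"latencies"`.
#' @export
routine_stage_timecourse <- function(batch, frac = 0.7) {
  stopifnot(inherits(batch, "vr_eval_batch"))
  L <- batch$length; Tm1 <- batch$n_timesteps
  traces <- list()
  for (d in seq_len(L)) {
    units <- which(batch$Tcnt[, d] > 0L & batch$Dcnt[, d] > 0L)
    if (base::length(units) == 0L) next
    tt <- colSums(batch$Tt[units, d, , drop = FALSE][, 1L, ]) /
      sum(batch$Tcnt[units, d])
    dd <- colSums(batch$Dt[units, d, , drop = FALSE][, 1L, ]) /
      sum(batch$Dcnt[units, d])
    if (base::length(units) == 1L) {
      tt <- batch$Tt[units, d, ] / batch$Tcnt[units, d]
      dd <- batch$Dt[units, d, ] / batch$Dcnt[units, d]
    }
    mod <- tt - dd
    element <- if (batch$task == "search_then_trace" && d == 1L) "marker"
      else if (batch$task == "trace_then_search" && d == L) "curve end"
      else "curve"
    traces[[base::length(traces) + 1L]] <- tibble::tibble(
      element = element, distance = d - 1L, step = seq_len(Tm1) - 1L,
      modulation = mod,
      normalized = if (max(mod) > 0) mod / max(mod) else mod)
  }
  if (!is.null(batch$ext_target)) {
    mod <- batch$ext_target - batch$ext_other
    traces[[base::length(traces) + 1L]] <- tibble::tibble(
      element = "external target", distance = NA_integer_,
      step = seq_len(Tm1) - 1L, modulation = mod,
      normalized = if (max(mod) > 0) mod / max(mod) else mod)
  }
  out <- dplyr::bind_rows(traces)
  lat <- out |>
    dplyr::group_by(.data$element, .data$distance) |>
    dplyr::summarise(latency = modulation_latency(.data$modulation, frac),
                     .groups = "drop")
  attr(out, "latencies") <- lat
  out
}

#' Population modulation-index summary across networks
#'
#' Pools per-unit modulation indices over several evaluation batches (one or
#' more trained networks) and reports their mean and distribution.
#'
#' @param batches A list of [evaluate_batch()] results (or a single batch).
#' @param breaks Histogram breaks (default width 0.1 between -2 and 2).
#' @return A `vr_mi_summary`: `mean_mi`, `n_units`, `n_excluded`,
#'   `histogram` tibble, and the pooled `per_unit` tibble.
#' @export
population_mi_summary <- function(batches, breaks = seq(-2, 2, by = 0.1)) {
  if (inherits(batches, "vr_eval_batch")) batches <- list(batches)
  per <- purrr::imap_dfr(batches, function(b, i) {
    m <- batch_modulation(b)
    m$network <- i
    m
  })
  excl <- sum(purrr::map_int(batches, function(b)
    attr(batch_modulation(b), "n_excluded")))
  h <- graphics::hist(pmax(pmin(per$mi, max(breaks)), min(breaks)),
                      breaks = breaks, plot = FALSE)
  structure(
    list(mean_mi = mean(per$mi), n_units = nrow(per), n_excluded = excl,
         histogram = tibble::tibble(mid = h$mids, count = h$counts),
         per_unit = per),
    class = "vr_mi_summary"
  )
}

#' @export
print.vr_mi_summary <- function(x, ...) {
  cat(sprintf("<vr_mi_summary> mean MI = %.3f over %d units (%d excluded)\n",
              x$mean_mi, x$n_units, x$n_excluded))
  invisible(x)
}
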