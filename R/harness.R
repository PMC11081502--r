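#' Save and load network checkpoints
#'
#' Checkpoints are plain JSON files holding the configuration and every
#' weight tensor at full double precision, so a load-save round trip is
#' bit-exact.
#'
#' @param net A `relearnn_network`.
#' @param path File path (conventionally `.json`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns a reconstructed `relearnn_network`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "relearnn_network"))
  # 17 significant digits make the decimal text round-trip every double
  # bit-exactly
  obj <- list(
    format = "visroutines-checkpoint",
    version = 1L,
    config = unclass(net$config),
    rng_state = if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL,
    weights = lapply(network_weights(net),
                     function(v) sprintf("%.17g", as.numeric(v))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param restore_rng Restore the R random-number-generator state that was
#'   current when the checkpoint was written (default `FALSE`).
#' @export
load_checkpoint <- function(path, restore_rng = FALSE) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupt or unreadable checkpoint file: ",
                         conditionMessage(e)))
  if (!identical(obj$format, "visroutines-checkpoint"))
    stop("not a visroutines checkpoint file")
  cfgl <- obj$config
  cfg <- network_config(
    height = cfgl$height, width = cfgl$width,
    max_timesteps = cfgl$max_timesteps,
    convergence_tol = cfgl$convergence_tol, epsilon = cfgl$epsilon,
    weight_sharing = cfgl$weight_sharing,
    dense_skip_feedback = cfgl$dense_skip_feedback,
    grid_lateral = cfgl$grid_lateral, monotone_gate = cfgl$monotone_gate,
    feedforward_drive = cfgl$feedforward_drive,
    excitatory_recurrent = cfgl$excitatory_recurrent,
    relax_damping = cfgl$relax_damping,
    readout_stream = cfgl$readout_stream)
  needed <- c("V1", "V2", "T0", "T1", "U1", "U2", "Hg", "Hx2g", "Hg2x",
              "Fskip", "Whid", "Win")
  if (!all(needed %in% names(obj$weights)))
    stop("corrupt checkpoint: missing weight tensors")
  if (isTRUE(restore_rng) && !is.null(obj$rng_state))
    assign(".Random.seed", as.integer(obj$rng_state), envir = globalenv())
  init_network(cfg, weights = lapply(obj$weights[needed], as.numeric))
}

#' Save and load a run bundle
#'
#' A bundle is a directory with one checkpoint per network, the tabular logs
#' as CSV, and a JSON manifest tying every artifact to the seeds and
#' configuration that produced it.
#'
#' @param nets Named list of `relearnn_network` objects.
#' @param logs Named list of tibbles/data frames to store as CSV.
#' @param info List of run metadata (seeds, config snapshot, outcomes).
#' @param path Bundle directory (created if needed).
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()` returns
#'   a list with `nets`, `logs`, `manifest`.
#' @export
save_bundle <- function(nets, logs = list(), info = list(), path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "visroutines-bundle", version = 1L,
    package_version = as.character(utils::packageVersion("visroutines")),
    info = info,
    networks = names(nets), logs = names(logs))
  for (nm in names(nets))
    save_checkpoint(nets[[nm]], file.path(path, paste0(nm, ".json")))
  for (nm in names(logs))
    utils::write.csv(logs[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in bundle directory")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  nets <- lapply(manifest$networks, function(nm)
    load_checkpoint(file.path(path, paste0(nm, ".json"))))
  names(nets) <- manifest$networks
  logs <- lapply(manifest$logs, function(nm)
    tibble::as_tibble(utils::read.csv(file.path(path, paste0(nm, ".csv")))))
  names(logs) <- manifest$logs
  list(nets = nets, logs = logs, manifest = manifest)
}

# reference values from the source study (means over 24 networks), with
# wide tolerance bands appropriate for small replicate counts
reference_values <- function() {
  tibble::tribble(
    ~quantity,            ~reference, ~band_lo, ~band_hi, ~units,
    "trace_trials",            19000,     9500,    28500, "trials",
    "mean_mi",                  1.18,     0.78,     1.58, "",
    "min_timesteps_len5",          2,        1,        6, "timesteps",
    "min_timesteps_len9",         13,        9,       17, "timesteps",
    "stt_learned_pct",            79,       40,      100, "%",
    "stt_trials",              40000,    20000,    60000, "trials",
    "tts_learned_pct",            66,       33,      100, "%",
    "tts_trials",              37000,    18500,    55500, "trials"
  )
}

#' Train one network on a task
#'
#' Convenience wrapper: seed, initialize, run the curriculum.
#'
#' @param task Task name.
#' @param seed Integer seed (controls weights, stimuli and exploration).
#' @param ncfg,lcfg,ccfg Optional configuration overrides.
#' @param verbose Print per-block progress.
#' @return List with `net` and `log` (a `vr_training_log`).
#' @export
train_network <- function(task = "trace", seed = 1L, ncfg = network_config(),
                          lcfg = learning_config(), ccfg = NULL,
                          verbose = FALSE) {
  if (is.null(ccfg)) ccfg <- curriculum_config(task)
  set.seed(seed)
  net <- init_network(ncfg)
  log <- run_curriculum(net, ccfg, lcfg, verbose = verbose)
  log$seed <- seed
  list(net = net, log = log)
}

#' Reproduce a model-side experiment at configurable scale
#'
#' Runs one of the study's experiment recipes end to end with fresh
#' networks, at a chosen replicate count, and reports the obtained
#' statistics next to the reference values with their tolerance bands.
#' Stochastic mismatch is reported (flag and z-like score), never an error.
#'
#' @param name One of `"trace_training"`, `"stt_training"`,
#'   `"tts_training"`, `"generalization"`, `"min_timesteps"`,
#'   `"mi_summary"`, `"latency_distance"`.
#' @param scale Number of replicate networks (default 3; recipes that need
#'   trained curve-tracing networks train `scale` of them).
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param n_stimuli Evaluation stimuli per network for analysis recipes.
#' @param max_total_trials Optional learning-trial budget per network
#'   (default: the full 500,000 of [curriculum_config()]); smaller budgets
#'   give desk-scale runs whose incomplete trainings are reported as such.
#' @param verbose Print progress.
#' @return A `vr_report`: tibble of obtained vs reference quantities, with
#'   the raw per-replicate results as attribute `"details"`.
#' @export
reproduce_experiment <- function(name = c("trace_training", "stt_training",
                                          "tts_training", "generalization",
                                          "min_timesteps", "mi_summary",
                                          "latency_distance"),
                                 scale = 3L, seed = 1L, n_stimuli = 1000L,
                                 max_total_trials = NULL, verbose = FALSE) {
  name <- match.arg(name)
  stopifnot(scale >= 1L)
  refs <- reference_values()
  seeds <- seed + seq_len(scale) - 1L
  details <- list()
  rows <- list()
  add_row <- function(quantity, value, n) {
    ref <- refs[refs$quantity == quantity, ]
    rows[[base::length(rows) + 1L]] <<- tibble::tibble(
      quantity = quantity, value = value, n = n,
      reference = if (nrow(ref)) ref$reference else NA_real_,
      band_lo = if (nrow(ref)) ref$band_lo else NA_real_,
      band_hi = if (nrow(ref)) ref$band_hi else NA_real_,
      within_band = if (nrow(ref)) value >= ref$band_lo & value <= ref$band_hi
                    else NA,
      z = if (nrow(ref)) (value - ref$reference) /
            ((ref$band_hi - ref$band_lo) / 4) else NA_real_)
  }
  train_many <- function(task) {
    ccfg <- if (is.null(max_total_trials)) curriculum_config(task)
            else curriculum_config(task, max_total_trials = max_total_trials)
    lapply(seeds, function(s) {
      if (verbose) message(sprintf("training %s network, seed %d", task, s))
      train_network(task, seed = s, ccfg = ccfg, verbose = verbose)
    })
  }
  trials_stat <- function(trials, learned) {
    # trials to criterion over completed runs; censored at the consumed
    # trials when no run completed
    if (any(learned)) mean(trials[learned]) else mean(trials)
  }
  if (name == "trace_training") {
    runs <- train_many("trace")
    trials <- purrr::map_dbl(runs, ~ .x$log$total_trials)
    learned <- purrr::map_lgl(runs, ~ .x$log$learned)
    add_row("trace_trials", trials_stat(trials, learned), sum(learned))
    details <- runs
  } else if (name == "stt_training") {
    runs <- train_many("search_then_trace")
    trials <- purrr::map_dbl(runs, ~ .x$log$total_trials)
    learned <- purrr::map_lgl(runs, ~ .x$log$learned)
    add_row("stt_learned_pct", 100 * mean(learned), scale)
    add_row("stt_trials", trials_stat(trials, learned), sum(learned))
    details <- runs
  } else if (name == "tts_training") {
    runs <- train_many("trace_then_search")
    trials <- purrr::map_dbl(runs, ~ .x$log$total_trials)
    learned <- purrr::map_lgl(runs, ~ .x$log$learned)
    add_row("tts_learned_pct", 100 * mean(learned), scale)
    add_row("tts_trials", trials_stat(trials, learned), sum(learned))
    details <- runs
  } else {
    runs <- train_many("trace")
    nets <- purrr::map(purrr::keep(runs, ~ .x$log$learned), "net")
    if (base::length(nets) == 0L) stop("no network learned the trace task")
    if (name == "mi_summary") {
      batches <- purrr::map(nets, evaluate_batch, task = "trace",
                            length = 9L, n_stimuli = n_stimuli)
      s <- population_mi_summary(batches)
      add_row("mean_mi", s$mean_mi, s$n_units)
      details <- s
    } else if (name == "min_timesteps") {
      t5 <- purrr::map_int(nets, ~ as.integer(min_timesteps_to_criterion(
        .x, "trace", length = 5L)))
      t9 <- purrr::map_int(nets, ~ as.integer(min_timesteps_to_criterion(
        .x, "trace", length = 9L)))
      add_row("min_timesteps_len5", mean(t5, na.rm = TRUE), base::length(t5))
      add_row("min_timesteps_len9", mean(t9, na.rm = TRUE), base::length(t9))
      details <- list(len5 = t5, len9 = t9)
    } else if (name == "generalization") {
      gen <- purrr::map(nets, evaluate_generalization, task = "trace",
                        trained_length = 9L)
      acc13 <- purrr::map_dbl(gen, ~ .x$accuracy[.x$length == 13L])
      add_row("generalization_len13_accuracy", mean(acc13),
              base::length(acc13))
      details <- gen
    } else if (name == "latency_distance") {
      batches <- purrr::map(nets, evaluate_batch, task = "trace",
                            length = 9L, n_stimuli = n_stimuli)
      cmps <- purrr::map(batches, latency_vs_distance)
      med <- purrr::map_dbl(cmps, ~ diff(.x$medians$median_latency))
      add_row("latency_median_gap_7_vs_2", mean(med), base::length(med))
      details <- cmps
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "details") <- details
  attr(out, "seeds") <- seeds
  class(out) <- c("vr_report", class(out))
  out
}
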