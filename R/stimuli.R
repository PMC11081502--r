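#' Color channels of the input grid
#'
#' The input layer carries four color channels per grid cell: red, brown,
#' blue and green. Two extra input units outside the grid carry the red and
#' brown color cues used by the composite tasks.
#'
#' @format Named integer vector mapping color name to channel index.
#' @export
vr_colors <- c(red = 1L, brown = 2L, blue = 3L, green = 4L)

#' Grid specification
#'
#' Defines the pixel grid on which stimuli are drawn: a `height` x `width`
#' array of cells, four color channels per cell, and two extra input units
#' outside the grid (red and brown cue/eye-movement units).
#'
#' @param height,width Grid dimensions in cells (both at least 3).
#' @return A `vr_grid` object.
#' @examples
#' grid_spec()
#' @export
grid_spec <- function(height = 15L, width = 15L) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 3L, width >= 3L)
  structure(
    list(height = height, width = width, n_colors = 4L, n_extra_units = 2L),
    class = "vr_grid"
  )
}

#' @export
print.vr_grid <- function(x, ...) {
  cat(sprintf("<vr_grid> %d x %d cells, %d color channels, %d extra units\n",
              x$height, x$width, x$n_colors, x$n_extra_units))
  invisible(x)
}

cell_id <- function(r, c, grid) (r - 1L) * grid$width + c

placement_failure <- function(msg) {
  stop(errorCondition(msg, class = c("vr_placement_failure", "error",
                                     "condition")))
}

# occupancy mask of cells that a new path must avoid: the cells themselves
# plus their Von Neumann neighbors (diagonal contact between curves is fine,
# 4-adjacent contact would merge them into one connected component)
forbidden_mask <- function(occupied, grid) {
  m <- matrix(FALSE, grid$height, grid$width)
  if (is.null(occupied) || nrow(occupied) == 0L) return(m)
  for (i in seq_len(nrow(occupied))) {
    r <- occupied[i, 1L]; c <- occupied[i, 2L]
    m[r, c] <- TRUE
    if (r > 1L) m[r - 1L, c] <- TRUE
    if (r < grid$height) m[r + 1L, c] <- TRUE
    if (c > 1L) m[r, c - 1L] <- TRUE
    if (c < grid$width) m[r, c + 1L] <- TRUE
  }
  m
}

#' Sample a self-avoiding path on the grid
#'
#' Draws a random self-avoiding walk of exactly `length` cells whose
#' consecutive cells are Von Neumann (4-neighborhood) adjacent. The path
#' avoids all `occupied` cells and their Von Neumann neighbors, so distinct
#' curves never touch 4-adjacently (diagonal contact is permitted). Dead
#' ends trigger a restart from a fresh random start; after `max_restarts`
#' failed attempts a placement-failure error (condition class
#' `vr_placement_failure`) is raised so the caller can retry with a fresh
#' layout.
#'
#' @param length Number of cells in the path (at least 2).
#' @param grid A [grid_spec()].
#' @param occupied Optional integer matrix of (row, col) cells already taken.
#' @param max_restarts Restarts before giving up.
#' @return Integer matrix with `length` rows and columns `row`, `col`.
#' @examples
#' set.seed(1)
#' sample_path(9)
#' @export
sample_path <- function(length, grid = grid_spec(), occupied = NULL,
                        max_restarts = 200L) {
  length <- as.integer(length)
  if (length < 2L) stop("a path needs at least 2 cells")
  if (length > grid$height * grid$width)
    placement_failure("path length exceeds the number of grid cells")
  forb <- forbidden_mask(occupied, grid)
  free <- which(!forb, arr.ind = TRUE)
  if (nrow(free) < length)
    placement_failure("not enough free cells for the requested path")
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  for (attempt in seq_len(max_restarts)) {
    start <- free[sample.int(nrow(free), 1L), ]
    path <- matrix(0L, length, 2L)
    onpath <- matrix(FALSE, grid$height, grid$width)
    path[1L, ] <- start
    onpath[start[1L], start[2L]] <- TRUE
    ok <- TRUE
    if (length > 1L) {
      for (i in 2L:length) {
        r <- path[i - 1L, 1L]; c <- path[i - 1L, 2L]
        cand_r <- r + dr; cand_c <- c + dc
        keep <- cand_r >= 1L & cand_r <= grid$height &
          cand_c >= 1L & cand_c <= grid$width
        cand_r <- cand_r[keep]; cand_c <- cand_c[keep]
        keep2 <- logical(base::length(cand_r))
        for (k in seq_along(cand_r))
          keep2[k] <- !forb[cand_r[k], cand_c[k]] && !onpath[cand_r[k], cand_c[k]]
        if (!any(keep2)) { ok <- FALSE; break }
        pick <- which(keep2)[sample.int(sum(keep2), 1L)]
        path[i, ] <- c(cand_r[pick], cand_c[pick])
        onpath[cand_r[pick], cand_c[pick]] <- TRUE
      }
    }
    if (ok) {
      colnames(path) <- c("row", "col")
      return(path)
    }
  }
  placement_failure(sprintf(
    "could not place a %d-cell path after %d restarts", length, max_restarts))
}

# inward rectangular spiral anchored at a random corner of a random
# sub-rectangle; supports lengths up to 25 on the default grid
spiral_path <- function(length, grid = grid_spec()) {
  side <- ceiling(sqrt(length))
  a <- min(grid$height, side + sample.int(2L, 1L) - 1L)
  b <- min(grid$width, side + sample.int(2L, 1L) - 1L)
  if (a * b < length) { a <- min(grid$height, side); b <- min(grid$width, side) }
  if (a * b < length)
    placement_failure("spiral does not fit the grid")
  # spiral traversal of an a x b rectangle from its top-left corner
  visited <- matrix(FALSE, a, b)
  cells <- matrix(0L, a * b, 2L)
  r <- 1L; c <- 1L; dir <- 1L
  dr <- c(0L, 1L, 0L, -1L); dc <- c(1L, 0L, -1L, 0L)
  for (i in seq_len(a * b)) {
    cells[i, ] <- c(r, c)
    visited[r, c] <- TRUE
    nr <- r + dr[dir]; nc <- c + dc[dir]
    if (nr < 1L || nr > a || nc < 1L || nc > b || visited[nr, nc]) {
      dir <- dir %% 4L + 1L
      nr <- r + dr[dir]; nc <- c + dc[dir]
    }
    r <- nr; c <- nc
  }
  cells <- cells[seq_len(length), , drop = FALSE]
  # random symmetry of the rectangle, then random placement on the grid
  if (sample.int(2L, 1L) == 2L) cells[, 1L] <- a + 1L - cells[, 1L]
  if (sample.int(2L, 1L) == 2L) cells[, 2L] <- b + 1L - cells[, 2L]
  if (sample.int(2L, 1L) == 2L) { cells <- cells[, 2L:1L, drop = FALSE]; tmp <- a; a <- b; b <- tmp }
  if (sample.int(2L, 1L) == 2L) cells <- cells[rev(seq_len(nrow(cells))), , drop = FALSE]
  r0 <- sample.int(grid$height - a + 1L, 1L) - 1L
  c0 <- sample.int(grid$width - b + 1L, 1L) - 1L
  cells[, 1L] <- cells[, 1L] + r0
  cells[, 2L] <- cells[, 2L] + c0
  colnames(cells) <- c("row", "col")
  cells
}

new_stimulus <- function(task, grid, target_path, distractor_paths,
                         target_colors, distractor_colors, cue_activation,
                         extras, correct_action, length, n_distractors) {
  paths <- c(list(target_path), distractor_paths)
  cols <- c(list(target_colors), distractor_colors)
  cells <- do.call(rbind, paths)
  colors <- unlist(cols, use.names = FALSE)
  structure(
    list(task = task, grid = grid,
         target_path = target_path, distractor_paths = distractor_paths,
         cells = cbind(cells, color = as.integer(colors)),
         cue_activation = cue_activation, extras = extras,
         correct_action = as.integer(correct_action),
         length = as.integer(length),
         n_distractors = as.integer(n_distractors)),
    class = "vr_stimulus"
  )
}

#' @export
print.vr_stimulus <- function(x, ...) {
  cat(sprintf(
    "<vr_stimulus> task=%s, length=%d, %d distractor(s), correct action %d\n",
    x$task, x$length, x$n_distractors, x$correct_action))
  invisible(x)
}

#' Generate a curve-tracing stimulus
#'
#' The target curve starts with a red pixel, continues with green pixels and
#' ends with a blue pixel that is the correct eye-movement target. Each
#' distractor curve is all green with a blue end pixel. Curves are mutually
#' disjoint and never 4-adjacent to each other.
#'
#' @param length Curve length in pixels (at least 2; `length = 2` gives the
#'   red-blue pixel pair used at the start of the curriculum).
#' @param n_distractors Number of distractor curves (default 1).
#' @param spiral If `TRUE`, the target curve is an inward rectangular spiral
#'   (lengths up to 25 on the default grid).
#' @param grid A [grid_spec()].
#' @return A `vr_stimulus`.
#' @examples
#' set.seed(1)
#' make_trace_stimulus(9)
#' @export
make_trace_stimulus <- function(length, n_distractors = 1L, spiral = FALSE,
                                grid = grid_spec()) {
  length <- as.integer(length)
  stopifnot(length >= 2L, n_distractors >= 0L)
  for (attempt in seq_len(25L)) {
    res <- tryCatch({
      target <- if (spiral) spiral_path(length, grid)
                else sample_path(length, grid)
      occupied <- target
      dpaths <- vector("list", n_distractors)
      for (d in seq_len(n_distractors)) {
        dpaths[[d]] <- sample_path(length, grid, occupied)
        occupied <- rbind(occupied, dpaths[[d]])
      }
      list(target = target, dpaths = dpaths)
    }, vr_placement_failure = function(e) e)
    if (!inherits(res, "vr_placement_failure")) {
      tcol <- c(vr_colors["red"],
                rep(vr_colors["green"], length - 2L), vr_colors["blue"])
      dcol <- lapply(res$dpaths, function(p)
        c(rep(vr_colors["green"], length - 1L), vr_colors["blue"]))
      endc <- res$target[length, ]
      return(new_stimulus(
        "trace", grid, res$target, res$dpaths, tcol, dcol,
        cue_activation = c(0, 0), extras = c(0, 0),
        correct_action = cell_id(endc[1L], endc[2L], grid),
        length = length, n_distractors = n_distractors))
    }
  }
  placement_failure("could not place the trace stimulus")
}

#' Generate a search-then-trace stimulus
#'
#' Two curves of equal length: one starts with a red marker, the other with
#' a brown marker; both continue green and end with a blue pixel. One of the
#' two extra input units is activated as the color cue; the correct action
#' is the blue end of the curve whose marker matches the cue.
#'
#' @param length Curve length in pixels (at least 3).
#' @param cue_color `"red"`, `"brown"`, or `NULL` to choose uniformly.
#' @param grid A [grid_spec()].
#' @return A `vr_stimulus`.
#' @export
make_search_then_trace_stimulus <- function(length, cue_color = NULL,
                                            grid = grid_spec()) {
  length <- as.integer(length)
  stopifnot(length >= 3L)
  for (attempt in seq_len(25L)) {
    res <- tryCatch({
      p1 <- sample_path(length, grid)
      p2 <- sample_path(length, grid, p1)
      list(p1 = p1, p2 = p2)
    }, vr_placement_failure = function(e) e)
    if (!inherits(res, "vr_placement_failure")) {
      cue <- if (is.null(cue_color)) c("red", "brown")[sample.int(2L, 1L)]
             else match.arg(cue_color, c("red", "brown"))
      # marker colors are tied to the curves; the cue decides which is target
      body <- c(rep(vr_colors["green"], length - 2L), vr_colors["blue"])
      col1 <- c(vr_colors["red"], body)
      col2 <- c(vr_colors["brown"], body)
      if (cue == "red") {
        target <- res$p1; tcol <- col1; dis <- res$p2; dcol <- col2
      } else {
        target <- res$p2; tcol <- col2; dis <- res$p1; dcol <- col1
      }
      cuevec <- if (cue == "red") c(1, 0) else c(0, 1)
      endc <- target[length, ]
      return(new_stimulus(
        "search_then_trace", grid, target, list(dis), tcol, list(dcol),
        cue_activation = cuevec, extras = cuevec,
        correct_action = cell_id(endc[1L], endc[2L], grid),
        length = length, n_distractors = 1L))
    }
  }
  placement_failure("could not place the search-then-trace stimulus")
}

#' Generate a trace-then-search stimulus
#'
#' The target curve starts with the single blue pixel, continues green and
#' ends with a colored marker (red or brown); the distractor curve is green
#' with the other marker color at its end. With `with_external = TRUE` the
#' two extra units are activated as selectable eye-movement targets (their
#' colors are fixed: the first is red, the second brown) and the correct
#' action is the extra unit matching the target's end marker. With
#' `with_external = FALSE` (the curriculum's tracing pre-stages) the correct
#' action is the grid location of the target's end marker.
#'
#' @param length Curve length in pixels (at least 2).
#' @param with_external Activate the external colored eye-movement targets.
#' @param end_color `"red"`, `"brown"`, or `NULL` to choose uniformly.
#' @param grid A [grid_spec()].
#' @return A `vr_stimulus`.
#' @export
make_trace_then_search_stimulus <- function(length, with_external = TRUE,
                                            end_color = NULL,
                                            grid = grid_spec()) {
  length <- as.integer(length)
  stopifnot(length >= 2L)
  for (attempt in seq_len(25L)) {
    res <- tryCatch({
      p1 <- sample_path(length, grid)
      p2 <- sample_path(length, grid, p1)
      list(p1 = p1, p2 = p2)
    }, vr_placement_failure = function(e) e)
    if (!inherits(res, "vr_placement_failure")) {
      endcol <- if (is.null(end_color)) c("red", "brown")[sample.int(2L, 1L)]
                else match.arg(end_color, c("red", "brown"))
      other <- if (endcol == "red") "brown" else "red"
      tcol <- c(vr_colors["blue"], rep(vr_colors["green"], length - 2L),
                vr_colors[endcol])
      dcol <- c(rep(vr_colors["green"], length - 1L), vr_colors[other])
      P <- grid$height * grid$width
      correct <- if (with_external) P + unname(vr_colors[endcol])
                 else cell_id(res$p1[length, 1L], res$p1[length, 2L], grid)
      return(new_stimulus(
        "trace_then_search", grid, res$p1, list(res$p2), tcol, list(dcol),
        cue_activation = c(0, 0),
        extras = if (with_external) c(1, 1) else c(0, 0),
        correct_action = correct, length = length, n_distractors = 1L))
    }
  }
  placement_failure("could not place the trace-then-search stimulus")
}

#' Encode a stimulus as input-layer activity
#'
#' One-hot activity over the four color channels at every occupied cell
#' (value 1), zero elsewhere, plus the activities of the two extra input
#' units (the color cue for search-then-trace, the always-on colored
#' eye-movement targets for trace-then-search, zero for plain tracing).
#'
#' @param s A `vr_stimulus`.
#' @return A list with `cells` (0-based integer matrix row, col, channel),
#'   `values`, `extras`, and the 0-based `correct` action index, the form
#'   consumed by the simulation core. Use [input_tensor()] for the dense
#'   array view.
#' @export
encode_stimulus <- function(s) {
  stopifnot(inherits(s, "vr_stimulus"))
  if (any(s$cells[, 3L] < 1L | s$cells[, 3L] > s$grid$n_colors))
    stop("unknown color in stimulus")
  if (anyDuplicated(s$cells[, 1L:2L]) > 0L)
    stop("a cell carries more than one color")
  list(cells = cbind(s$cells[, 1L, drop = TRUE] - 1L,
                     s$cells[, 2L, drop = TRUE] - 1L,
                     s$cells[, 3L, drop = TRUE] - 1L),
       values = rep(1.0, nrow(s$cells)),
       extras = as.numeric(s$extras),
       correct = s$correct_action - 1L)
}

#' Dense input tensor of a stimulus
#'
#' @param s A `vr_stimulus`.
#' @return A list with `grid`, a `height x width x 4` array of one-hot color
#'   activities, and `extras`, the two extra-unit activities.
#' @export
input_tensor <- function(s) {
  enc <- encode_stimulus(s)
  arr <- array(0, dim = c(s$grid$height, s$grid$width, s$grid$n_colors))
  for (i in seq_len(nrow(enc$cells)))
    arr[enc$cells[i, 1L] + 1L, enc$cells[i, 2L] + 1L,
        enc$cells[i, 3L] + 1L] <- enc$values[i]
  list(grid = arr, extras = enc$extras)
}

#' Reward of an action on a stimulus
#'
#' Binary reward: 1 if the chosen action is the stimulus' correct action,
#' 0 otherwise.
#'
#' @param s A `vr_stimulus`.
#' @param action Action index in `1..(height*width + 2)` (grid cells in
#'   row-major order, then the red and brown extra units).
#' @return 1.0 or 0.0.
#' @export
stimulus_reward <- function(s, action) {
  stopifnot(inherits(s, "vr_stimulus"))
  n_actions <- s$grid$height * s$grid$width + s$grid$n_extra_units
  if (!is.numeric(action) || length(action) != 1L || is.na(action) ||
      action < 1 || action > n_actions)
    stop("action out of range")
  if (as.integer(action) == s$correct_action) 1.0 else 0.0
}

#' Stimulus sampler for a task
#'
#' Returns a zero-argument function that draws a fresh random stimulus of
#' the requested kind each time it is called (training and test stimuli are
#' never reused).
#'
#' @param task One of `"trace"`, `"search_then_trace"`,
#'   `"trace_then_search"`.
#' @param length Curve length in pixels.
#' @param n_distractors Distractor count (trace task only).
#' @param spiral Spiral target curve (trace task only).
#' @param with_external Activate external targets (trace-then-search only).
#' @param grid A [grid_spec()].
#' @return A function producing `vr_stimulus` objects.
#' @export
stimulus_sampler <- function(task = c("trace", "search_then_trace",
                                      "trace_then_search"),
                             length, n_distractors = 1L, spiral = FALSE,
                             with_external = TRUE, grid = grid_spec()) {
  task <- match.arg(task)
  force(length); force(n_distractors); force(spiral); force(with_external)
  force(grid)
  switch(task,
    trace = function() make_trace_stimulus(length, n_distractors, spiral,
                                           grid),
    search_then_trace = function()
      make_search_then_trace_stimulus(length, grid = grid),
    trace_then_search = function()
      make_trace_then_search_stimulus(length, with_external, grid = grid))
}
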