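#' Session design configuration
#'
#' Captures the design of one experimental session: study version
#' (continuous "hedge" with ten target bins, or discrete "box" with up to
#' eight boxes), cohort, randomization mode, and counts. Defaults follow
#' the published session designs: children receive 4 training + 15 test
#' trials; in the fixed-retest designs adults receive 30 test trials
#' (hedge, each of ten bins three times) or 32 (box, each of eight boxes
#' four times), and children in the box version see each of five boxes
#' exactly three times.
#'
#' @param version `"hedge"` (continuous outcome) or `"box"` (discrete).
#' @param cohort `"child"` or `"adult"`; sets trial-count and box-count
#'   defaults.
#' @param mode `"randomized"` (fresh constrained randomization) or
#'   `"fixed_retest"` (a sequence randomized once and held constant across
#'   participants and test days).
#' @param n_training Number of training trials (at least 3; default 4).
#' @param n_test Number of test trials. Defaults: child 15; adult 30
#'   (hedge) or 32 (box).
#' @param n_bins Number of target bins (hedge version), default 10.
#' @param n_boxes Number of boxes (box version). Defaults: child 5,
#'   adult 8.
#' @param agents Character vector of agent labels (default sheep, monkey,
#'   pig).
#' @param colors Character vector of target colors (default blue, green,
#'   yellow, red).
#' @param max_run Maximum number of consecutive trials sharing the same
#'   agent, color, bin or box (default 2).
#' @param seed Integer seed making the session reproducible; `NULL` uses
#'   the current RNG state.
#' @return An object of class `session_config`.
#' @examples
#' session_config(version = "box", cohort = "child", seed = 7)
#' @export
session_config <- function(version = c("hedge", "box"),
                           cohort = c("child", "adult"),
                           mode = c("randomized", "fixed_retest"),
                           n_training = 4,
                           n_test = NULL,
                           n_bins = 10,
                           n_boxes = NULL,
                           agents = c("sheep", "monkey", "pig"),
                           colors = c("blue", "green", "yellow", "red"),
                           max_run = 2,
                           seed = 1L) {
  version <- match.arg(version)
  cohort <- match.arg(cohort)
  mode <- match.arg(mode)
  if (is.null(n_test)) {
    n_test <- if (cohort == "child") 15L else if (version == "hedge") 30L else 32L
  }
  if (is.null(n_boxes)) n_boxes <- if (cohort == "child") 5L else 8L
  n_training <- as.integer(n_training)
  n_test <- as.integer(n_test)
  n_bins <- as.integer(n_bins)
  n_boxes <- as.integer(n_boxes)
  if (n_test < 1) abort("`n_test` must be positive.")
  if (n_boxes < 1 || n_boxes > 8) abort("`n_boxes` must be between 1 and 8.")
  if (max_run < 1) abort("`max_run` must be at least 1.")
  structure(
    list(
      version = version, cohort = cohort, mode = mode,
      n_training = n_training, n_test = n_test,
      n_bins = n_bins, n_boxes = n_boxes,
      agents = agents, colors = colors,
      max_run = as.integer(max_run),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> %s %s (%s): %d training + %d test trials, seed %s\n",
              x$cohort, x$version, x$mode, x$n_training, x$n_test,
              if (is.null(x$seed)) "<current RNG>" else x$seed))
  invisible(x)
}

## counts summing to n over k categories, equal up to a remainder of +1s
balanced_counts <- function(k, n) {
  counts <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) {
    extra <- sample.int(k, r)
    counts[extra] <- counts[extra] + 1L
  }
  counts
}

## shuffle a multiset given by `counts` (values 1..k) so that no value
## occurs more than `max_run` times consecutively; bounded rejection
## sampling, errors when the constraint set appears unsatisfiable
sample_run_constrained <- function(counts, max_run, max_tries = 2000L) {
  values <- rep(seq_along(counts), counts)
  if (length(values) <= 1) return(values)
  for (i in seq_len(max_tries)) {
    perm <- sample(values)
    if (max(rle(perm)$lengths) <= max_run) return(perm)
  }
  abort(sprintf(
    "Failed to generate a sequence with runs <= %d after %d tries; constraints may be unsatisfiable.",
    max_run, max_tries))
}

## per-bin target counts for hedge test trials. A 15-trial, 10-bin session
## uses the published scheme: every bin once, plus one repeat drawn from
## each adjacent pair {0,1}, {2,3}, ..., {8,9}. Other sizes fall back to
## equal counts up to a remainder of 1.
hedge_bin_counts <- function(n_bins, n_test) {
  if (n_bins == 10L && n_test == 15L) {
    counts <- rep(1L, 10)
    repeats <- vapply(seq.int(1L, 9L, by = 2L),
                      function(i) sample(c(i, i + 1L), 1L), integer(1))
    counts[repeats] <- counts[repeats] + 1L
    counts
  } else {
    balanced_counts(n_bins, n_test)
  }
}

#' Sample a target x-coordinate uniformly inside a bin
#'
#' Exact target coordinates are drawn uniformly within the selected bin,
#' on the half-open interval `[bin / n_bins, (bin + 1) / n_bins)`.
#'
#' @param bin 0-based bin index (scalar or vector).
#' @param layout A [scene_layout()] supplying `n_bins`.
#' @return Numeric vector of x-coordinates, one per element of `bin`.
#' @examples
#' set.seed(1)
#' sample_coordinate_in_bin(0, scene_layout())
#' @export
sample_coordinate_in_bin <- function(bin, layout) {
  stopifnot(inherits(layout, "scene_layout"))
  bin <- as.integer(bin)
  if (any(bin < 0 | bin >= layout$n_bins)) {
    abort(sprintf("Bin index out of range [0, %d).", layout$n_bins))
  }
  (bin + runif(length(bin))) / layout$n_bins
}

## uniform coordinate inside a (possibly unequal) box interval
sample_coordinate_in_box <- function(box, layout) {
  stopifnot(inherits(layout, "scene_layout"))
  box <- as.integer(box)
  if (any(box < 0 | box >= layout$n_boxes)) {
    abort(sprintf("Box index out of range [0, %d).", layout$n_boxes))
  }
  lo <- layout$box_edges[box + 1L]
  hi <- layout$box_edges[box + 2L]
  lo + runif(length(box)) * (hi - lo)
}

#' Training block of a session
#'
#' The first training trial gives full visual access to the target flight
#' and landing position; the second and third give partial access (flight
#' visible, landing hidden); any further training trials are fully covered,
#' completing the ramp toward the test trials, which give no visual access.
#' Voice-over descriptions accompany the first trial of each access type.
#'
#' @param config A [session_config()].
#' @param layout A [scene_layout()]; defaults to one matching the config's
#'   bin/box counts.
#' @return A tibble of training trials (columns as in
#'   [generate_session()]).
#' @export
training_block <- function(config, layout = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (config$n_training < 3) {
    abort("`n_training` must be at least 3 (full, partial, partial access).")
  }
  layout <- layout %||%
    scene_layout(n_bins = config$n_bins, n_boxes = config$n_boxes)
  run <- function() build_training(config, layout)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

build_training <- function(config, layout) {
  n <- config$n_training
  visibility <- c("full", "partial", "partial", rep("none", max(0, n - 3)))
  phase <- c("training_full", "training_partial", "training_partial",
             rep("training_covered", max(0, n - 3)))
  agent <- sample(config$agents, n, replace = TRUE)
  color <- sample(config$colors, n, replace = TRUE)
  if (config$version == "hedge") {
    bin <- sample.int(config$n_bins, n, replace = TRUE) - 1L
    box <- rep(NA_integer_, n)
    target_x <- sample_coordinate_in_bin(bin, layout)
  } else {
    box <- sample.int(config$n_boxes, n, replace = TRUE) - 1L
    bin <- rep(NA_integer_, n)
    target_x <- sample_coordinate_in_box(box, layout)
  }
  tibble(
    index = seq_len(n) - 1L,
    phase = phase[seq_len(n)],
    agent = agent, color = color,
    bin = bin, box = box, target_x = target_x,
    visibility = visibility[seq_len(n)],
    # voice-over on the first full-access and first partial-access trial
    voiceover = seq_len(n) %in% c(1L, 2L)
  )
}

#' Generate a full session of training and test trials
#'
#' Produces an ordered trial list under the task's randomization
#' constraints: over the test trials, agents and target colors appear
#' equally often (up to a remainder of one) and no agent, color, bin or
#' box occurs more than `max_run` (default two) times in a row. In the
#' hedge version the viewport is divided into ten bins and exact target
#' coordinates are drawn uniformly within the selected bin; a 15-trial
#' ten-bin session uses each bin once plus one repeat from each adjacent
#' bin pair. In the box version each box occurs equally often (exactly
#' equal when `n_test` is divisible by `n_boxes`). Deterministic given
#' `config$seed`.
#'
#' @inheritParams training_block
#' @return A tibble with one row per trial and columns `index` (0-based),
#'   `phase`, `agent`, `color`, `bin`, `box`, `target_x`, `visibility`,
#'   `voiceover`. The config is attached as attribute `"config"`.
#' @examples
#' sess <- generate_session(session_config(version = "box", seed = 3))
#' table(sess$box[sess$phase == "test"])
#' @export
generate_session <- function(config, layout = NULL) {
  stopifnot(inherits(config, "session_config"))
  layout <- layout %||%
    scene_layout(n_bins = config$n_bins, n_boxes = config$n_boxes)
  run <- function() {
    training <- build_training(config, layout)
    test <- build_test_block(config, layout)
    test$index <- test$index + nrow(training)
    out <- dplyr::bind_rows(training, test)
    attr(out, "config") <- config
    out
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

build_test_block <- function(config, layout) {
  n <- config$n_test
  agent_counts <- balanced_counts(length(config$agents), n)
  color_counts <- balanced_counts(length(config$colors), n)
  agent <- config$agents[sample_run_constrained(agent_counts, config$max_run)]
  color <- config$colors[sample_run_constrained(color_counts, config$max_run)]
  if (config$version == "hedge") {
    bin_counts <- hedge_bin_counts(config$n_bins, n)
    bin <- sample_run_constrained(bin_counts, config$max_run) - 1L
    box <- rep(NA_integer_, n)
    target_x <- sample_coordinate_in_bin(bin, layout)
  } else {
    box_counts <- balanced_counts(config$n_boxes, n)
    box <- sample_run_constrained(box_counts, config$max_run) - 1L
    bin <- rep(NA_integer_, n)
    target_x <- sample_coordinate_in_box(box, layout)
  }
  tibble(
    index = seq_len(n) - 1L,
    phase = "test",
    agent = agent, color = color,
    bin = bin, box = box, target_x = target_x,
    visibility = "none",
    voiceover = seq_len(n) == 1L # first test trial carries the voice-over
  )
}

#' Fixed retest sequence
#'
#' For test-retest designs the trial sequence is randomized once and then
#' held constant across participants and both test days. The sequence is a
#' deterministic function of the configuration (including its seed): two
#' calls with the same config return identical trial lists.
#'
#' @inheritParams training_block
#' @return A tibble of trials, as [generate_session()].
#' @examples
#' cfg <- session_config(cohort = "adult", mode = "fixed_retest", seed = 11)
#' seq1 <- fixed_retest_sequence(cfg)
#' seq2 <- fixed_retest_sequence(cfg)
#' identical(seq1, seq2)
#' @export
fixed_retest_sequence <- function(config, layout = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (config$mode != "fixed_retest") {
    abort("`config$mode` must be \"fixed_retest\".")
  }
  if (is.null(config$seed)) {
    abort("A fixed retest sequence requires an explicit `seed` in the config.")
  }
  generate_session(config, layout)
}
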