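#' Active categorical perception task environments
#'
#' The animat sits at the bottom of a 16-column world with periodic
#' boundaries. Each trial drops one block from 36 rows up; the block moves
#' one unit down and one unit sideways (left or right) per time step, so it
#' lands after 36 steps displaced 36 columns (mod 16, i.e. 4) from its start.
#' The animat is 3 units wide with sensors on its outer units (the middle is
#' a blind spot); a sensor switches on whenever a block unit is in the column
#' directly above it. Blocks in the catch set must overlap the animat when
#' they land; blocks in the avoid set must not.
#'
#' @param task Task number 1--4: Task 1 catches size 1 / avoids size 3;
#'   Task 2 catches 1 / avoids 2; Task 3 catches 1 and 4 / avoids 2 and 3;
#'   Task 4 catches 3 and 6 / avoids 4 and 5. Tasks 1--2 show each of their
#'   two sizes twice per 4-slot cycle so that every task runs 128 trials.
#' @param disabled_sensor Optional sensor index (1 or 2) forced to 0 every
#'   step.
#' @param disabled_motor Optional motor index (1 or 2) ignored for movement.
#' @param sensor_noise Per-sensor, per-step flip probability (0 or 0.01).
#' @param noise_repetitions Repetitions of each trial when noise is active
#'   (fitness is the average across repetitions).
#' @return A `task_spec` object.
#' @export
task_spec <- function(task = 1L, disabled_sensor = NULL, disabled_motor = NULL,
                      sensor_noise = 0, noise_repetitions = 20L) {
  defs <- list(
    `1` = list(sizes = c(1L, 3L, 1L, 3L), is_catch = c(1L, 0L, 1L, 0L)),
    `2` = list(sizes = c(1L, 2L, 1L, 2L), is_catch = c(1L, 0L, 1L, 0L)),
    `3` = list(sizes = c(1L, 2L, 3L, 4L), is_catch = c(1L, 0L, 0L, 1L)),
    `4` = list(sizes = c(3L, 4L, 5L, 6L), is_catch = c(1L, 0L, 0L, 1L)))
  if (!as.character(task) %in% names(defs)) stop("task must be 1, 2, 3 or 4")
  d <- defs[[as.character(task)]]
  if (sensor_noise < 0 || sensor_noise > 1) stop("sensor_noise must be in [0, 1]")
  structure(list(task = as.integer(task),
                 sizes = d$sizes, is_catch = d$is_catch,
                 catch_sizes = sort(unique(d$sizes[d$is_catch == 1L])),
                 avoid_sizes = sort(unique(d$sizes[d$is_catch == 0L])),
                 world_width = 16L, fall_steps = 36L,
                 disabled_sensor = if (is.null(disabled_sensor)) -1L
                                   else as.integer(disabled_sensor) - 1L,
                 disabled_motor = if (is.null(disabled_motor)) -1L
                                  else as.integer(disabled_motor) - 1L,
                 sensor_noise = sensor_noise,
                 noise_reps = as.integer(noise_repetitions)),
            class = "task_spec")
}

#' Enumerate the 128 test trials of a task
#'
#' All 16 starting columns x 2 fall directions x the task's 4 block-size
#' slots. Starting columns are relative to the animat's leftmost unit.
#'
#' @param task A [task_spec()].
#' @return Data frame with columns `size`, `direction` (+1 right / -1 left),
#'   and `start` (0--15).
#' @export
enumerate_trials <- function(task) {
  stopifnot(inherits(task, "task_spec"))
  grid <- expand.grid(start = 0:15, direction = c(1L, -1L),
                      slot = 1:4, KEEP.OUT.ATTRS = FALSE)
  data.frame(size = task$sizes[grid$slot], direction = grid$direction,
             start = grid$start)
}

#' Run a single trial
#'
#' @param brain A deterministic animat `logic_network`.
#' @param trial A list or one-row data frame with `size`, `direction`,
#'   `start`.
#' @param task A [task_spec()].
#' @return List with `caught`, `correct`, `trajectory` (36 experienced brain
#'   states: sensor bits as written each step, hidden/motor bits carried
#'   from the previous update), `positions` (animat column after each step),
#'   `final_animat` and `final_block` columns.
#' @export
run_trial <- function(brain, trial, task) {
  stopifnot(inherits(brain, "logic_network"), !is.null(brain$next_state))
  res <- cpp_evaluate(brain$next_state, unclass(task), record = TRUE)
  i <- which(res$size == trial$size & res$direction == trial$direction &
             res$start == trial$start)[1]
  if (is.na(i)) stop("trial does not belong to this task")
  list(caught = res$caught[i] > 0.5,
       correct = res$correct[i] > 0.5,
       trajectory = res$trajectories[i, ],
       positions = res$positions[i, ],
       final_animat = res$positions[i, task$fall_steps],
       final_block = (trial$start + task$fall_steps * trial$direction) %% 16L)
}

#' Evaluate a brain on all trials of a task
#'
#' Runs the full 128-trial battery (times `noise_repetitions` under sensor
#' noise) and aggregates fitness and the distribution of experienced brain
#' states.
#'
#' @param brain A deterministic animat `logic_network`.
#' @param task A [task_spec()].
#' @return A `fitness_record`: list with `F` (fraction of correct trials),
#'   `n_correct`, `state_distribution` (named numeric over visited state
#'   codes, summing to 1), `trials` (per-trial data frame), `trajectories`
#'   and `positions` (128 x 36 integer matrices from the first repetition).
#' @export
evaluate_brain <- function(brain, task) {
  stopifnot(inherits(brain, "logic_network"), !is.null(brain$next_state),
            inherits(task, "task_spec"))
  res <- cpp_evaluate(brain$next_state, unclass(task), record = TRUE)
  counts <- res$state_counts
  names(counts) <- 0:255
  counts <- counts[counts > 0]
  structure(list(F = res$F, n_correct = res$n_correct,
                 state_distribution = counts / sum(counts),
                 trials = data.frame(size = res$size,
                                     direction = res$direction,
                                     start = res$start,
                                     caught = res$caught,
                                     correct = res$correct),
                 trajectories = res$trajectories,
                 positions = res$positions),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("fitness_record: F = %.4f (%g/128 correct), %d distinct states\n",
              x$F, x$n_correct, length(x$state_distribution)))
  invisible(x)
}

#' Write per-trial results to CSV
#'
#' @param record A `fitness_record` from [evaluate_brain()].
#' @param path File path.
#' @export
write_trials_csv <- function(record, path) {
  utils::write.csv(record$trials, path, row.names = FALSE)
  invisible(path)
}
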