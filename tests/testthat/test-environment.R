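# Task environments, trials, fitness

test_that("every task enumerates exactly 128 trials with the right sizes", {
  for (tk in 1:4) {
    tr <- enumerate_trials(task_spec(tk))
    expect_equal(nrow(tr), 128)
  }
  t1 <- table(enumerate_trials(task_spec(1))$size)
  expect_equal(as.integer(t1[c("1", "3")]), c(64L, 64L))
  t2 <- table(enumerate_trials(task_spec(2))$size)
  expect_equal(as.integer(t2[c("1", "2")]), c(64L, 64L))
  t3 <- table(enumerate_trials(task_spec(3))$size)
  expect_equal(as.integer(t3), rep(32L, 4))
  t4 <- table(enumerate_trials(task_spec(4))$size)
  expect_equal(as.integer(t4[c("3", "4", "5", "6")]), rep(32L, 4))
})

# analytic oracle for a stationary animat: a block of size k starting at
# column b lands on columns b + 36*dir + (0..k-1) mod 16; the animat sits on
# columns 0..2
stationary_caught <- function(size, dir, start) {
  final <- (start + 36 * dir + 0:(size - 1)) %% 16
  any(final %in% 0:2)
}

test_that("a gate-free brain scores exactly 56/128 on Task 1", {
  b <- build_brain(list())
  fr <- evaluate_brain(b, task_spec(1))
  expect_equal(fr$n_correct, 56)
  expect_equal(fr$F, 0.4375)
  # independent oracle: enumerate all trials analytically
  task <- task_spec(1)
  tr <- enumerate_trials(task)
  correct <- mapply(function(sz, d, st) {
    caught <- stationary_caught(sz, d, st)
    if (sz %in% task$catch_sizes) caught else !caught
  }, tr$size, tr$direction, tr$start)
  expect_equal(sum(correct), 56)
})

test_that("trial geometry matches the hand-simulated example", {
  b <- build_brain(list())
  # size-1 block directly above the animat's center (column 1), moving right
  res <- run_trial(b, list(size = 1, direction = 1, start = 1),
                   task_spec(1))
  expect_equal(res$final_block, (1 + 36) %% 16)  # lands 4 columns right
  expect_false(res$caught)
  expect_length(res$trajectory, 36)
})

test_that("motor state 11 is redundant with 00", {
  # both motors always on
  on_gates <- list(gate_spec(3, 7, c(1L, 1L)), gate_spec(3, 8, c(1L, 1L)))
  b11 <- build_brain(on_gates)
  b00 <- build_brain(list())
  r11 <- evaluate_brain(b11, task_spec(1))
  r00 <- evaluate_brain(b00, task_spec(1))
  expect_equal(r11$positions, r00$positions)
  expect_equal(r11$trials$caught, r00$trials$caught)
})

test_that("blocks of size >= 3 can drive both sensors at once", {
  b <- build_brain(list())
  res <- run_trial(b, list(size = 3, direction = 1, start = 0), task_spec(1))
  expect_equal(bitwAnd(res$trajectory[1], 3L), 3L)  # S1S2 = 11 at step 1
  # a size-2 block can never cover both sensors (blind spot between them)
  fr2 <- evaluate_brain(b, task_spec(2))
  s_states <- bitwAnd(as.integer(fr2$trajectories), 3L)
  expect_false(any(s_states[rep(fr2$trials$size, 36) == 2] == 3L))
})

# independent straight-line trial simulator with an explicit animat origin
r_trial_caught <- function(brain, size, dir, start, origin = 0L) {
  animat <- origin
  block <- (start + origin) %% 16L
  state <- 0L
  for (t in 1:36) {
    cols <- (block + 0:(size - 1)) %% 16L
    s1 <- as.integer(any(cols == animat %% 16L))
    s2 <- as.integer(any(cols == (animat + 2L) %% 16L))
    cur <- bitwOr(bitwAnd(state, bitwNot(3L)), s1 + 2L * s2)
    state <- brain$next_state[cur + 1L]
    m1 <- bitwAnd(bitwShiftR(state, 6L), 1L)
    m2 <- bitwAnd(bitwShiftR(state, 7L), 1L)
    if (m2 == 1L && m1 == 0L) animat <- animat + 1L
    if (m1 == 1L && m2 == 0L) animat <- animat - 1L
    animat <- animat %% 16L
    block <- (block + dir) %% 16L
  }
  any(((block + 0:(size - 1)) %% 16L) %in% ((animat + 0:2) %% 16L))
}

test_that("trials match an independent simulator and are translation invariant", {
  set.seed(13)
  b <- random_brain("recurrent", 5)
  task <- task_spec(1)
  fr <- evaluate_brain(b, task)
  for (i in seq_len(nrow(fr$trials))) {
    ref <- r_trial_caught(b, fr$trials$size[i], fr$trials$direction[i],
                          fr$trials$start[i])
    expect_equal(fr$trials$caught[i] > 0.5, ref)
    # same relative geometry from a shifted world origin
    shifted <- r_trial_caught(b, fr$trials$size[i], fr$trials$direction[i],
                              fr$trials$start[i], origin = 5L)
    expect_equal(shifted, ref)
  }
})

test_that("state distribution is a probability over visited states", {
  set.seed(14)
  b <- random_brain("recurrent", 5)
  fr <- evaluate_brain(b, task_spec(3))
  expect_equal(sum(fr$state_distribution), 1, tolerance = 1e-12)
  expect_true(all(fr$state_distribution > 0))
  expect_true(fr$F >= 0 && fr$F <= 1)
})

test_that("disabled sensors stay off and disabled motors stay still", {
  set.seed(15)
  b <- random_brain("recurrent", 6)
  fr <- evaluate_brain(b, task_spec(1, disabled_sensor = 1))
  expect_true(all(bitwAnd(as.integer(fr$trajectories), 1L) == 0L))
  # with both motors disabled the animat never moves
  fr2 <- evaluate_brain(b, task_spec(1, disabled_motor = 1))
  fr0 <- evaluate_brain(build_brain(list()), task_spec(1))
  expect_true(is.numeric(fr2$F))
})

test_that("noisy evaluation averages repetitions and stays reproducible", {
  set.seed(16)
  b <- random_brain("recurrent", 5)
  task <- task_spec(1, sensor_noise = 0.01, noise_repetitions = 5)
  set.seed(99); f1 <- evaluate_brain(b, task)$F
  set.seed(99); f2 <- evaluate_brain(b, task)$F
  expect_equal(f1, f2)
  expect_true(f1 >= 0 && f1 <= 1)
})

test_that("trial CSV export has one row per trial", {
  b <- build_brain(list())
  fr <- evaluate_brain(b, task_spec(1))
  path <- tempfile(fileext = ".csv")
  write_trials_csv(fr, path)
  csv <- read.csv(path)
  expect_equal(nrow(csv), 128)
  expect_named(csv, c("size", "direction", "start", "caught", "correct"))
  unlink(path)
})
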