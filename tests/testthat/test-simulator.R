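test_that("a symmetric deterministic trial preserves symmetry and ends in
          indecision", {
  rec <- run_trial(trial_config(epsilon = 0, correct_side = 1),
                   params_nonoise)
  expect_equal(rec$S1, rec$S2, tolerance = 1e-14)
  expect_equal(rec$y_L, rec$y_R, tolerance = 1e-14)
  expect_true(all(rec$x == 0))
  expect_true(rec$indecision)
  expect_equal(rec$final_choice, 0)
  expect_false(rec$com)
})

test_that("a deterministic easy trial resolves to the correct side without
          change-of-mind", {
  rec <- run_trial(trial_config(epsilon = 51.2, correct_side = 2),
                   params_nonoise)
  expect_false(rec$indecision)
  expect_equal(rec$initial_choice, 2)
  expect_equal(rec$final_choice, 2)
  expect_false(rec$com)
  expect_gt(rec$rt, 0)
  # the motor read-out ends beyond the opposite target side convention:
  # choice 2 maps to negative positions
  expect_lt(min(rec$x), -700)
})

test_that("the event schedule clamps and releases the modules on time", {
  rec <- run_trial(trial_config(epsilon = 51.2, correct_side = 1),
                   params_nonoise)
  t_stim <- rec$t_stimulus_onset
  # uncertainty module silent until its release 500 ms after stimulus onset
  expect_true(all(rec$y_U[rec$time < t_stim + 500] == 0))
  expect_true(all(rec$y_inh[rec$time < t_stim + 400] == 0))
  # motor module clamped until the decision
  t_dec <- t_stim + rec$rt
  expect_true(all(rec$y_L[rec$time < t_dec] == 0))
  expect_true(all(rec$y_R[rec$time < t_dec] == 0))
  expect_gt(max(rec$y_L), 0)
})

test_that("trajectories stay inside the state-space bounds", {
  for (sd in 1:6) {
    rec <- run_trial(trial_config(epsilon = sample(c(0, 3.2, 25.6), 1),
                                  seed = sd), params_default)
    expect_true(all(rec$S1 >= 0 & rec$S1 <= 1))
    expect_true(all(rec$S2 >= 0 & rec$S2 <= 1))
    expect_true(all(rec$y_inh >= 0))
    expect_true(all(rec$y_U >= 0))
    expect_true(all(rec$y_L >= 0))
    expect_true(all(rec$y_R >= 0))
  }
})

test_that("relabelling the populations mirrors the trajectory exactly", {
  a <- run_trial(trial_config(epsilon = 12.8, correct_side = 1),
                 params_nonoise)
  b <- run_trial(trial_config(epsilon = 12.8, correct_side = 2),
                 params_nonoise)
  expect_equal(a$S1, b$S2, tolerance = 1e-14)
  expect_equal(a$S2, b$S1, tolerance = 1e-14)
  expect_equal(a$y_L, b$y_R, tolerance = 1e-14)
  expect_equal(a$x, -b$x, tolerance = 1e-12)
  expect_equal(a$rt, b$rt)
  expect_equal(a$final_choice, 3L - b$final_choice)
})

test_that("blocks are bitwise reproducible from the master seed", {
  t1 <- run_block(10, c(0, 6.4), params_default, master_seed = 314)
  t2 <- run_block(10, c(0, 6.4), params_default, master_seed = 314)
  expect_identical(t1$summary, t2$summary)
  t3 <- run_block(10, c(0, 6.4), params_default, master_seed = 315)
  expect_false(identical(t3$summary$rt_ms, t1$summary$rt_ms))
  # correct side is counterbalanced within each condition
  tab <- table(t1$summary$epsilon, t1$summary$correct_side)
  expect_true(all(tab == 5))
})

test_that("a single trial is reproducible from its own seed", {
  r1 <- run_trial(trial_config(epsilon = 6.4, seed = 123), params_default)
  r2 <- run_trial(trial_config(epsilon = 6.4, seed = 123), params_default)
  expect_identical(r1$rt, r2$rt)
  expect_identical(r1$S1, r2$S1)
})

test_that("the engine summary agrees with the trace-level classifier", {
  set.seed(404)
  for (i in 1:40) {
    rec <- run_trial(trial_config(epsilon = sample(c(0, 3.2, 6.4), 1),
                                  correct_side = sample(1:2, 1),
                                  seed = sample.int(1e7, 1)),
                     params_default)
    cls <- classify_change_of_mind(rec)
    expect_identical(rec$com, cls$com)
    if (rec$com) expect_identical(rec$com_direction, cls$direction)
    m <- uncertainty_measures(rec)
    expect_equal(rec$uncertainty_peak, m$peak, tolerance = 1e-12)
    expect_equal(rec$uncertainty_area, m$area, tolerance = 1e-9)
  }
})

test_that("deterministic trajectories converge as the step shrinks", {
  r1 <- run_trial(trial_config(epsilon = 51.2, correct_side = 1, dt = 0.5),
                  params_nonoise)
  r2 <- run_trial(trial_config(epsilon = 51.2, correct_side = 1, dt = 0.05),
                  params_nonoise)
  expect_equal(r1$final_choice, r2$final_choice)
  expect_lt(abs(r1$rt - r2$rt), 5)
  # compare S1 on the coarse grid (forward Euler: O(dt) agreement)
  idx <- match(r1$time, r2$time)
  expect_lt(max(abs(r1$S1 - r2$S1[idx]), na.rm = TRUE), 5e-3)
})

test_that("indecision and response-time bookkeeping are consistent", {
  ts <- run_block(60, c(0, 51.2), params_default, master_seed = 2024)
  s <- ts$summary
  expect_true(all(is.na(s$rt_ms[s$final_choice == 0 & !s$indecision])))
  expect_true(all(s$final_choice[!s$indecision] %in% 1:2))
  expect_true(all(!s$com[s$indecision]))
  expect_true(all(s$rt_ms[!is.na(s$rt_ms)] >= 0))
})
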