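test_that("causal smoothing has the stated closed forms", {
  const <- cbind(rep(3, 50), rep(7, 50))
  expect_equal(smooth_positions(const, 3), const)
  # unit step: trailing mean ramps linearly and completes after the window
  step <- cbind(c(rep(0, 30), rep(1, 60)), rep(0, 90))
  sm <- smooth_positions(step, 3)
  expect_equal(sm[30, 1], 0)
  expect_equal(sm[45, 1], 15 / 30)       # halfway through the 30-tick window
  expect_equal(sm[60, 1], 1)             # fully ramped after 3 s
  expect_true(all(diff(sm[30:60, 1]) >= 0))
  # single-sample window is the identity
  rnd <- cbind(runif(20), runif(20))
  expect_equal(smooth_positions(rnd, 0.1), rnd)
  expect_equal(nrow(smooth_positions(rnd[0, , drop = FALSE], 3)), 0L)
})

test_that("closed-loop sessions are deterministic and causally consistent", {
  art <- acc_artifacts()
  s1 <- run_jumper_session(art$map, art$model, intention_config(fidelity = 1),
                           jumper_config(n_trials = 3), seed = 77)
  s2 <- run_jumper_session(art$map, art$model, intention_config(fidelity = 1),
                           jumper_config(n_trials = 3), seed = 77)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$streams, s2$streams)
  expect_identical(s1$raster$counts, s2$raster$counts)
  # the logged decode at tick k is reproduced from spikes up to tick k only
  k <- nrow(s1$streams)
  r_trunc <- spike_raster(s1$raster$counts[, seq_len(k * 10), drop = FALSE],
                          bin_s = 0.01, unit_ids = s1$raster$unit_ids)
  dec <- decode_stream(art$model, r_trunc)
  expect_equal(unname(tail(cbind(dec$x_cm, dec$y_cm), 1)),
               unname(cbind(s1$streams$decoded_x, s1$streams$decoded_y)[k, ,
                                                                        drop = FALSE]),
               tolerance = 1e-10)
  # unit mismatch between agent map and model is a hard error
  bad_map <- art$map
  bad_map$unit_ids <- rev(bad_map$unit_ids)
  expect_error(run_jumper_session(bad_map, art$model,
                                  intention_config(), jumper_config(n_trials = 1),
                                  seed = 1),
               "unit")
})

test_that("Jedi reward accounting is monotone, capped, and zero off-goal", {
  art <- acc_artifacts()
  jed <- art$jedi1
  expect_true(all(jed$trials$reward_ml >= 0))
  expect_true(all(jed$trials$reward_ml <= 0.5 + 1e-9))
  cap_trials <- jed$trials[jed$trials$outcome == "reward_cap", ]
  expect_gt(nrow(cap_trials), 0)
  # a capped trial must have spent exactly cap / rate seconds in the goal
  for (i in seq_len(nrow(cap_trials))) {
    tr <- cap_trials[i, ]
    sel <- jed$streams$t_s > tr$t_start_s & jed$streams$t_s <= tr$t_end_s
    obj <- cbind(jed$streams$avatar_x, jed$streams$avatar_y)[sel, ]
    in_goal <- mapbmi:::dist_xy(obj, c(tr$goal_x_cm, tr$goal_y_cm)) <=
      jed$goal_radius_cm
    expect_equal(sum(in_goal) * 0.1 * 0.01, 0.5, tolerance = 0.011)
  }
  # trials are contiguous and goals respect the minimum jump
  expect_equal(jed$trials$t_start_s[-1],
               jed$trials$t_end_s[-nrow(jed$trials)])
  g <- cbind(jed$trials$goal_x_cm, jed$trials$goal_y_cm)
  jumps <- sqrt(rowSums(diff(g)^2))
  expect_true(all(jumps >= jed$config$min_goal_jump_cm))
})

test_that("Jumper durations at fidelity 1 stochastically dominate fidelity 0", {
  art <- acc_artifacts()
  d1 <- art$jumper1$trials$t_end_s - art$jumper1$trials$t_start_s
  d0 <- art$jumper0$trials$t_end_s - art$jumper0$trials$t_start_s
  expect_equal(length(d1), 50L)
  w <- suppressWarnings(wilcox.test(d1, d0, alternative = "less"))
  expect_lt(w$p.value, 0.01)
})

test_that("offline Jumper replay matches the reach rule", {
  # constructed decoded stream: parked at (10,10) for 4 s, then at (80,80)
  dec <- data.frame(x_cm = c(rep(10, 40), rep(80, 200)),
                    y_cm = c(rep(10, 40), rep(80, 200)))
  goals <- rbind(c(80, 80), c(10, 10))
  cfg <- jumper_config(smoothing_s = 0.1, timeout_s = 10)
  rep1 <- replay_jumper(dec, goals, cfg, goal_radius_cm = 10)
  expect_true(rep1$reached[1])
  expect_equal(rep1$duration_s[1], 4.1, tolerance = 1e-9)
  expect_false(rep1$reached[2])           # stream never returns to (10,10)
  expect_equal(rep1$duration_s[2], 10)    # censored at the timeout
})
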