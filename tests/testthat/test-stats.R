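test_that("empirical p-values use the add-one rule and are never zero", {
  nd <- null_distribution("x", observed = -5, shuffled = 1:200, tail = "less")
  expect_equal(nd$p_empirical, 1 / 201)
  expect_gt(nd$p_empirical, 0)
  nd2 <- null_distribution("x", observed = 500, shuffled = 1:200,
                           tail = "less")
  expect_equal(nd2$p_empirical, 1)
  nd3 <- null_distribution("x", observed = 3, shuffled = c(1, 2, 3, 4),
                           tail = "greater")
  expect_equal(nd3$p_empirical, (1 + 2) / 5)
  expect_error(null_distribution("x", 1, numeric(0)), "one shuffle")
})

test_that("angle histograms recover straight, reversed, and diffuse motion", {
  fwd <- cbind(seq(10, 80, by = 1), seq(10, 80, by = 1))
  h <- angle_to_goal_histogram(fwd, c(90, 90))
  expect_equal(h$circular_mean_deg, 0, tolerance = 1e-9)
  expect_equal(h$resultant_length, 1, tolerance = 1e-12)
  expect_lte(abs(h$mode_deg), 7.5)   # the mode bin straddles 0
  away <- cbind(seq(80, 30, by = -1), rep(50, 51))
  h2 <- angle_to_goal_histogram(away, c(90, 50))
  expect_equal(abs(h2$circular_mean_deg), 180, tolerance = 1e-9)
  set.seed(5)
  walk <- cbind(cumsum(rnorm(4000)), cumsum(rnorm(4000))) / 10 + 50
  h3 <- angle_to_goal_histogram(walk, c(50, 50), min_step_cm = 0)
  expect_lte(h3$resultant_length, 0.1)
  expect_warning(angle_to_goal_histogram(cbind(c(1, 1.0001), c(1, 1)),
                                         c(5, 5)),
                 "min_step_cm")
  expect_error(angle_to_goal_histogram(fwd, c(90, 90), bin_deg = 17),
               "divide")
})

test_that("mean goal distance applies the rotation exclusion and known values", {
  pinned <- cbind(rep(30, 100), rep(40, 100))
  expect_equal(mean_goal_distance(pinned, c(30, 40))$mean_distance_cm, 0)
  # uniform positions in a square: mean distance to the center is
  # ~0.382598 * side (classic box integral, checked by quadrature)
  set.seed(6)
  u <- cbind(runif(2e5, 0, 100), runif(2e5, 0, 100))
  mgd <- mean_goal_distance(u, c(50, 50))
  expect_equal(mgd$mean_distance_cm, 0.382598 * 100, tolerance = 0.01)
  rot <- c(rep(0, 50), rep(20, 50))
  res <- mean_goal_distance(pinned, c(0, 0), rotation_deg_s = rot)
  expect_equal(res$retained_fraction, 0.5)
  expect_error(mean_goal_distance(pinned, c(0, 0),
                                  rotation_deg_s = rep(15, 100)),
               "excluded")
})

test_that("trial duration summaries are censoring-aware arithmetic", {
  logs <- data.frame(task = "jumper",
                     t_start_s = c(0, 2, 6), t_end_s = c(2, 6, 15),
                     outcome = c("reached", "reached", "timeout"))
  s <- trial_duration_summary(logs)
  expect_equal(s$mean_duration_s, mean(c(2, 4, 9)))
  expect_equal(s$reached_fraction, 2 / 3)
  expect_equal(s$n_censored, 1L)
  allto <- data.frame(task = "jumper", t_start_s = c(0, 62),
                      t_end_s = c(62, 124), outcome = "timeout")
  s2 <- trial_duration_summary(allto)
  expect_equal(s2$reached_fraction, 0)
  expect_equal(s2$mean_duration_s, 62)
})

test_that("goal shuffling with preserved paths behaves at the extremes", {
  arena <- arena_spec()
  # a path parked exactly on its goal: observed distance 0, minimal p
  paths <- list(cbind(rep(70, 200), rep(20, 200)))
  nd <- shuffle_goals_null(paths, goals = c(70, 20), arena = arena,
                           metric = "mean_distance", n_shuffles = 99,
                           min_dist_cm = 30, seed = 2)
  expect_equal(nd$observed, 0)
  expect_equal(nd$p_empirical, 1 / 100)
  # a space-covering path is not goal-directed: observed sits inside the null
  set.seed(3)
  cover <- cbind(runif(5000, 0, 100), runif(5000, 0, 100))
  nd2 <- shuffle_goals_null(list(cover), goals = c(65, 40), arena = arena,
                            metric = "mean_distance", n_shuffles = 199,
                            min_dist_cm = 0, seed = 4)
  qs <- quantile(nd2$shuffled_values, c(0.025, 0.975))
  expect_gt(nd2$observed, qs[1])
  expect_lt(nd2$observed, qs[2])
  expect_error(shuffle_goals_null(list(), goals = c(1, 1)), "nonempty")
})
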