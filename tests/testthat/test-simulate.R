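test_that("noiseless running moves straight at the goal with predictable duration", {
  arena <- arena_spec()
  ens <- make_ensemble(arena, 5, seed = 1)
  p <- run_params(speed_mean = 20, speed_sd = 0, heading_noise_sd = 0,
                  pause_range_s = c(0, 0))
  s <- simulate_running_session(arena, ens, n_trials = 3, params = p,
                                seed = 2, lfp = FALSE)
  for (i in seq_len(3)) {
    tr <- s$trials[i, ]
    sel <- s$trajectory$t_s >= tr$t_start_s & s$trajectory$t_s < tr$t_end_s
    xy <- cbind(s$trajectory$x_cm, s$trajectory$y_cm)[sel, , drop = FALSE]
    goal <- c(tr$goal_x_cm, tr$goal_y_cm)
    # displacement steps all point at the goal: path is a straight line
    if (nrow(xy) > 2) {
      d <- dist_to_segment <- abs(
        (goal[2] - xy[1, 2]) * (xy[, 1] - xy[1, 1]) -
          (goal[1] - xy[1, 1]) * (xy[, 2] - xy[1, 2])) /
        sqrt(sum((goal - xy[1, ])^2))
      expect_lt(max(d), 1e-6)
    }
    # duration: ticks to close (start distance - goal radius) at 2 cm/tick
    start <- if (i == 1) xy[1, ] - (xy[2, ] - xy[1, ]) else {
      prev <- max(which(s$trajectory$t_s < tr$t_start_s))
      c(s$trajectory$x_cm[prev], s$trajectory$y_cm[prev])
    }
    d0 <- sqrt(sum((start - goal)^2))
    expect_equal(tr$t_end_s - tr$t_start_s,
                 ceiling((d0 - arena$goal_radius_cm) / 2 - 1e-9) * 0.1,
                 tolerance = 0.11)
  }
})

test_that("trajectories stay inside the arena and use a constant 0.1-s grid", {
  fx <- tiny_fixture()
  tr <- fx$session$trajectory
  expect_true(all(tr$x_cm >= 0 & tr$x_cm <= fx$arena$side_cm))
  expect_true(all(tr$y_cm >= 0 & tr$y_cm <= fx$arena$side_cm))
  expect_equal(unique(round(diff(tr$t_s), 10)), 0.1)
  expect_true(all(tr$speed_cm_s >= 0))
  expect_true(all(is.finite(as.matrix(tr[, -1]))))
})

test_that("sessions are deterministic given seed and stall on zero speed", {
  arena <- arena_spec()
  ens <- make_ensemble(arena, 4, seed = 1)
  s1 <- simulate_running_session(arena, ens, n_trials = 2, seed = 5, lfp = FALSE)
  s2 <- simulate_running_session(arena, ens, n_trials = 2, seed = 5, lfp = FALSE)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$raster$counts, s2$raster$counts)
  expect_error(
    simulate_running_session(arena, ens, n_trials = 1,
                             params = run_params(speed_mean = 0, speed_sd = 0),
                             seed = 1, lfp = FALSE),
    "stall")
})

test_that("spiking is Poisson-calibrated against the tuning rates", {
  arena <- arena_spec()
  ens <- make_ensemble(arena, 20, seed = 3)
  # fixed position: per-bin counts must be Poisson with mean rate * bin_s
  xy <- matrix(rep(c(50, 50), each = 2000), ncol = 2)
  set.seed(9)
  r <- mapbmi:::poisson_raster(ens, xy)   # 2e4 base bins
  rates <- tuning_rate(ens, c(50, 50))[1, ]
  lam <- rates * 0.01
  m <- rowMeans(r$counts)
  v <- apply(r$counts, 1, var)
  z_mean <- (m - lam) / sqrt(lam / ncol(r$counts))
  expect_lt(max(abs(z_mean)), 4)
  ratio <- v / m
  expect_true(all(ratio > 0.9 & ratio < 1.1))
  # session totals match occupancy-weighted mean tuning within 3 SE
  fx <- tiny_fixture()
  s <- fx$session
  exp_counts <- colSums(tuning_rate(fx$ensemble,
                                    cbind(s$trajectory$x_cm,
                                          s$trajectory$y_cm))) * 0.1
  obs <- rowSums(s$raster$counts)
  z <- (obs - exp_counts) / sqrt(exp_counts)
  expect_true(all(abs(z) < 4))
})

test_that("synthetic LFP has the specified theta peaks", {
  n_ticks <- 600  # 60 s
  move <- simulate_lfp(rep(20, n_ticks), noise_amp = 0, seed = 1)
  pk_m <- psd_theta_peak(move, zscore_first = FALSE)
  expect_lt(abs(pk_m$peak_hz - 7.3), 0.1 + 1e-9)
  still <- simulate_lfp(rep(0, n_ticks), noise_amp = 0, seed = 1)
  pk_s <- psd_theta_peak(still, zscore_first = FALSE)
  expect_lt(abs(pk_s$peak_hz - 6.3), 0.1 + 1e-9)
  # zero theta amplitude: nothing stands out of the 1/f background
  flat <- simulate_lfp(rep(20, n_ticks), theta_amp = 0, noise_amp = 0.5,
                       seed = 2)
  pk_f <- psd_theta_peak(flat)
  expect_true(pk_f$low_prominence)
  expect_false(pk_m$low_prominence)
  expect_error(simulate_lfp(rep(1, 10), fs = 10), "Nyquist")
})
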