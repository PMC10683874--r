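#' Running-task movement parameters
#'
#' Parameters of the goal-directed movement model used to emulate the
#' Running task: per 100-ms tick the agent orients toward the goal cue with
#' first-order relaxation plus Gaussian heading noise, and advances at a
#' truncated-Gaussian treadmill speed. After each reached goal the agent
#' consumes reward while essentially immobile for a random pause, which also
#' supplies the immobility epochs used by the spectral and burst analyses.
#'
#' @param speed_mean,speed_sd Running speed distribution (cm/s); negative
#'   draws are truncated to 0.
#' @param heading_gain Fraction of the heading error corrected per tick.
#' @param heading_noise_sd Heading noise SD per tick (deg).
#' @param goal_min_dist_cm Minimum distance between the agent and a newly
#'   placed goal cue (cm).
#' @param pause_range_s Range of the post-reward immobile pause (s).
#' @param pause_speed_max Upper bound of treadmill jitter while paused (cm/s).
#' @param max_trial_s Step cap per trial; exceeding it raises a stall error.
#' @param reward_ml Reward volume per reached goal (mL).
#' @return A list of class `run_params`.
#' @export
run_params <- function(speed_mean = 15, speed_sd = 5, heading_gain = 0.5,
                       heading_noise_sd = 10, goal_min_dist_cm = 30,
                       pause_range_s = c(8, 16), pause_speed_max = 0.4,
                       max_trial_s = 120, reward_ml = 0.04) {
  if (speed_mean < 0 || speed_sd < 0) stop("speeds must be nonnegative")
  structure(list(speed_mean = speed_mean, speed_sd = speed_sd,
                 heading_gain = heading_gain,
                 heading_noise_sd = heading_noise_sd,
                 goal_min_dist_cm = goal_min_dist_cm,
                 pause_range_s = pause_range_s,
                 pause_speed_max = pause_speed_max,
                 max_trial_s = max_trial_s, reward_ml = reward_ml),
            class = "run_params")
}

# Draw a goal uniformly in the arena at least min_dist from `from`, inset
# so the whole goal region lies inside the walls.
draw_goal <- function(arena, from, min_dist, inset = arena$goal_radius_cm) {
  if (min_dist > 1.35 * arena$side_cm)
    stop("goal_min_dist_cm unsatisfiable in this arena")
  repeat {
    g <- stats::runif(2, inset, arena$side_cm - inset)
    if (sqrt(sum((g - from)^2)) >= min_dist) return(g)
  }
}

#' Simulate a Running-task session
#'
#' Generates goal-directed running behaviour in the arena, inhomogeneous
#' Poisson place-cell spiking at a 10-ms base bin driven by the ensemble
#' tuning at the current position, per-trial logs, and a phenomenological
#' LFP trace whose theta frequency tracks movement versus stillness.
#'
#' @param arena An [arena_spec()].
#' @param ensemble A [make_ensemble()] place-cell ensemble.
#' @param n_trials Number of goal-reaching trials (>= 1).
#' @param params A [run_params()] object.
#' @param seed Integer seed; the session is fully reproducible.
#' @param lfp Logical; set `FALSE` to skip LFP synthesis.
#' @return An object of class `running_session`: a list with `trajectory`
#'   (data frame on a 0.1-s grid: `t_s`, `x_cm`, `y_cm`, `heading_deg`,
#'   `speed_cm_s`, `rotation_deg_s`), `raster` (10-ms [spike_raster()]),
#'   `trials` (per-trial log), `lfp` (an `lfp_trace` or `NULL`), plus the
#'   generating `arena`, `ensemble`, `params` and `seed`.
#' @export
simulate_running_session <- function(arena, ensemble, n_trials = 120,
                                     params = run_params(), seed = 1L,
                                     lfp = TRUE) {
  stopifnot(inherits(arena, "arena_spec"), inherits(ensemble, "place_ensemble"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  dt <- 0.1
  with_seed(seed, {
    pos <- stats::runif(2, 0.25, 0.75) * arena$side_cm
    heading <- stats::runif(1, 0, 360)
    xs <- ys <- hs <- sp <- numeric(0)
    trials <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      goal <- draw_goal(arena, pos, params$goal_min_dist_cm)
      t_start <- length(xs) * dt
      heading <- atan2(goal[2] - pos[2], goal[1] - pos[1]) * 180 / pi
      steps <- 0L
      cap <- as.integer(ceiling(params$max_trial_s / dt))
      txs <- tys <- ths <- tsp <- numeric(cap)
      while (sqrt(sum((pos - goal)^2)) > arena$goal_radius_cm) {
        steps <- steps + 1L
        if (steps > cap)
          stop("stall: goal not reached within max_trial_s step cap")
        bearing <- atan2(goal[2] - pos[2], goal[1] - pos[1]) * 180 / pi
        heading <- heading + params$heading_gain * wrap_deg(bearing - heading) +
          if (params$heading_noise_sd > 0)
            stats::rnorm(1, 0, params$heading_noise_sd) else 0
        v <- max(0, params$speed_mean +
                   if (params$speed_sd > 0) stats::rnorm(1, 0, params$speed_sd) else 0)
        pos <- pmin(pmax(pos + v * dt *
                           c(cos(heading * pi / 180), sin(heading * pi / 180)),
                         0), arena$side_cm)
        txs[steps] <- pos[1]; tys[steps] <- pos[2]
        ths[steps] <- heading %% 360; tsp[steps] <- v
      }
      if (steps > 0L) {
        keep <- seq_len(steps)
        xs <- c(xs, txs[keep]); ys <- c(ys, tys[keep])
        hs <- c(hs, ths[keep]); sp <- c(sp, tsp[keep])
      }
      t_end <- length(xs) * dt
      trials[[tr]] <- data.frame(trial_id = tr, task = "running",
                                 goal_x_cm = goal[1], goal_y_cm = goal[2],
                                 t_start_s = t_start, t_end_s = t_end,
                                 outcome = "reached",
                                 reward_ml = params$reward_ml)
      # post-reward immobile pause (skipped after the final trial)
      if (tr < n_trials) {
        n_pause <- round(stats::runif(1, params$pause_range_s[1],
                                      params$pause_range_s[2]) / dt)
        if (n_pause > 0) {
          vpause <- stats::runif(n_pause, 0, params$pause_speed_max)
          xs <- c(xs, rep(pos[1], n_pause)); ys <- c(ys, rep(pos[2], n_pause))
          hs <- c(hs, (hs[length(hs)] +
                         cumsum(stats::rnorm(n_pause, 0, 2))) %% 360)
          sp <- c(sp, vpause)
        }
      }
    }
    n_ticks <- length(xs)
    t_s <- seq_len(n_ticks) * dt - dt
    rot <- c(0, wrap_deg(diff(hs))) / dt
    trajectory <- data.frame(t_s = t_s, x_cm = xs, y_cm = ys,
                             heading_deg = hs, speed_cm_s = sp,
                             rotation_deg_s = rot)
    raster <- poisson_raster(ensemble, cbind(xs, ys), dt = dt, base_bin_s = 0.01)
    lfp_trace <- if (lfp) simulate_lfp(sp) else NULL
    structure(list(trajectory = trajectory, raster = raster,
                   trials = do.call(rbind, trials), lfp = lfp_trace,
                   arena = arena, ensemble = ensemble, params = params,
                   seed = as.integer(seed)),
              class = "running_session")
  })
}

#' @export
print.running_session <- function(x, ...) {
  cat(sprintf("<running_session> %d trials, %.1f min, %d units, %d spikes\n",
              nrow(x$trials), raster_duration(x$raster) / 60,
              nrow(x$raster$counts), sum(x$raster$counts)))
  invisible(x)
}

# Inhomogeneous-Poisson spike raster from tuning rates along a trajectory
# sampled every `dt`; rates held constant within each dt tick and emitted at
# the finer base bin. Chunked over time to bound peak memory.
poisson_raster <- function(ensemble, xy, dt = 0.1, base_bin_s = 0.01) {
  n_ticks <- nrow(xy)
  rep_f <- as.integer(round(dt / base_bin_s))
  n_units <- ensemble$n_units
  counts <- matrix(0L, nrow = n_units, ncol = n_ticks * rep_f)
  chunk <- 20000L
  for (s in seq(1L, n_ticks, by = chunk)) {
    e <- min(n_ticks, s + chunk - 1L)
    rates <- tuning_rate(ensemble, xy[s:e, , drop = FALSE])  # ticks x units
    lam <- rates[rep(seq_len(e - s + 1L), each = rep_f), , drop = FALSE] *
      base_bin_s
    cc <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
    counts[, ((s - 1L) * rep_f + 1L):(e * rep_f)] <- t(cc)
  }
  spike_raster(counts, bin_s = base_bin_s, unit_ids = ensemble$unit_ids)
}

#' Synthesize a theta-modulated LFP trace
#'
#' Phenomenological LFP: a sinusoid whose instantaneous frequency is
#' `theta_move_hz` whenever treadmill speed exceeds `speed_thresh_cm_s` and
#' `theta_still_hz` otherwise, amplitude-modulated so that still-period
#' theta is intermittent, plus 1/f background noise. No spike-LFP coupling
#' is modelled; the trace supports the spectral analyses only.
#'
#' @param speed_cm_s Treadmill speed on a 0.1-s grid (cm/s).
#' @param theta_move_hz,theta_still_hz Theta frequency during movement and
#'   stillness (Hz).
#' @param band Analysis band (Hz); must satisfy the Nyquist limit.
#' @param fs Sampling rate (Hz).
#' @param speed_thresh_cm_s Movement threshold (cm/s).
#' @param theta_amp Theta amplitude (a.u.).
#' @param still_amp Relative theta amplitude during still epochs.
#' @param still_duty Fraction of still time with theta present.
#' @param noise_amp SD of the 1/f background (a.u.).
#' @param seed Integer seed.
#' @return An object of class `lfp_trace` with fields `values`, `fs`,
#'   `zscored`.
#' @export
simulate_lfp <- function(speed_cm_s, theta_move_hz = 7.3, theta_still_hz = 6.3,
                         band = c(5, 12), fs = 1000, speed_thresh_cm_s = 5,
                         theta_amp = 1, still_amp = 0.8, still_duty = 0.65,
                         noise_amp = 0.5, seed = 1L) {
  if (max(band) >= fs / 2 || max(theta_move_hz, theta_still_hz) >= fs / 2)
    stop("sampling rate too low for requested band (Nyquist)")
  rep_f <- as.integer(round(0.1 * fs))
  n <- length(speed_cm_s) * rep_f
  with_seed(seed, {
    moving <- rep(speed_cm_s > speed_thresh_cm_s, each = rep_f)
    freq <- ifelse(moving, theta_move_hz, theta_still_hz)
    phase <- 2 * pi * cumsum(freq) / fs
    # intermittent theta while still: 1-s on/off gate, lightly smoothed
    gate_raw <- stats::runif(ceiling(n / fs) + 1) < still_duty
    gate <- rep(gate_raw, each = fs)[seq_len(n)]
    gate <- stats::filter(gate, rep(1 / (fs / 5), fs / 5), sides = 2)
    gate[is.na(gate)] <- gate_raw[1]
    amp <- ifelse(moving, 1, still_amp * as.numeric(gate))
    signal <- theta_amp * amp * sin(phase)
    if (noise_amp > 0) {
      wh <- stats::rnorm(n)
      f_ax <- c(1, seq_len(n - 1))
      f_ax <- pmin(f_ax, n - f_ax + 1)          # symmetric frequency index
      shaped <- Re(stats::fft(stats::fft(wh) / sqrt(f_ax), inverse = TRUE)) / n
      signal <- signal + noise_amp * shaped / stats::sd(shaped)
    }
    structure(list(values = signal, fs = fs, zscored = FALSE),
              class = "lfp_trace")
  })
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %.1f s @ %g Hz%s\n", length(x$values) / x$fs, x$fs,
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' Write / read an LFP trace as CSV
#'
#' Plain-text serialization with a header comment carrying `fs` and the
#' z-scored flag, then one sample value per line.
#'
#' @param lfp An `lfp_trace`.
#' @param path File path.
#' @return `write_lfp_csv` returns `path` invisibly; `read_lfp_csv` an
#'   `lfp_trace`.
#' @export
write_lfp_csv <- function(lfp, path) {
  stopifnot(inherits(lfp, "lfp_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g zscored=%d", lfp$fs, as.integer(lfp$zscored)),
             con)
  writeLines("value", con)
  writeLines(sprintf("%.17g", lfp$values), con)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  fs <- as.numeric(sub(".*fs=([^ ]+).*", "\\1", hdr))
  zs <- sub(".*zscored=([01]).*", "\\1", hdr) == "1"
  v <- utils::read.csv(path, skip = 1L)$value
  structure(list(values = v, fs = fs, zscored = zs), class = "lfp_trace")
}

#' Write a trajectory or trial log to CSV
#'
#' Plain-text writers with the documented headers (`t_s`, `x_cm`, `y_cm`,
#' `heading_deg`, `speed_cm_s`, `rotation_deg_s`; `trial_id`, `goal_x_cm`,
#' `goal_y_cm`, `t_start_s`, `t_end_s`, `outcome`, `reward_ml`).
#'
#' @param x A trajectory or trial-log data frame.
#' @param path Output file path.
#' @export
write_session_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
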