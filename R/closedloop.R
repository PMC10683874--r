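#' Jumper (BMI navigation) task configuration
#'
#' @param smoothing_s Causal sliding-mean window applied to the decoded
#'   stream (s); default 3.
#' @param timeout_s Trial limit (s); default 62.
#' @param goal_radius_cm Goal region radius (cm); `NULL` takes the arena's.
#' @param movement_rule `"teleport_to_smoothed"` (avatar set to the smoothed
#'   decoded location each tick) or `"rate_limited"` (step of at most
#'   `max_step_cm_per_tick` toward it).
#' @param max_step_cm_per_tick Step cap under the rate-limited rule (cm).
#' @param min_goal_dist_cm Minimum distance of a new goal from the avatar.
#' @param n_trials Number of trials.
#' @return A list of class `jumper_config`.
#' @export
jumper_config <- function(smoothing_s = 3, timeout_s = 62,
                          goal_radius_cm = NULL,
                          movement_rule = c("teleport_to_smoothed",
                                            "rate_limited"),
                          max_step_cm_per_tick = 4,
                          min_goal_dist_cm = 30, n_trials = 20) {
  movement_rule <- match.arg(movement_rule)
  if (timeout_s <= 0) stop("timeout_s must be > 0")
  if (smoothing_s < 0.1) stop("smoothing_s must be at least one tick")
  structure(list(smoothing_s = smoothing_s, timeout_s = timeout_s,
                 goal_radius_cm = goal_radius_cm,
                 movement_rule = movement_rule,
                 max_step_cm_per_tick = max_step_cm_per_tick,
                 min_goal_dist_cm = min_goal_dist_cm,
                 n_trials = as.integer(n_trials)),
            class = "jumper_config")
}

#' Jedi (BMI object location control) task configuration
#'
#' @param smoothing_s Causal sliding-mean window (s); default 2.
#' @param trial_limit_s Trial limit (s); default 180 (3 min).
#' @param reward_cap_ml Reward cap ending the trial (mL); default 0.5.
#' @param reward_rate_ml_s Reward flow while the object touches the goal
#'   (mL/s).
#' @param goal_radius_cm Goal region radius (cm); `NULL` takes the arena's.
#' @param min_goal_jump_cm Minimum distance of each new goal from the
#'   previous one ("distant random location").
#' @param n_trials Number of trials.
#' @return A list of class `jedi_config`.
#' @export
jedi_config <- function(smoothing_s = 2, trial_limit_s = 180,
                        reward_cap_ml = 0.5, reward_rate_ml_s = 0.01,
                        goal_radius_cm = NULL, min_goal_jump_cm = 40,
                        n_trials = 8) {
  if (trial_limit_s <= 0 || reward_rate_ml_s <= 0 || reward_cap_ml <= 0)
    stop("invalid Jedi config")
  structure(list(smoothing_s = smoothing_s, trial_limit_s = trial_limit_s,
                 reward_cap_ml = reward_cap_ml,
                 reward_rate_ml_s = reward_rate_ml_s,
                 goal_radius_cm = goal_radius_cm,
                 min_goal_jump_cm = min_goal_jump_cm,
                 n_trials = as.integer(n_trials)),
            class = "jedi_config")
}

#' Causal sliding-mean smoothing of a decoded position stream
#'
#' Trailing moving average over the most recent `min(elapsed, smoothing_s)`
#' samples on the 0.1-s grid; defined from the first sample onward (the
#' window expands until it reaches full length).
#'
#' @param xy n x 2 matrix (or data frame) of positions on the 0.1-s grid.
#' @param smoothing_s Window length (s).
#' @param dt Sample interval (s).
#' @return n x 2 matrix of smoothed positions; empty input gives an empty
#'   matrix.
#' @export
smooth_positions <- function(xy, smoothing_s, dt = 0.1) {
  xy <- as.matrix(xy)
  if (!nrow(xy)) return(xy)
  k <- max(1L, as.integer(round(smoothing_s / dt)))
  cs <- apply(xy, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(xy))
  n <- nrow(xy)
  denom <- pmin(seq_len(n), k)
  out <- cs
  if (n > k) out[(k + 1):n, ] <- cs[(k + 1):n, , drop = FALSE] -
    cs[1:(n - k), , drop = FALSE]
  out / denom
}

# Incremental closed-loop engine shared by Jumper and Jedi.
# Per 0.1-s tick: the intention agent picks an intended location, emits
# 10-ms Poisson spikes from the rPV blend, the decoder consumes the
# trailing window of emitted spikes only (strict causality), the decoded
# point is smoothed, and the task rule updates avatar/object, reward and
# trial state.
closed_loop_engine <- function(rpv_map, model, agent_cfg, arena, task,
                               cfg, seed) {
  stopifnot(inherits(model, "place_decoder"),
            inherits(rpv_map, "place_field_map"),
            inherits(agent_cfg, "intention_config"))
  if (!identical(model$unit_ids, rpv_map$unit_ids))
    stop("agent (rPV map) and model unit sets differ")
  dt <- 0.1
  goal_radius <- if (is.null(cfg$goal_radius_cm)) arena$goal_radius_cm else
    cfg$goal_radius_cm
  dcfg <- model$config
  wb <- as.integer(round(dcfg$window_s / dt))
  n_u <- length(model$unit_ids)
  base_per_tick <- as.integer(round(dt / 0.01))
  sm_k <- max(1L, as.integer(round(cfg$smoothing_s / dt)))
  max_ticks <- cfg$n_trials * as.integer(ceiling(
    (if (task == "jumper") cfg$timeout_s else cfg$trial_limit_s) / dt)) + wb
  counts10 <- matrix(0L, n_u, max_ticks * base_per_tick)  # 10-ms base raster
  tick_counts <- matrix(0, n_u, max_ticks)                # per-tick totals
  decoded <- smoothed <- avatar_m <- intended_m <- matrix(NA_real_, max_ticks, 2)
  speed <- rot <- numeric(max_ticks)
  center <- rep(arena$side_cm / 2, 2)
  with_seed(seed, {
    start_pos <- if (task == "jedi") center else
      stats::runif(2, 0.25, 0.75) * arena$side_cm
    avatar <- start_pos
    goal <- if (task == "jumper")
      draw_goal(arena, avatar, cfg$min_goal_dist_cm) else
        draw_goal(arena, center, cfg$min_goal_jump_cm)
    walker <- center   # random_walk policy starts goal-blind at the center
    heading <- stats::runif(1, 0, 360)
    trials <- list()
    tick <- 0L
    trial_id <- 1L
    trial_start_tick <- wb        # first trial starts after the warm-up
    reward <- 0
    sm_sum <- c(0, 0)             # running smoothing-window sum
    finished <- FALSE
    while (!finished) {
      tick <- tick + 1L
      if (tick > max_ticks) break
      # 1. intended location
      intended <- switch(agent_cfg$policy,
        toward_goal = goal,
        hold_goal = goal,
        random_walk = {
          walker <- pmin(pmax(walker + stats::rnorm(2, 0,
                                                    agent_cfg$walk_step_cm),
                              0), arena$side_cm)
          walker
        })
      # 2. emission (10-ms Poisson at the blended rate)
      rates <- intention_rates(rpv_map, intended, agent_cfg, warn = FALSE)
      cc <- matrix(stats::rpois(n_u * base_per_tick, rates * 0.01), nrow = n_u)
      counts10[, ((tick - 1L) * base_per_tick + 1L):(tick * base_per_tick)] <- cc
      new_counts <- rowSums(cc)
      tick_counts[, tick] <- new_counts
      # 3. decode the trailing window (only spikes with t <= now exist)
      dec <- predict_features(model, tick_features(tick_counts, tick, dcfg))
      decoded[tick, ] <- dec
      # 4. causal smoothing
      sm_sum <- sm_sum + dec
      if (tick > sm_k) sm_sum <- sm_sum - decoded[tick - sm_k, ]
      sm <- sm_sum / min(tick, sm_k)
      smoothed[tick, ] <- sm
      # body kinematics: heading relaxes toward the goal bearing
      bearing <- atan2(goal[2] - avatar[2], goal[1] - avatar[1]) * 180 / pi
      d_head <- 0.2 * wrap_deg(bearing - heading) + stats::rnorm(1, 0, 1.5)
      heading <- (heading + d_head) %% 360
      rot[tick] <- d_head / dt
      speed[tick] <- if (task == "jedi") stats::runif(1, 0, 0.4) else
        stats::runif(1, 0, 0.4)
      intended_m[tick, ] <- intended
      # 5. avatar / object update
      if (task == "jumper") {
        avatar <- if (cfg$movement_rule == "teleport_to_smoothed") sm else {
          step <- sm - avatar
          d <- sqrt(sum(step^2))
          if (d > cfg$max_step_cm_per_tick)
            avatar + step / d * cfg$max_step_cm_per_tick else sm
        }
      } else avatar <- sm          # Jedi object tracks the smoothed decode
      avatar_m[tick, ] <- avatar
      # 6. trial logic (active only after warm-up)
      if (tick <= wb) next
      t_in_trial <- (tick - trial_start_tick) * dt
      ended <- NULL
      if (task == "jumper") {
        if (sqrt(sum((avatar - goal)^2)) <= goal_radius) ended <- "reached"
        else if (t_in_trial >= cfg$timeout_s) ended <- "timeout"
      } else {
        if (sqrt(sum((avatar - goal)^2)) <= goal_radius)
          reward <- reward + cfg$reward_rate_ml_s * dt
        if (reward >= cfg$reward_cap_ml - 1e-12) ended <- "reward_cap"
        else if (t_in_trial >= cfg$trial_limit_s) ended <- "limit"
      }
      if (!is.null(ended)) {
        trials[[trial_id]] <- data.frame(
          trial_id = trial_id, task = task, goal_x_cm = goal[1],
          goal_y_cm = goal[2], t_start_s = (trial_start_tick) * dt,
          t_end_s = tick * dt, outcome = ended,
          reward_ml = if (task == "jedi") reward else
            if (ended == "reached") 0.04 else 0)
        trial_id <- trial_id + 1L
        if (trial_id > cfg$n_trials) { finished <- TRUE; next }
        goal <- if (task == "jumper")
          draw_goal(arena, avatar, cfg$min_goal_dist_cm) else
            draw_goal(arena, goal, cfg$min_goal_jump_cm)
        trial_start_tick <- tick
        reward <- 0
      }
    }
    used <- seq_len(tick)
    raster <- spike_raster(counts10[, seq_len(tick * base_per_tick),
                                    drop = FALSE],
                           bin_s = 0.01, unit_ids = model$unit_ids)
    streams <- data.frame(
      t_s = used * dt, decoded_x = decoded[used, 1], decoded_y = decoded[used, 2],
      smoothed_x = smoothed[used, 1], smoothed_y = smoothed[used, 2],
      avatar_x = avatar_m[used, 1], avatar_y = avatar_m[used, 2],
      intended_x = intended_m[used, 1], intended_y = intended_m[used, 2],
      speed_cm_s = speed[used], rotation_deg_s = rot[used])
    structure(list(task = task, trials = do.call(rbind, trials),
                   streams = streams, raster = raster, config = cfg,
                   agent = agent_cfg, arena = arena,
                   goal_radius_cm = goal_radius, warmup_s = wb * dt,
                   seed = as.integer(seed)),
              class = "bmi_session")
  })
}

#' Run a closed-loop Jumper (BMI navigation) session
#'
#' Couples the intention agent, the trained decoder, causal 3-s smoothing
#' and the avatar movement rule in a discrete 0.1-s loop. Each trial ends
#' when the avatar enters the goal region ("reached") or at the 62-s
#' timeout; a new goal is then placed uniformly at random subject to the
#' minimum-distance constraint. The loop starts with one decoder window of
#' warm-up emission before the first trial so the decoder always sees a
#' full window.
#'
#' @param rpv_map A [compute_rpv_map()] object (the agent's map).
#' @param model A [train_decoder()] model sharing the map's unit set.
#' @param agent_cfg An [intention_config()].
#' @param cfg A [jumper_config()].
#' @param arena An [arena_spec()].
#' @param seed Integer seed.
#' @return A `bmi_session` object: `trials` (per-trial log), `streams`
#'   (per-tick decoded/smoothed/avatar/intended positions, treadmill speed
#'   and body rotation rate), `raster` (emitted 10-ms spikes), configs.
#' @export
run_jumper_session <- function(rpv_map, model, agent_cfg = intention_config(),
                               cfg = jumper_config(), arena = NULL,
                               seed = 1L) {
  if (is.null(arena)) arena <- rpv_map$arena
  closed_loop_engine(rpv_map, model, agent_cfg, arena, "jumper", cfg, seed)
}

#' Run a closed-loop Jedi (BMI object location control) session
#'
#' The agent is positionally fixed at the arena center (free to turn; body
#' rotation is simulated so the >12 deg/s exclusion rule has data to act
#' on) and holds the goal's representation; the controlled object tracks
#' the 2-s-smoothed decoded location. Reward accrues at `reward_rate_ml_s`
#' whenever the object is inside the goal region; a trial ends at the
#' reward cap or the 3-min limit, after which the goal jumps at least
#' `min_goal_jump_cm` away.
#'
#' @inheritParams run_jumper_session
#' @param cfg A [jedi_config()].
#' @return A `bmi_session` object (see [run_jumper_session()]).
#' @export
run_jedi_session <- function(rpv_map, model, agent_cfg = NULL,
                             cfg = jedi_config(), arena = NULL, seed = 1L) {
  if (is.null(agent_cfg)) agent_cfg <- intention_config(policy = "hold_goal")
  if (is.null(arena)) arena <- rpv_map$arena
  closed_loop_engine(rpv_map, model, agent_cfg, arena, "jedi", cfg, seed)
}

#' @export
print.bmi_session <- function(x, ...) {
  cat(sprintf("<bmi_session:%s> %d trials, %.1f s, outcomes: %s\n",
              x$task, nrow(x$trials),
              max(x$streams$t_s),
              paste(sprintf("%s=%d", names(table(x$trials$outcome)),
                            table(x$trials$outcome)), collapse = ", ")))
  invisible(x)
}

#' Replay Jumper kinematics offline over a decoded stream
#'
#' Given a decoded position stream and the original goal sequence,
#' reproduces the Jumper avatar rule (smoothing plus goal-reach test) to
#' determine how long each goal would have taken to reach; used by the
#' unit-identity shuffle null. Trials are censored at the timeout, and
#' goals not attempted before the stream ends count as censored.
#'
#' @param decoded Data frame with `x_cm`, `y_cm` on the 0.1-s grid.
#' @param goals Matrix/data frame of goal positions (one row per trial).
#' @param cfg A [jumper_config()].
#' @param goal_radius_cm Goal radius (cm).
#' @param skip_s Initial stream segment to skip (warm-up, s).
#' @return Data frame with per-goal `duration_s` and `reached`.
#' @export
replay_jumper <- function(decoded, goals, cfg = jumper_config(),
                          goal_radius_cm = 10, skip_s = 0) {
  goals <- as_xy_matrix(goals)
  dt <- 0.1
  sm <- smooth_positions(cbind(decoded$x_cm, decoded$y_cm), cfg$smoothing_s)
  n <- nrow(sm)
  i <- as.integer(round(skip_s / dt)) + 1L
  timeout_ticks <- as.integer(round(cfg$timeout_s / dt))
  out <- data.frame(duration_s = rep(cfg$timeout_s, nrow(goals)),
                    reached = rep(FALSE, nrow(goals)))
  for (g in seq_len(nrow(goals))) {
    if (i > n) break
    j_max <- min(n, i + timeout_ticks - 1L)
    d <- dist_xy(sm[i:j_max, , drop = FALSE], goals[g, ])
    hit <- which(d <= goal_radius_cm)
    if (length(hit)) {
      out$duration_s[g] <- hit[1] * dt
      out$reached[g] <- TRUE
      i <- i + hit[1]
    } else i <- j_max + 1L
  }
  out
}
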