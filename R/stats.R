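#' Shuffle-null distribution container
#'
#' Holds an observed statistic against its shuffle distribution. The
#' empirical p-value uses the add-one rule,
#' `p = (1 + #{shuffled at-or-beyond observed}) / (1 + n_shuffles)`, so it
#' is never 0; because the shuffle distributions behind the very small
#' p-values reported for this class of experiment are far from the observed
#' statistic, a normal-approximation p-value (from the shuffle mean and SD)
#' is reported alongside, labelled as such.
#'
#' @param statistic_name Name of the statistic.
#' @param observed Observed scalar.
#' @param shuffled Vector of per-shuffle statistics.
#' @param tail `"less"` if small observed values are extreme, `"greater"`
#'   otherwise.
#' @param seed Seed used to generate the shuffles (metadata).
#' @return An object of class `null_distribution`.
#' @export
null_distribution <- function(statistic_name, observed, shuffled,
                              tail = c("less", "greater"), seed = NA_integer_) {
  tail <- match.arg(tail)
  n <- length(shuffled)
  if (n < 1) stop("need at least one shuffle")
  k <- if (tail == "less") sum(shuffled <= observed) else
    sum(shuffled >= observed)
  mu <- mean(shuffled); sdv <- stats::sd(shuffled)
  p_norm <- if (is.finite(sdv) && sdv > 0) {
    if (tail == "less") stats::pnorm(observed, mu, sdv)
    else stats::pnorm(observed, mu, sdv, lower.tail = FALSE)
  } else NA_real_
  structure(list(statistic_name = statistic_name, observed = observed,
                 shuffled_values = shuffled, n_shuffles = n, tail = tail,
                 p_empirical = (1 + k) / (1 + n), p_normal = p_norm,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %s\n  observed %.4g vs null %.4g +/- %.4g (n=%d, tail=%s)\n  p_empirical = %.4g (add-one), p_normal = %.3g\n",
    x$statistic_name, x$observed, mean(x$shuffled_values),
    stats::sd(x$shuffled_values), x$n_shuffles, x$tail, x$p_empirical,
    x$p_normal))
  invisible(x)
}

#' Unit-identity shuffle null for Jumper trial durations
#'
#' Tests the spatial specificity of closed-loop navigation: for each
#' shuffle, whole spike trains are randomly reassigned across unit
#' identities, the shuffled raster is run through the original decoder, the
#' Jumper kinematics are replayed offline over the re-decoded stream
#' against the original goal sequence, and the mean time-to-goal (censored
#' at the timeout) is recorded. The observed statistic is the session's
#' actual mean trial duration; the p-value is one-sided for observed less
#' than the null.
#'
#' @param session A Jumper `bmi_session` from [run_jumper_session()].
#' @param model The [train_decoder()] model used in the session.
#' @param n_shuffles Number of unit-identity shuffles (>= 1).
#' @param seed Integer seed.
#' @return A [null_distribution()].
#' @export
unit_shuffle_duration_null <- function(session, model, n_shuffles = 200,
                                       seed = 1L) {
  stopifnot(inherits(session, "bmi_session"))
  if (session$task != "jumper") stop("expected a Jumper session")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  goals <- cbind(session$trials$goal_x_cm, session$trials$goal_y_cm)
  observed <- mean(session$trials$t_end_s - session$trials$t_start_s)
  shuffled <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      sh <- shuffle_unit_identities(session$raster,
                                    perm = sample.int(nrow(session$raster$counts)))
      dec <- decode_stream(model, sh)
      rep_k <- replay_jumper(dec, goals, session$config,
                             goal_radius_cm = session$goal_radius_cm)
      mean(rep_k$duration_s)
    }, numeric(1))
  })
  null_distribution("mean Jumper trial duration (unit-identity shuffle)",
                    observed, shuffled, tail = "less", seed = as.integer(seed))
}

# Per-trial position paths from a bmi_session's streams.
trial_paths <- function(session, which = c("avatar", "decoded", "smoothed")) {
  which <- match.arg(which)
  cols <- switch(which, avatar = c("avatar_x", "avatar_y"),
                 decoded = c("decoded_x", "decoded_y"),
                 smoothed = c("smoothed_x", "smoothed_y"))
  lapply(seq_len(nrow(session$trials)), function(i) {
    sel <- session$streams$t_s > session$trials$t_start_s[i] &
      session$streams$t_s <= session$trials$t_end_s[i]
    as.matrix(session$streams[sel, cols])
  })
}

#' Goal-location shuffle null preserving the BMI trajectories
#'
#' Redraws a random goal per trial (respecting the task's goal-placement
#' constraints) while keeping the original per-trial position paths, and
#' recomputes the performance metric: `"time_to_reach"` (first entry of the
#' path into the goal region, censored at the trial length; Jumper) or
#' `"mean_distance"` (time-average distance from the path to the goal;
#' Jedi). The observed statistic uses the true goals; p is one-sided for
#' observed less than the null.
#'
#' @param paths List of per-trial n_i x 2 position paths (cm), or a
#'   `bmi_session` (paths are extracted: avatar path for Jumper trials with
#'   `time_to_reach`, decoded path for `mean_distance`).
#' @param goals Matrix of true goals (one row per trial); taken from the
#'   session when `paths` is a `bmi_session`.
#' @param arena An [arena_spec()].
#' @param metric `"time_to_reach"` or `"mean_distance"`.
#' @param n_shuffles Number of goal redraws.
#' @param goal_radius_cm Goal radius (cm) for `time_to_reach`.
#' @param min_dist_cm Minimum distance of a redrawn goal from the trial's
#'   reference point (path start for `time_to_reach`, previous goal for
#'   `mean_distance`), mirroring task goal placement.
#' @param seed Integer seed.
#' @return A [null_distribution()].
#' @export
shuffle_goals_null <- function(paths, goals = NULL, arena = arena_spec(),
                               metric = c("time_to_reach", "mean_distance"),
                               n_shuffles = 200, goal_radius_cm = 10,
                               min_dist_cm = 30, seed = 1L) {
  metric <- match.arg(metric)
  if (inherits(paths, "bmi_session")) {
    session <- paths
    goals <- cbind(session$trials$goal_x_cm, session$trials$goal_y_cm)
    arena <- session$arena
    goal_radius_cm <- session$goal_radius_cm
    if (metric == "time_to_reach") {
      # Preserve the continuous BMI trajectory and replay it against random
      # goal sequences: each replayed trial starts where the previous one
      # ended and is censored at the task timeout.
      return(goal_replay_null(session, n_shuffles, seed))
    }
    paths <- trial_paths(session, "decoded")
    min_dist_cm <- session$config$min_goal_jump_cm
  }
  if (!length(paths)) stop("paths must be nonempty")
  goals <- as_xy_matrix(goals)
  dt <- 0.1
  eval_metric <- function(goal_set) {
    vals <- vapply(seq_along(paths), function(i) {
      p <- paths[[i]]
      if (!nrow(p)) return(NA_real_)
      d <- dist_xy(p, goal_set[i, ])
      if (metric == "time_to_reach") {
        hit <- which(d <= goal_radius_cm)
        if (length(hit)) hit[1] * dt else nrow(p) * dt
      } else mean(d)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  observed <- eval_metric(goals)
  shuffled <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      gs <- goals
      prev <- NULL
      for (i in seq_along(paths)) {
        ref <- if (metric == "time_to_reach") {
          if (nrow(paths[[i]])) paths[[i]][1, ] else c(arena$side_cm / 2,
                                                       arena$side_cm / 2)
        } else if (is.null(prev)) rep(arena$side_cm / 2, 2) else prev
        gs[i, ] <- draw_goal(arena, ref, min_dist_cm)
        prev <- gs[i, ]
      }
      eval_metric(gs)
    }, numeric(1))
  })
  null_distribution(sprintf("%s (goal shuffle)", metric), observed, shuffled,
                    tail = "less", seed = as.integer(seed))
}

# Goal-shuffle null for Jumper sessions over the preserved continuous
# avatar trajectory: per shuffle, a fresh random goal sequence (respecting
# the task's minimum-distance placement rule) is replayed along the
# original stream; per-goal time-to-reach is censored at the timeout.
goal_replay_null <- function(session, n_shuffles, seed) {
  dt <- 0.1
  keep <- session$streams$t_s > session$warmup_s
  stream <- cbind(session$streams$avatar_x,
                  session$streams$avatar_y)[keep, , drop = FALSE]
  n <- nrow(stream)
  n_trials <- nrow(session$trials)
  timeout_ticks <- as.integer(round(session$config$timeout_s / dt))
  observed <- mean(session$trials$t_end_s - session$trials$t_start_s)
  one_replay <- function() {
    i <- 1L
    durs <- rep(session$config$timeout_s, n_trials)
    for (g in seq_len(n_trials)) {
      if (i > n) break
      goal <- draw_goal(session$arena, stream[i, ],
                        session$config$min_goal_dist_cm)
      j_max <- min(n, i + timeout_ticks - 1L)
      d <- dist_xy(stream[i:j_max, , drop = FALSE], goal)
      hit <- which(d <= session$goal_radius_cm)
      if (length(hit)) {
        durs[g] <- hit[1] * dt
        i <- i + hit[1]
      } else i <- j_max + 1L
    }
    mean(durs)
  }
  shuffled <- with_seed(seed, vapply(seq_len(n_shuffles),
                                     function(k) one_replay(), numeric(1)))
  null_distribution("mean time to reach (goal shuffle, replayed trajectory)",
                    observed, shuffled, tail = "less",
                    seed = as.integer(seed))
}

#' Angle-to-goal distribution of a movement path
#'
#' For every step with displacement at least `min_step_cm`, computes the
#' signed angle between the instantaneous movement bearing and the bearing
#' from the current position to the goal, wrapped to (-180, 180], and pools
#' the angles into a probability histogram with `bin_deg`-wide bins. Also
#' reports the circular mean, the resultant length, and the mode bin
#' center. Movement straight at the goal gives angles near 0.
#'
#' @param paths A single n x 2 path (cm) or a list of per-trial paths.
#' @param goals A single goal (length-2) or one row per trial.
#' @param bin_deg Histogram bin width (deg); must divide 360.
#' @param min_step_cm Minimum per-step displacement (cm) for a step to
#'   count.
#' @return An object of class `angle_histogram`: `breaks_deg`, `counts`,
#'   `prob`, `circular_mean_deg`, `resultant_length`, `mode_deg`,
#'   `n_steps`. Empty (with a warning) if no step passes the filter.
#' @export
angle_to_goal_histogram <- function(paths, goals, bin_deg = 15,
                                    min_step_cm = 0.5) {
  if (360 %% bin_deg != 0) stop("bin_deg must divide 360")
  if (!is.list(paths)) paths <- list(as_xy_matrix(paths))
  goals <- as_xy_matrix(goals)
  if (nrow(goals) == 1L && length(paths) > 1L)
    goals <- goals[rep(1L, length(paths)), , drop = FALSE]
  angles <- numeric(0)
  for (i in seq_along(paths)) {
    p <- as_xy_matrix(paths[[i]])
    if (nrow(p) < 2) next
    dp <- diff(p)
    step <- sqrt(rowSums(dp^2))
    ok <- step >= min_step_cm
    if (!any(ok)) next
    move_bear <- atan2(dp[ok, 2], dp[ok, 1]) * 180 / pi
    to_goal <- goals[i, ]
    gb <- atan2(to_goal[2] - p[which(ok), 2],
                to_goal[1] - p[which(ok), 1]) * 180 / pi
    angles <- c(angles, wrap_deg(move_bear - gb))
  }
  breaks <- seq(-180, 180, by = bin_deg)
  if (!length(angles)) {
    warning("no steps above min_step_cm; empty histogram")
    counts <- rep(0L, length(breaks) - 1L)
    return(structure(list(breaks_deg = breaks, counts = counts,
                          prob = counts, circular_mean_deg = NA_real_,
                          resultant_length = NA_real_, mode_deg = NA_real_,
                          n_steps = 0L),
                     class = "angle_histogram"))
  }
  counts <- as.integer(table(cut(angles, breaks, include.lowest = TRUE)))
  rad <- angles * pi / 180
  cm <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  rl <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  centers <- breaks[-length(breaks)] + bin_deg / 2
  structure(list(breaks_deg = breaks, counts = counts,
                 prob = counts / sum(counts), circular_mean_deg = cm,
                 resultant_length = rl,
                 mode_deg = centers[which.max(counts)],
                 n_steps = length(angles)),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf(
    "<angle_histogram> %d steps; circular mean %.1f deg, resultant %.3f, mode %.0f deg\n",
    x$n_steps, x$circular_mean_deg, x$resultant_length, x$mode_deg))
  invisible(x)
}

#' @export
plot.angle_histogram <- function(x, ...) {
  centers <- x$breaks_deg[-length(x$breaks_deg)] + diff(x$breaks_deg) / 2
  graphics::plot(centers, x$prob, type = "h", lwd = 4,
                 xlab = "angle to goal (deg)", ylab = "probability", ...)
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(x)
}

#' Mean decoded distance to goal with rotation exclusion
#'
#' Time-average of the Euclidean distance between decoded locations and the
#' goal, excluding samples during which the body rotation rate exceeded
#' `exclude_above_deg_s` (in absolute value).
#'
#' @param decoded n x 2 decoded positions (cm) on the 0.1-s grid.
#' @param goal Goal position (cm).
#' @param rotation_deg_s Optional aligned body rotation rate (deg/s).
#' @param exclude_above_deg_s Exclusion threshold (deg/s); default 12.
#' @return List with `mean_distance_cm` and `retained_fraction`; an error
#'   if every sample is excluded.
#' @export
mean_goal_distance <- function(decoded, goal, rotation_deg_s = NULL,
                               exclude_above_deg_s = 12) {
  decoded <- as_xy_matrix(decoded)
  keep <- if (is.null(rotation_deg_s)) rep(TRUE, nrow(decoded)) else {
    if (length(rotation_deg_s) != nrow(decoded))
      stop("rotation series must align with decoded series")
    abs(rotation_deg_s) <= exclude_above_deg_s
  }
  if (!any(keep)) stop("all samples excluded by the rotation criterion")
  list(mean_distance_cm = mean(dist_xy(decoded[keep, , drop = FALSE], goal)),
       retained_fraction = mean(keep))
}

#' Per-task trial duration summary
#'
#' @param trials A per-trial log data frame (fields `task`, `t_start_s`,
#'   `t_end_s`, `outcome`), or a list of them (rows are pooled).
#' @return Data frame per task: `n_trials`, `mean_duration_s`,
#'   `median_duration_s`, `reached_fraction`, `n_censored`. Censored trials
#'   (timeout / limit) enter the means at their censored duration.
#' @export
trial_duration_summary <- function(trials) {
  if (is.list(trials) && !is.data.frame(trials))
    trials <- do.call(rbind, trials)
  if (!nrow(trials)) stop("need at least one trial")
  dur <- trials$t_end_s - trials$t_start_s
  reached <- trials$outcome %in% c("reached", "reward_cap")
  agg <- lapply(split(seq_len(nrow(trials)), trials$task), function(ix) {
    data.frame(task = trials$task[ix[1]], n_trials = length(ix),
               mean_duration_s = mean(dur[ix]),
               median_duration_s = stats::median(dur[ix]),
               reached_fraction = mean(reached[ix]),
               n_censored = sum(!reached[ix]))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
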