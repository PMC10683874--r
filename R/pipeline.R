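#' Full-experiment configuration
#'
#' Bundles every stage's configuration for [run_experiment()]. All
#' sub-seeds are derived deterministically from `master_seed` and the stage
#' name, so a master seed fixes the whole experiment.
#'
#' @param arena An [arena_spec()].
#' @param n_units Number of simulated place units.
#' @param n_running_trials Running-task trials used for decoder training.
#' @param run_params A [run_params()] object.
#' @param decoder A [decoder_config()].
#' @param jumper A [jumper_config()].
#' @param jedi A [jedi_config()].
#' @param agent An [intention_config()] (the Jedi agent reuses it with the
#'   `hold_goal` policy).
#' @param n_shuffles Shuffles per null distribution.
#' @param pv_windows Integration windows for the PV-rPV profile (s).
#' @param noise_levels Noise levels for [noise_robustness_curve()].
#' @param master_seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(arena = arena_spec(), n_units = 90,
                              n_running_trials = 120,
                              run_params = mapbmi::run_params(),
                              decoder = decoder_config(),
                              jumper = jumper_config(),
                              jedi = jedi_config(),
                              agent = intention_config(),
                              n_shuffles = 200,
                              pv_windows = c(0.5, 1, 2, 5),
                              noise_levels = c(0, 0.25, 0.5, 0.75),
                              master_seed = 1L) {
  structure(list(arena = arena, n_units = n_units,
                 n_running_trials = n_running_trials,
                 run_params = run_params, decoder = decoder,
                 jumper = jumper, jedi = jedi, agent = agent,
                 n_shuffles = n_shuffles, pv_windows = pv_windows,
                 noise_levels = noise_levels,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Run the three-phase experiment end to end
#'
#' Phase 1 simulates the Running task; phase 2 computes the place-field
#' (rPV) map and trains the decoder; phase 3 runs the Jumper and Jedi
#' closed-loop sessions. The full analysis battery follows: trial-duration
#' summaries, the unit-identity and goal-location shuffle nulls, the
#' angle-to-goal distribution, PV-rPV correlation profiles, PBE detection
#' and excision re-decoding, decoder noise-robustness, and the
#' movement/immobility theta PSD peaks. Everything is reproducible from the
#' master seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory; when given, a machine-readable
#'   `summary.json` (versioned schema), per-stage CSV logs and (with
#'   `plots = TRUE`) PDF figures are written.
#' @param plots Write diagnostic figures (requires `out_dir`).
#' @return A list of class `experiment_result` with all stage objects and
#'   the `summary` list.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           plots = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  # phase 1: Running task
  ensemble <- make_ensemble(config$arena, config$n_units,
                            seed = derive_seed(ms, "ensemble"))
  running <- simulate_running_session(config$arena, ensemble,
                                      n_trials = config$n_running_trials,
                                      params = config$run_params,
                                      seed = derive_seed(ms, "running"))
  # phase 2: map + decoder
  rpv_map <- compute_rpv_map(running$raster, running$trajectory, config$arena)
  windows <- make_training_windows(running$raster, running$trajectory,
                                   config$decoder)
  model <- train_decoder(windows, arena = config$arena,
                         seed = derive_seed(ms, "decoder"))
  # phase 3: closed-loop BMI tasks
  jumper <- run_jumper_session(rpv_map, model, config$agent, config$jumper,
                               seed = derive_seed(ms, "jumper"))
  jedi_agent <- config$agent
  jedi_agent$policy <- "hold_goal"
  jedi <- run_jedi_session(rpv_map, model, jedi_agent, config$jedi,
                           seed = derive_seed(ms, "jedi"))
  # statistics
  durations <- trial_duration_summary(rbind(running$trials, jumper$trials,
                                            jedi$trials))
  unit_null <- unit_shuffle_duration_null(jumper, model,
                                          n_shuffles = config$n_shuffles,
                                          seed = derive_seed(ms, "unitshuffle"))
  goal_null_jumper <- shuffle_goals_null(jumper, metric = "time_to_reach",
                                         n_shuffles = config$n_shuffles,
                                         seed = derive_seed(ms, "goalshuffle_jumper"))
  goal_null_jedi <- shuffle_goals_null(jedi, metric = "mean_distance",
                                       n_shuffles = config$n_shuffles,
                                       seed = derive_seed(ms, "goalshuffle_jedi"))
  angles <- angle_to_goal_histogram(trial_paths(jumper, "avatar"),
                                    cbind(jumper$trials$goal_x_cm,
                                          jumper$trials$goal_y_cm))
  # Jedi distance-to-goal with the rotation exclusion
  jedi_dist <- mean(vapply(seq_len(nrow(jedi$trials)), function(i) {
    sel <- jedi$streams$t_s > jedi$trials$t_start_s[i] &
      jedi$streams$t_s <= jedi$trials$t_end_s[i]
    mean_goal_distance(cbind(jedi$streams$decoded_x,
                             jedi$streams$decoded_y)[sel, , drop = FALSE],
                       c(jedi$trials$goal_x_cm[i], jedi$trials$goal_y_cm[i]),
                       jedi$streams$rotation_deg_s[sel])$mean_distance_cm
  }, numeric(1)))
  # PV-rPV correlation profile on Jedi (hold-goal) data
  jedi_locs <- data.frame(t_s = jedi$streams$t_s,
                          x_cm = jedi$streams$decoded_x,
                          y_cm = jedi$streams$decoded_y)
  pv_profile <- pv_rpv_correlation_profile(jedi$raster, jedi_locs, rpv_map,
                                           windows = config$pv_windows,
                                           seed = derive_seed(ms, "pvcorr"))
  # PBEs: detect on Jedi emission, excise and re-decode
  pbes <- detect_pbes(jedi$raster, jedi$streams$speed_cm_s)
  pbe_redecode <- mask_pbes_and_redecode(jedi$raster, pbes, model)
  rate_cmp <- rate_correlation_across_tasks(running$raster, jedi$raster)
  # decoder robustness to corrupted rPV probes
  robustness <- noise_robustness_curve(model, rpv_map,
                                       noise_levels = config$noise_levels,
                                       seed = derive_seed(ms, "robustness"))
  # theta spectral peaks during movement versus immobility
  still <- segment_immobility(running$trajectory$speed_cm_s)
  moving <- segment_movement(running$trajectory$speed_cm_s)
  psd_move <- psd_theta_peak(running$lfp, moving)
  psd_still <- psd_theta_peak(running$lfp, still)
  summary <- list(
    schema_version = 1L,
    master_seed = ms,
    n_units = config$n_units,
    running_minutes = raster_duration(running$raster) / 60,
    decoder = list(validation_r2_x = unname(model$validation_r2[1]),
                   validation_r2_y = unname(model$validation_r2[2]),
                   median_error_cm = model$validation_median_error_cm),
    durations = durations,
    jumper = list(reached_fraction =
                    mean(jumper$trials$outcome == "reached"),
                  mean_duration_s = mean(jumper$trials$t_end_s -
                                           jumper$trials$t_start_s),
                  unit_shuffle_p_empirical = unit_null$p_empirical,
                  unit_shuffle_p_normal = unit_null$p_normal,
                  goal_shuffle_p_empirical = goal_null_jumper$p_empirical,
                  angle_mode_deg = angles$mode_deg,
                  angle_resultant = angles$resultant_length),
    jedi = list(mean_goal_distance_cm = jedi_dist,
                goal_shuffle_p_empirical = goal_null_jedi$p_empirical,
                goal_shuffle_p_normal = goal_null_jedi$p_normal,
                rate_ratio_vs_running = rate_cmp$median_ratio,
                rate_correlation_r = rate_cmp$pearson_r),
    pv_rpv = pv_profile,
    pbe = list(n_events = nrow(pbes),
               redecode_flagged_fraction = mean(pbe_redecode$overlaps_pbe)),
    robustness = robustness,
    lfp = list(theta_peak_move_hz = psd_move$peak_hz,
               theta_peak_still_hz = psd_still$peak_hz,
               n_still_segments = nrow(still),
               mean_still_duration_s = if (nrow(still)) mean(still$duration_s)
               else NA_real_))
  result <- structure(
    list(config = config, ensemble = ensemble, running = running,
         rpv_map = rpv_map, model = model, jumper = jumper, jedi = jedi,
         nulls = list(unit = unit_null, goal_jumper = goal_null_jumper,
                      goal_jedi = goal_null_jedi),
         angles = angles, pv_profile = pv_profile, pbes = pbes,
         robustness = robustness,
         psd = list(move = psd_move, still = psd_still),
         summary = summary),
    class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_experiment_summary(summary, file.path(out_dir, "summary.json"))
    write_session_csv(running$trajectory, file.path(out_dir, "trajectory.csv"))
    write_session_csv(durations, file.path(out_dir, "durations.csv"))
    write_session_csv(jumper$trials, file.path(out_dir, "jumper_trials.csv"))
    write_session_csv(jedi$trials, file.path(out_dir, "jedi_trials.csv"))
    write_session_csv(pv_profile, file.path(out_dir, "pv_rpv_profile.csv"))
    write_session_csv(robustness, file.path(out_dir, "noise_robustness.csv"))
    if (plots) write_experiment_plots(result, out_dir)
  }
  result
}

segment_movement <- function(speed_cm_s, min_dur_s = 4, min_speed_cm_s = 5,
                             dt = 0.1) {
  # movement epochs are defined on 1-s-smoothed speed so brief dips below
  # threshold do not chop a run into sub-window fragments
  k <- as.integer(round(1 / dt))
  sm <- stats::filter(speed_cm_s, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- speed_cm_s[is.na(sm)]
  moving <- as.numeric(sm) > min_speed_cm_s
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * dt >= min_dur_s
  data.frame(t_start_s = (starts[keep] - 1L) * dt, t_end_s = ends[keep] * dt,
             duration_s = r$lengths[keep] * dt)
}

#' @export
print.experiment_result <- function(x, ...) {
  s <- x$summary
  cat("<experiment_result>\n")
  cat(sprintf("  decoder validation R2: x %.3f, y %.3f\n",
              s$decoder$validation_r2_x, s$decoder$validation_r2_y))
  cat(sprintf("  Jumper reached %.0f%%, mean duration %.1f s (p_unit %.3g, p_goal %.3g)\n",
              100 * s$jumper$reached_fraction, s$jumper$mean_duration_s,
              s$jumper$unit_shuffle_p_empirical,
              s$jumper$goal_shuffle_p_empirical))
  cat(sprintf("  Jedi mean goal distance %.1f cm (p_goal %.3g)\n",
              s$jedi$mean_goal_distance_cm, s$jedi$goal_shuffle_p_empirical))
  cat(sprintf("  theta peaks: move %.2f Hz, still %.2f Hz\n",
              s$lfp$theta_peak_move_hz, s$lfp$theta_peak_still_hz))
  invisible(x)
}

#' Write / read the machine-readable experiment summary
#'
#' The summary is a versioned JSON document; the reader rejects unknown
#' schema versions.
#'
#' @param summary The `summary` element of an [run_experiment()] result.
#' @param path JSON file path.
#' @export
write_experiment_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_experiment_summary
#' @export
read_experiment_summary <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(s$schema_version) || s$schema_version != 1L)
    stop("unknown summary schema version")
  s
}

write_experiment_plots <- function(result, out_dir) {
  pdf_one <- function(name, expr) {
    grDevices::pdf(file.path(out_dir, name), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    force(expr)
  }
  pdf_one("decoder_validation.pdf", plot(result$model))
  pdf_one("angles.pdf", plot(result$angles))
  pdf_one("psd.pdf", {
    plot(result$psd$move, main = "movement vs immobility theta")
    graphics::lines(result$psd$still$freqs, result$psd$still$power,
                    col = "blue")
  })
  pdf_one("pv_profile.pdf", {
    p <- result$pv_profile
    graphics::plot(p$window_s, p$matched_mean, type = "b", ylim = c(0, 1),
                   xlab = "integration window (s)", ylab = "PV-rPV correlation")
    graphics::lines(p$window_s, p$random_mean, type = "b", col = "gray")
  })
  pdf_one("noise_robustness.pdf", {
    r <- result$robustness
    reg <- r[r$decoder == "regressor", ]
    bay <- r[r$decoder == "bayesian", ]
    graphics::plot(reg$noise_level, reg$mean_error_cm, type = "b",
                   ylim = range(r$mean_error_cm), xlab = "noise level",
                   ylab = "mean decoding error (cm)")
    graphics::lines(bay$noise_level, bay$mean_error_cm, type = "b",
                    col = "red")
    graphics::legend("topleft", c("regressor", "Bayesian"),
                     col = c("black", "red"), lty = 1)
  })
  invisible(NULL)
}

#' Generate a standard test fixture session
#'
#' `"tiny"` (a dozen units, a couple of minutes; fast unit-test fixture) or
#' `"small"` (80 units, a ~40-minute Running session supporting full
#' decoder training).
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Integer seed.
#' @return A list with `arena`, `ensemble`, `session` (a
#'   [simulate_running_session()] result).
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 1L) {
  size <- match.arg(size)
  arena <- arena_spec()
  if (size == "tiny") {
    ensemble <- make_ensemble(arena, 12, seed = derive_seed(seed, "ensemble"))
    session <- simulate_running_session(
      arena, ensemble, n_trials = 10,
      params = run_params(pause_range_s = c(4, 8)),
      seed = derive_seed(seed, "session"))
  } else {
    ensemble <- make_ensemble(arena, 80, seed = derive_seed(seed, "ensemble"))
    session <- simulate_running_session(arena, ensemble, n_trials = 120,
                                        seed = derive_seed(seed, "session"))
  }
  list(arena = arena, ensemble = ensemble, session = session)
}
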