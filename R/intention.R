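#' Intention-agent configuration
#'
#' The intention agent is the simulated stand-in for the animal's volitional
#' hippocampal activity during the BMI tasks: it emits Poisson population
#' activity whose per-unit rate is a convex blend of the reference
#' population vector (rPV) at the intended location and the unit's session
#' mean rate,
#' `rate_i = fidelity * rate_gain * rPV_i(intended) +
#'  (1 - fidelity) * mean_rate_i + noise_floor_hz`.
#' `fidelity` is the single knob for how faithfully the agent reproduces the
#' map representation: 1 gives ideal place-field-like activity, 0 gives
#' spatially uninformative activity.
#'
#' @param fidelity Blend weight in \[0, 1\].
#' @param rate_gain Multiplier on the rPV component (> 0).
#' @param noise_floor_hz Baseline Poisson rate added to every unit (Hz).
#' @param policy Intended-location rule: `"toward_goal"` (intend the goal
#'   itself), `"hold_goal"` (same, used when holding an object at the goal),
#'   or `"random_walk"` (goal-blind control agent).
#' @param walk_step_cm Per-tick step of the random-walk policy (cm).
#' @param seed Integer seed.
#' @return A list of class `intention_config`.
#' @export
intention_config <- function(fidelity = 1, rate_gain = 1, noise_floor_hz = 0,
                             policy = c("toward_goal", "hold_goal",
                                        "random_walk"),
                             walk_step_cm = 5, seed = 1L) {
  policy <- match.arg(policy)
  if (fidelity < 0 || fidelity > 1) stop("fidelity must be in [0, 1]")
  if (rate_gain <= 0) stop("rate_gain must be > 0")
  if (noise_floor_hz < 0) stop("noise_floor_hz must be >= 0")
  structure(list(fidelity = fidelity, rate_gain = rate_gain,
                 noise_floor_hz = noise_floor_hz, policy = policy,
                 walk_step_cm = walk_step_cm, seed = as.integer(seed)),
            class = "intention_config")
}

# Per-unit emission rate (Hz) for an intended location.
intention_rates <- function(rpv_map, intended_xy, cfg, warn = TRUE) {
  r <- rpv_at(rpv_map, intended_xy, warn = warn)
  cfg$fidelity * cfg$rate_gain * r$rates +
    (1 - cfg$fidelity) * rpv_map$mean_rates + cfg$noise_floor_hz
}

#' Emit intention-agent population activity for a fixed intended location
#'
#' Draws a Poisson spike raster at the base bin width whose expected counts
#' per bin equal the agent's emission rate times the bin width.
#'
#' @param rpv_map A [compute_rpv_map()] object.
#' @param intended_xy Intended location (cm); if its bin is occupancy-masked
#'   the nearest unmasked bin is used with a warning.
#' @param cfg An [intention_config()].
#' @param duration_s Segment length (s).
#' @param seed Integer seed.
#' @param base_bin_s Base bin width (s).
#' @return A [spike_raster()] segment.
#' @export
intention_pv <- function(rpv_map, intended_xy, cfg, duration_s, seed = 1L,
                         base_bin_s = 0.01) {
  stopifnot(inherits(rpv_map, "place_field_map"),
            inherits(cfg, "intention_config"))
  rates <- intention_rates(rpv_map, intended_xy, cfg)
  nb <- as.integer(round(duration_s / base_bin_s))
  with_seed(seed, {
    counts <- matrix(stats::rpois(length(rates) * nb, rates * base_bin_s),
                     nrow = length(rates))
    spike_raster(counts, bin_s = base_bin_s, unit_ids = rpv_map$unit_ids)
  })
}
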