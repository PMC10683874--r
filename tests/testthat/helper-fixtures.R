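# Shared fixtures, built lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Tiny session: 12 units, ~1.5 min; fast enough for unit tests.
tiny_fixture <- function() cached("tiny", function() make_fixture("tiny", seed = 3))

# Mid-sized session (~14 min) for map-recovery and decoder-property tests.
mid_fixture <- function() cached("mid", function() {
  arena <- arena_spec()
  ensemble <- make_ensemble(arena, 60, seed = 7)
  session <- simulate_running_session(arena, ensemble, n_trials = 80,
                                      params = run_params(pause_range_s = c(6, 10)),
                                      seed = 8)
  list(arena = arena, ensemble = ensemble, session = session,
       map = compute_rpv_map(session$raster, session$trajectory, arena))
})

# Small decoder-model spec used where full accuracy is not the point.
small_model_spec <- list(hidden = c(64, 64), epochs = 100, batch = 128,
                         lr = 1e-3, l2 = 1e-4)

# Decoder trained on the mid fixture with the small model spec.
mid_model <- function() cached("mid_model", function() {
  fx <- mid_fixture()
  cfg <- decoder_config(model = small_model_spec)
  tw <- make_training_windows(fx$session$raster, fx$session$trajectory, cfg)
  train_decoder(tw, arena = fx$arena, seed = 42)
})

# Full study-scale artifacts backing the acceptance suite: a ~40-min
# Running session with 90 units, the rPV map, the default trained decoder,
# and fidelity-1/0 Jumper arms plus a fidelity-1 Jedi session.
acc_artifacts <- function() cached("acc", function() {
  arena <- arena_spec()
  ensemble <- make_ensemble(arena, 90, seed = 11)
  session <- simulate_running_session(arena, ensemble, n_trials = 120,
                                      seed = 12)
  map <- compute_rpv_map(session$raster, session$trajectory, arena)
  windows <- make_training_windows(session$raster, session$trajectory,
                                   decoder_config())
  model <- train_decoder(windows, arena = arena, seed = 13)
  jumper1 <- run_jumper_session(map, model, intention_config(fidelity = 1),
                                jumper_config(n_trials = 50), seed = 21)
  jumper0 <- run_jumper_session(map, model, intention_config(fidelity = 0),
                                jumper_config(n_trials = 50), seed = 22)
  jedi1 <- run_jedi_session(map, model,
                            intention_config(fidelity = 1,
                                             policy = "hold_goal"),
                            jedi_config(n_trials = 6), seed = 23)
  list(arena = arena, ensemble = ensemble, session = session, map = map,
       windows = windows, model = model, jumper1 = jumper1,
       jumper0 = jumper0, jedi1 = jedi1)
})

# Homogeneous-Poisson raster with bursts of known timing implanted.
planted_burst_raster <- function(n_units = 30, duration_s = 100,
                                 base_rate = 2, burst_gain = 10,
                                 burst_dur_s = 0.1, n_bursts = 12,
                                 seed = 5) {
  nb <- as.integer(duration_s / 0.01)
  set.seed(seed)
  counts <- matrix(rpois(n_units * nb, base_rate * 0.01), n_units)
  burst_bins <- as.integer(burst_dur_s / 0.01)
  starts <- sort(sample(seq(100L, nb - 200L, by = 300L), n_bursts))
  for (s in starts) {
    idx <- s:(s + burst_bins - 1L)
    counts[, idx] <- counts[, idx] +
      matrix(rpois(n_units * burst_bins, (burst_gain - 1) * base_rate * 0.01),
             n_units)
  }
  list(raster = spike_raster(counts, bin_s = 0.01),
       t_start = (starts - 1L) * 0.01,
       t_end = (starts - 1L + burst_bins) * 0.01)
}
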