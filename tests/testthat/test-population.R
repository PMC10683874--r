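test_that("rate maps divide spikes by occupancy and honour the mask", {
  arena <- arena_spec()
  # stationary animal: 60 s parked inside one bin
  traj <- data.frame(t_s = seq(0, 59.9, by = 0.1),
                     x_cm = rep(32, 600), y_cm = rep(57, 600))
  set.seed(4)
  counts <- matrix(rpois(3 * 6000, c(0.05, 0.1, 0.01)), 3, 6000)
  r <- spike_raster(counts, bin_s = 0.01)
  map <- compute_rpv_map(r, traj, arena, smoothing_sigma_cm = 0)
  b <- xy_to_bin(arena, c(32, 57))
  expect_equal(sum(map$mask), 1L)
  expect_true(map$mask[b])
  expect_equal(map$rates[, b], rowSums(counts) / 60,
               ignore_attr = TRUE)
  expect_true(all(is.na(map$rates[, -b])))
})

test_that("unsmoothed rate x occupancy recovers total spike counts exactly", {
  fx <- mid_fixture()
  map <- fx$map
  occ <- matrix(map$occupancy, nrow = nrow(map$rates_raw),
                ncol = ncol(map$rates_raw), byrow = TRUE)
  recovered <- rowSums(map$rates_raw * occ, na.rm = TRUE)
  # totals restricted to samples spent in unmasked bins
  r100 <- bin_counts(fx$session$raster, 0.1)
  n_t <- min(ncol(r100$counts), nrow(fx$session$trajectory))
  bins <- xy_to_bin(fx$arena, cbind(fx$session$trajectory$x_cm,
                                    fx$session$trajectory$y_cm)[1:n_t, ])
  in_mask <- map$mask[bins]
  expected <- rowSums(r100$counts[, which(in_mask), drop = FALSE])
  expect_equal(unname(recovered), unname(expected), tolerance = 1e-10)
})

test_that("rate-map peaks recover the generating field centers", {
  fx <- mid_fixture()
  map <- fx$map
  ens <- fx$ensemble
  # recoverable fields: strong tuning and a field center the trajectory
  # actually sampled (unmasked bin) — unvisited fields cannot be localized
  center_bin <- xy_to_bin(fx$arena, ens$centers)
  strong <- which(ens$peak_rates >= 5 * ens$baseline_rates &
                    map$mask[center_bin])
  expect_gt(length(strong), 10)
  ctr <- bin_centers(fx$arena)
  err_bins <- vapply(strong, function(u) {
    peak_bin <- which.max(map$rates[u, ])
    max(abs(ctr[peak_bin, ] - ens$centers[u, ])) / fx$arena$spatial_bin_cm
  }, numeric(1))
  # within one bin of the true center (adjacent-bin quantization: 1.5 bin
  # widths from the argmax bin center to the continuous true center)
  expect_gte(mean(err_bins <= 1.5), 0.8)
})

test_that("population vectors are windowed rate estimates", {
  counts <- matrix(0, 2, 200)
  counts[, 151:200] <- 1   # one spike per 10-ms bin in the last 0.5 s
  r <- spike_raster(counts, bin_s = 0.01)
  expect_equal(unname(population_vector(r, 2, 0.5)), c(100, 100))
  expect_equal(unname(population_vector(r, 1.5, 0.5)), c(0, 0))
  expect_error(population_vector(r, 0.3, 0.5), "outside")
  # a PV constructed exactly from an rPV column correlates at 1
  fx <- mid_fixture()
  map <- fx$map
  b <- which(map$mask)[5]
  pv_counts <- matrix(map$rates[, b] * 0.01, nrow = nrow(map$rates), ncol = 50)
  rr <- spike_raster(pv_counts, bin_s = 0.01, unit_ids = map$unit_ids)
  pv <- population_vector(rr, 0.5, 0.5)
  expect_equal(cor(pv, map$rates[, b]), 1, tolerance = 1e-12)
})

test_that("the near-goal filter restricts PV correlations to goal-adjacent samples", {
  fx <- mid_fixture()
  s <- fx$session
  locs <- data.frame(t_s = s$trajectory$t_s, x_cm = s$trajectory$x_cm,
                     y_cm = s$trajectory$y_cm)
  goal <- c(s$trials$goal_x_cm[1], s$trials$goal_y_cm[1])
  short <- spike_raster(s$raster$counts[, 1:30000], bin_s = 0.01,
                        unit_ids = s$raster$unit_ids)
  all_pts <- pv_rpv_correlation_profile(short, locs[1:3000, ], fx$map,
                                        windows = 0.5, n_boot = 50, seed = 1)
  # the runner stops at the 10-cm goal radius, so filter slightly wider
  near <- pv_rpv_correlation_profile(short, locs[1:3000, ], fx$map,
                                     windows = 0.5, near_goal_cm = 15,
                                     goal = goal, n_boot = 50, seed = 1)
  expect_lt(near$n_timepoints, all_pts$n_timepoints)
  expect_gt(near$n_timepoints, 0)
  expect_error(pv_rpv_correlation_profile(short, locs[1:3000, ], fx$map,
                                          windows = 0.5, near_goal_cm = 5),
               "goal required")
})

test_that("burst detection finds planted events and respects edge cases", {
  pl <- planted_burst_raster()
  ev <- detect_pbes(pl$raster, speed_cm_s = NULL, max_speed_cm_s = Inf)
  # recall and precision with +/- 50 ms matching
  matched <- vapply(seq_along(pl$t_start), function(i) {
    any(abs(ev$t_start_s - pl$t_start[i]) <= 0.05 |
          abs(ev$t_end_s - pl$t_end[i]) <= 0.05)
  }, logical(1))
  hit <- vapply(seq_len(nrow(ev)), function(j) {
    any(pl$t_start - 0.05 <= ev$t_end_s[j] & pl$t_end + 0.05 >= ev$t_start_s[j])
  }, logical(1))
  expect_gte(mean(matched), 0.9)
  expect_gte(mean(hit), 0.9)
  # intervals disjoint, sorted, in bounds
  expect_true(all(diff(ev$t_start_s) > 0))
  expect_true(all(ev$t_end_s > ev$t_start_s))
  expect_true(all(ev$t_end_s <= 100))
  if (nrow(ev) > 1)
    expect_true(all(ev$t_start_s[-1] >= ev$t_end_s[-nrow(ev)]))
  # speed gating removes events during movement
  fast <- rep(50, 1000)
  expect_equal(nrow(detect_pbes(pl$raster, fast, max_speed_cm_s = 5)), 0L)
  # degenerate all-zero raster
  z <- spike_raster(matrix(0, 3, 1000), bin_s = 0.01)
  expect_warning(ez <- detect_pbes(z), "zero-variance")
  expect_equal(nrow(ez), 0L)
})

test_that("PBE excision only perturbs decoding windows that overlap events", {
  fx <- mid_fixture()
  m <- mid_model()
  seg <- fx$session$raster
  short <- spike_raster(seg$counts[, 1:30000], bin_s = 0.01,
                        unit_ids = seg$unit_ids)   # 5 min
  plain <- decode_stream(m, short)
  none <- mask_pbes_and_redecode(short, mapbmi:::empty_pbes(), m)
  expect_equal(cbind(none$x_cm, none$y_cm), cbind(plain$x_cm, plain$y_cm))
  iv <- data.frame(t_start_s = c(100, 100.3), t_end_s = c(100.4, 100.6))
  expect_warning(masked <- mask_pbes_and_redecode(short, iv, m), "merged")
  same <- !masked$overlaps_pbe
  expect_gt(sum(same), 0)
  expect_equal(cbind(masked$x_cm, masked$y_cm)[same, ],
               cbind(plain$x_cm, plain$y_cm)[same, ])
  expect_true(any(masked$overlaps_pbe))
})

test_that("cross-task rate comparisons behave under duplication and thinning", {
  fx <- mid_fixture()
  r <- fx$session$raster
  self <- rate_correlation_across_tasks(r, r)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$median_ratio, 1)
  # deleting every other bin halves duration but preserves rates
  half <- spike_raster(r$counts[, seq(1, ncol(r$counts), by = 2)],
                       bin_s = 0.01, unit_ids = r$unit_ids)
  sub <- rate_correlation_across_tasks(r, half)
  expect_gt(sub$pearson_r, 0.98)
  expect_equal(sub$median_ratio, 1, tolerance = 0.1)
  # binomial thinning halves rates but keeps them correlated
  set.seed(9)
  thinned <- r
  thinned$counts <- matrix(rbinom(length(r$counts), as.integer(r$counts), 0.5),
                           nrow(r$counts), dimnames = dimnames(r$counts))
  thin <- rate_correlation_across_tasks(r, thinned)
  expect_equal(thin$median_ratio, 0.5, tolerance = 0.1)
  expect_gt(thin$pearson_r, 0.95)
  expect_error(rate_correlation_across_tasks(
    spike_raster(matrix(1, 2, 5)), spike_raster(matrix(1, 2, 5))), "3 units")
})
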