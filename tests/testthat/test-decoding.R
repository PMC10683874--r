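test_that("training-window construction follows the stated conventions", {
  # 10-s session, 5-s window: trailing edges 5.0 .. 10.0 s inclusive
  counts <- matrix(rpois(4 * 1000, 0.2), 4, 1000)
  r <- spike_raster(counts, bin_s = 0.01)
  traj <- data.frame(t_s = seq(0, 99.9, by = 0.1)[1:100],
                     x_cm = seq(1, 100, length.out = 100),
                     y_cm = rep(50, 100))
  tw <- make_training_windows(r, traj, decoder_config(window_s = 5))
  expect_equal(length(tw$end_bins), 51L)
  expect_equal(tw$end_bins[1] * 0.1, 5)
  expect_equal(tw$end_bins[51] * 0.1, 10)
  # targets are the on-grid trajectory positions at t_end, no interpolation
  expect_equal(tw$targets[, 1], traj$x_cm[tw$end_bins])
  # window shape at 1.5 s and 0.1-s bins is units x 15
  tw15 <- make_training_windows(r, traj, decoder_config(window_s = 1.5))
  expect_equal(dim(get_window(tw15, 1)), c(4L, 15L))
  expect_warning(
    make_training_windows(spike_raster(counts[, 1:100], bin_s = 0.01),
                          traj[1:10, ], decoder_config(window_s = 5)),
    "shorter")
})

test_that("window augmentation follows its declared recipe", {
  set.seed(2)
  w <- matrix(rpois(30 * 20, 2), 30, 20)
  none <- augmentation_config(unit_dropout_p = 0, count_noise_scale = 0,
                              time_jitter_bins = 0, n_augmented_copies = 1)
  expect_identical(augment_window(w, none, seed = 1), w)
  expect_identical(augment_window(w, augmentation_config(), seed = 7),
                   augment_window(w, augmentation_config(), seed = 7))
  # circular time shift preserves per-unit totals
  shift_only <- augmentation_config(unit_dropout_p = 0, count_noise_scale = 0,
                                    time_jitter_bins = 3,
                                    n_augmented_copies = 1)
  expect_equal(rowSums(augment_window(w, shift_only, seed = 3)), rowSums(w))
  # dropout fraction matches its binomial expectation over many draws
  drop_only <- augmentation_config(unit_dropout_p = 0.3, count_noise_scale = 0,
                                   time_jitter_bins = 0,
                                   n_augmented_copies = 1)
  frac <- vapply(1:2000, function(s) {
    mean(rowSums(augment_window(w, drop_only, seed = s)) == 0)
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / (30 * 2000))
  expect_lt(abs(mean(frac) - 0.3), 3 * se + 1e-3)
  expect_error(augmentation_config(unit_dropout_p = 1), "unit_dropout_p")
})

test_that("r2_score matches its definition on hand-computed cases", {
  act <- cbind(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r2_score(act, act)$r2, c(x = 1, y = 1))
  cm <- cbind(rep(3, 5), rep(3, 5))
  expect_equal(r2_score(cm, act)$r2, c(x = 0, y = 0))
  pred <- cbind(c(1.5, 2, 2.5, 4.5, 5), c(2, 2, 3, 3, 4))
  ssx <- 1 - sum((act[, 1] - pred[, 1])^2) / sum((act[, 1] - 3)^2)
  ssy <- 1 - sum((act[, 2] - pred[, 2])^2) / sum((act[, 2] - 3)^2)
  expect_equal(r2_score(pred, act)$r2, c(x = ssx, y = ssy))
  expect_equal(r2_score(pred, act)$median_error_cm,
               median(sqrt(rowSums((pred - act)^2))))
  expect_error(r2_score(cbind(1:3, 1:3), cbind(rep(1, 3), 1:3)), "variance")
  expect_error(r2_score(cbind(1:3, 1:3), cbind(1:4, 1:4)), "equal length")
})

test_that("training requires informative data and is seed-deterministic", {
  fx <- mid_fixture()
  cfg <- decoder_config(model = small_model_spec)
  tw <- make_training_windows(fx$session$raster, fx$session$trajectory, cfg)
  expect_error(train_decoder(matrix(1, 200, 3), targets = cbind(rep(1, 200),
                                                                rep(2, 200)),
                             config = cfg),
               "degenerate")
  expect_error(train_decoder(matrix(1, 50, 3), targets = cbind(1:50, 1:50),
                             config = cfg),
               "100 windows")
  m1 <- mid_model()
  m2 <- train_decoder(tw, arena = fx$arena, seed = 42)
  expect_identical(m1$validation_r2, m2$validation_r2)
  expect_identical(m1$fit, m2$fit)
  expect_gt(mean(m1$validation_r2), 0.5)
})

test_that("zero-fidelity emissions carry no decodable position signal", {
  fx <- mid_fixture()
  cfg <- decoder_config(model = small_model_spec)
  # emission with fidelity 0 has location-independent rates; pair it with a
  # wandering trajectory and train: held-out R2 collapses to chance
  seg <- intention_pv(fx$map, c(50, 50), intention_config(fidelity = 0),
                      duration_s = 240, seed = 6)
  set.seed(7)
  ang <- cumsum(rnorm(2400, 0, 0.3))
  traj <- data.frame(t_s = seq(0.1, 240, by = 0.1),
                     x_cm = 50 + 40 * sin(ang),
                     y_cm = 50 + 40 * cos(0.7 * ang))
  tw <- make_training_windows(seg, traj, cfg)
  m <- train_decoder(tw, arena = fx$arena, seed = 8)
  expect_lt(mean(m$validation_r2), 0.05)
})

test_that("augmentation training confers robustness to corrupted inputs", {
  fx <- mid_fixture()
  cfg_aug <- decoder_config(model = small_model_spec)
  cfg_plain <- decoder_config(model = small_model_spec,
                              augmentation = augmentation_config(
                                unit_dropout_p = 0, count_noise_scale = 0,
                                time_jitter_bins = 0, n_augmented_copies = 0))
  tw <- make_training_windows(fx$session$raster, fx$session$trajectory,
                              cfg_aug)
  m_aug <- mid_model()
  m_plain <- train_decoder(tw, config = cfg_plain, arena = fx$arena,
                           seed = 42)
  feats <- mapbmi:::window_features(tw$counts, tw$end_bins, cfg_aug)
  n_val <- nrow(feats)
  va <- seq.int(floor(0.8 * n_val) + 1L, n_val)
  set.seed(31)
  n_units <- length(tw$unit_ids)
  drop <- matrix(runif(length(va) * n_units) < 0.3, length(va))
  corrupted <- feats[va, , drop = FALSE]
  corrupted[rep(drop, length(cfg_aug$feature_windows))] <- 0
  r_aug <- r2_score(mapbmi:::predict_features(m_aug, corrupted),
                    tw$targets[va, ])
  r_plain <- r2_score(mapbmi:::predict_features(m_plain, corrupted),
                      tw$targets[va, ])
  expect_gte(r_aug$mean_r2, r_plain$mean_r2)
  expect_gt(r_aug$mean_r2, 0.5)
})

test_that("streamed decoding equals batch prediction and enforces unit sets", {
  fx <- mid_fixture()
  cfg <- decoder_config(model = small_model_spec)
  tw <- make_training_windows(fx$session$raster, fx$session$trajectory, cfg)
  m <- mid_model()
  dec <- decode_stream(m, fx$session$raster)
  expect_equal(nrow(dec), length(tw$end_bins))
  batch <- predict(m, tw)
  expect_equal(cbind(dec$x_cm, dec$y_cm), unname(batch))
  expect_true(all(dec$x_cm >= 0 & dec$x_cm <= fx$arena$side_cm))
  expect_true(all(dec$y_cm >= 0 & dec$y_cm <= fx$arena$side_cm))
  # all-zero raster decodes to a constant (whatever zero maps to)
  z <- spike_raster(matrix(0, fx$ensemble$n_units, 6000), bin_s = 0.01,
                    unit_ids = fx$ensemble$unit_ids)
  dz <- decode_stream(m, z)
  expect_equal(max(mapbmi:::dist_xy(cbind(dz$x_cm, dz$y_cm),
                           c(dz$x_cm[1], dz$y_cm[1]))), 0)
  # unit mismatch is a hard error, never silent reindexing
  bad <- fx$session$raster
  bad$unit_ids <- rev(bad$unit_ids)
  expect_error(decode_stream(m, bad), "unit")
  # serialization round trip preserves behaviour
  path <- withr::local_tempfile(fileext = ".rds")
  write_decoder(m, path)
  m2 <- read_decoder(path)
  expect_identical(predict(m2, tw)[1:5, ], batch[1:5, ])
})
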