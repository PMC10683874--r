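test_that("immobility segmentation finds exactly the qualifying runs", {
  expect_equal(segment_immobility(rep(0, 600)),
               data.frame(t_start_s = 0, t_end_s = 60, duration_s = 60))
  # alternating 7 s still / 1 s moving: no run reaches 8 s
  sp <- rep(c(rep(0, 70), rep(5, 10)), 5)
  expect_equal(nrow(segment_immobility(sp)), 0L)
  # three planted runs amid noise, recovered with exact boundaries
  set.seed(3)
  sp2 <- runif(3000, 5, 30)
  sp2[101:200] <- 0.2      # 10 s
  sp2[1001:1085] <- 0.8    # 8.5 s
  sp2[2501:2600] <- 0      # 10 s
  seg <- segment_immobility(sp2)
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$t_start_s, c(10, 100, 250))
  expect_equal(seg$duration_s, c(10, 8.5, 10))
})

test_that("Welch PSD conserves variance and resolves pure tones", {
  fs <- 1000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  for (f0 in c(5.5, 8.25, 11.75)) {
    x <- structure(list(values = sin(2 * pi * f0 * t), fs = fs,
                        zscored = FALSE), class = "lfp_trace")
    pk <- psd_theta_peak(x, zscore_first = FALSE)
    expect_lte(abs(pk$peak_hz - f0), 0.25)   # within one resolution step
  }
  set.seed(8)
  x <- stats::filter(rnorm(40 * fs), rep(0.2, 5), circular = TRUE)
  x <- as.numeric(x)
  ps <- mapbmi:::welch_psd(x, fs)
  total_power <- sum(ps$power) * (ps$freqs[2] - ps$freqs[1])
  expect_equal(total_power, var(x), tolerance = 0.1)
})

test_that("segment-aware PSD never mixes samples across a gap", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  # 6-Hz tone for the first 10 s, 10-Hz tone afterwards
  v <- ifelse(t < 10, sin(2 * pi * 6 * t), sin(2 * pi * 10 * t))
  lfp <- structure(list(values = v, fs = fs, zscored = FALSE),
                   class = "lfp_trace")
  seg_a <- data.frame(t_start_s = 0, t_end_s = 10)
  seg_b <- data.frame(t_start_s = 10, t_end_s = 30)
  pa <- psd_theta_peak(lfp, seg_a, zscore_first = FALSE)
  pb <- psd_theta_peak(lfp, seg_b, zscore_first = FALSE)
  expect_equal(pa$peak_hz, 6, tolerance = 0.25)
  expect_equal(pb$peak_hz, 10, tolerance = 0.25)
  # power of segment A at 10 Hz is negligible: no leakage across the gap
  at10 <- which.min(abs(pa$freqs - 10))
  expect_lt(pa$power[at10], 1e-3 * pa$peak_power)
  expect_error(psd_theta_peak(lfp, data.frame(t_start_s = 0, t_end_s = 2)),
               "at least 8 s")
})

test_that("wavelet spectrogram localizes tones in frequency", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  lfp1 <- structure(list(values = sin(2 * pi * 7.3 * t), fs = fs,
                         zscored = FALSE), class = "lfp_trace")
  sp <- wavelet_spectrogram(lfp1, decimate = 5L)
  expect_equal(sp$peak_hz, sp$freqs[which.min(abs(sp$freqs - 7.3))])
  # two tones give two local maxima at the nearest grid frequencies
  lfp2 <- structure(list(values = sin(2 * pi * 6.3 * t) +
                           sin(2 * pi * 20 * t),
                         fs = fs, zscored = FALSE), class = "lfp_trace")
  sp2 <- wavelet_spectrogram(lfp2, decimate = 5L)
  mp <- sp2$mean_power
  locmax <- which(diff(sign(diff(mp))) == -2) + 1
  peaks <- sp2$freqs[locmax[order(mp[locmax], decreasing = TRUE)][1:2]]
  expect_equal(sort(peaks),
               sort(c(sp2$freqs[which.min(abs(sp2$freqs - 6.3))],
                      sp2$freqs[which.min(abs(sp2$freqs - 20))])))
  expect_error(wavelet_spectrogram(lfp1, freqs = c(10, 400)), "Nyquist")
})
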