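#' Immobility segmentation from treadmill speed
#'
#' Maximal runs of the 0.1-s speed series with speed at most
#' `max_speed_cm_s` lasting at least `min_dur_s`. Only treadmill speed is
#' used (body rotation is allowed during immobility).
#'
#' @param speed_cm_s Speed on the uniform 0.1-s grid (cm/s).
#' @param min_dur_s Minimum run duration (s); default 8.
#' @param max_speed_cm_s Speed ceiling (cm/s); default 1.
#' @param dt Sample interval (s).
#' @return Data frame with `t_start_s`, `t_end_s`, `duration_s`; disjoint
#'   and sorted (possibly empty).
#' @export
segment_immobility <- function(speed_cm_s, min_dur_s = 8, max_speed_cm_s = 1,
                               dt = 0.1) {
  still <- speed_cm_s <= max_speed_cm_s
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * dt >= min_dur_s
  data.frame(t_start_s = (starts[keep] - 1L) * dt,
             t_end_s = ends[keep] * dt,
             duration_s = r$lengths[keep] * dt)
}

# Welch power spectral density with Hann windows. Segment-aware: windows
# are placed only fully inside each analysis interval, so no window ever
# spans a gap between segments.
welch_psd <- function(values, fs, intervals = NULL, window_s = 4,
                      overlap = 0.5) {
  nwin <- as.integer(round(window_s * fs))
  if (is.null(intervals))
    intervals <- data.frame(t_start_s = 0, t_end_s = length(values) / fs)
  hop <- max(1L, as.integer(round(nwin * (1 - overlap))))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  norm <- fs * sum(w^2)
  acc <- NULL
  n_seg <- 0L
  for (k in seq_len(nrow(intervals))) {
    i0 <- as.integer(floor(intervals$t_start_s[k] * fs)) + 1L
    i1 <- min(length(values), as.integer(floor(intervals$t_end_s[k] * fs)))
    s <- i0
    while (s + nwin - 1L <= i1) {
      x <- values[s:(s + nwin - 1L)]
      x <- (x - mean(x)) * w
      px <- Mod(stats::fft(x))^2 / norm
      acc <- if (is.null(acc)) px else acc + px
      n_seg <- n_seg + 1L
      s <- s + hop
    }
  }
  if (n_seg == 0L) stop("segments too short for one Welch window")
  p <- acc / n_seg
  half <- seq_len(nwin %/% 2 + 1L)
  p_one <- p[half]
  if (nwin %% 2 == 0) p_one[2:(length(half) - 1L)] <-
      2 * p_one[2:(length(half) - 1L)] else
        p_one[-1] <- 2 * p_one[-1]
  list(freqs = (half - 1L) * fs / nwin, power = p_one, n_windows = n_seg)
}

#' Theta-band PSD peak over analysis segments
#'
#' Z-scores the LFP trace (for pooling across sessions), computes a
#' segment-aware Welch PSD (4-s Hann windows, 50% overlap, 0.25-Hz
#' resolution; no window spans a segment gap), and reports the power peak
#' within the analysis band. A peak-prominence flag marks spectra whose
#' in-band peak barely exceeds the in-band median (flat spectra).
#'
#' @param lfp An `lfp_trace` (see [simulate_lfp()]).
#' @param intervals Data frame of analysis segments (`t_start_s`,
#'   `t_end_s`), e.g. from [segment_immobility()]; `NULL` uses the whole
#'   trace.
#' @param band Analysis band (Hz), default c(5, 12).
#' @param zscore_first Z-score the trace before the PSD (default TRUE).
#' @param window_s Welch window (s); sets the frequency resolution
#'   `1 / window_s`.
#' @return Object of class `spectral_result`: `freqs`, `power`, `band`,
#'   `peak_hz`, `peak_power`, `low_prominence` flag, `n_windows`.
#' @export
psd_theta_peak <- function(lfp, intervals = NULL, band = c(5, 12),
                           zscore_first = TRUE, window_s = 4) {
  stopifnot(inherits(lfp, "lfp_trace"))
  if (!is.null(intervals) && nrow(intervals) &&
      sum(intervals$t_end_s - intervals$t_start_s) < 8)
    stop("total segment duration must be at least 8 s")
  v <- lfp$values
  if (zscore_first) v <- (v - mean(v)) / stats::sd(v)
  ps <- welch_psd(v, lfp$fs, intervals, window_s = window_s)
  in_band <- ps$freqs >= band[1] & ps$freqs <= band[2]
  if (!any(in_band)) stop("no PSD frequencies inside band")
  bi <- which(in_band)
  pk <- bi[which.max(ps$power[bi])]
  # prominence against a smooth 1/f^a background fitted in log-log space,
  # so a sloped broadband spectrum does not masquerade as a peak
  lx <- log(ps$freqs[bi])
  ly <- log(pmax(ps$power[bi], .Machine$double.xmin))
  trend <- stats::lm.fit(cbind(1, lx), ly)$coefficients
  prom <- ps$power[pk] / exp(trend[1] + trend[2] * log(ps$freqs[pk]))
  structure(list(freqs = ps$freqs, power = ps$power, band = band,
                 peak_hz = ps$freqs[pk], peak_power = ps$power[pk],
                 prominence_ratio = prom, low_prominence = prom < 2,
                 n_windows = ps$n_windows, method = "welch-hann"),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf(
    "<spectral_result:%s> peak %.2f Hz in [%g, %g] Hz (%d windows)%s\n",
    x$method, x$peak_hz, x$band[1], x$band[2], x$n_windows,
    if (isTRUE(x$low_prominence)) " [low prominence]" else ""))
  invisible(x)
}

#' @export
plot.spectral_result <- function(x, ...) {
  sel <- x$freqs > 0 & x$freqs <= 4 * x$band[2]
  graphics::plot(x$freqs[sel], x$power[sel], type = "l",
                 xlab = "frequency (Hz)", ylab = "PSD (a.u.)", ...)
  graphics::abline(v = x$peak_hz, col = "red", lty = 2)
  invisible(x)
}

#' Morlet continuous-wavelet spectrogram
#'
#' Complex Morlet transform (width parameter `wavelet_width` cycles)
#' evaluated by FFT convolution at each analysis frequency; power is the
#' squared magnitude. The default frequency grid is log-spaced from 2 to
#' 50 Hz.
#'
#' @param lfp An `lfp_trace`.
#' @param freqs Analysis frequencies (Hz); all must be below Nyquist.
#' @param wavelet_width Morlet width (cycles), default 7.
#' @param decimate Keep every `decimate`-th time sample of the power
#'   matrix.
#' @return Object of class `spectral_result` with `power` a time x
#'   frequency matrix, `freqs`, `times_s`, and `peak_hz` the argmax of the
#'   time-averaged power.
#' @export
wavelet_spectrogram <- function(lfp, freqs = NULL, wavelet_width = 7,
                                decimate = 1L) {
  stopifnot(inherits(lfp, "lfp_trace"))
  if (is.null(freqs)) freqs <- exp(seq(log(2), log(50), length.out = 30))
  if (max(freqs) >= lfp$fs / 2) stop("frequency above Nyquist")
  n <- length(lfp$values)
  xf <- stats::fft(lfp$values)
  keep_t <- seq.int(1L, n, by = as.integer(decimate))
  power <- matrix(NA_real_, length(keep_t), length(freqs))
  # frequency axis of the length-n DFT
  f_ax <- (seq_len(n) - 1L) / n * lfp$fs
  f_ax[f_ax > lfp$fs / 2] <- f_ax[f_ax > lfp$fs / 2] - lfp$fs
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    sigma_f <- f0 / wavelet_width
    # Morlet in the frequency domain: Gaussian around f0 (analytic signal)
    wf <- exp(-(f_ax - f0)^2 / (2 * sigma_f^2)) * (f_ax > 0) * 2
    conv <- stats::fft(xf * wf, inverse = TRUE) / n
    power[, j] <- Mod(conv[keep_t])^2
  }
  mean_p <- colMeans(power)
  structure(list(freqs = freqs, times_s = (keep_t - 1L) / lfp$fs,
                 power = power, band = range(freqs),
                 peak_hz = freqs[which.max(mean_p)],
                 mean_power = mean_p, method = "morlet-cwt"),
            class = "spectral_result")
}
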