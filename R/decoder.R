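#' Decoder configuration
#'
#' The decoder consumes the binned spike counts from the most recent
#' `window_s` seconds (1.5 or 5 s by default convention) at `bin_s`-wide
#' bins and outputs a position estimate every `output_interval_s` (fixed at
#' 0.1 s). The window is summarized as per-unit mean firing rates over a
#' small set of nested trailing sub-windows (`feature_windows`), so the
#' regressor sees both the recent, position-specific activity and the
#' longer, noise-averaged history. The regressor is a multilayer perceptron
#' (ReLU hidden layers, linear output, Adam/MSE) trained with data
#' augmentation (see [augmentation_config()]) to make it robust to
#' corrupted inputs.
#'
#' @param window_s History length (s); integer multiple of `bin_s`.
#' @param bin_s Decoder bin width (s).
#' @param feature_windows Trailing sub-window lengths (s) summarized per
#'   unit; values are capped at `window_s`. Default `c(0.5, 1.5, window_s)`.
#' @param augmentation An [augmentation_config()].
#' @param model List of regressor hyperparameters: `hidden` (integer vector
#'   of hidden-layer widths), `epochs`, `batch`, `lr` (Adam learning rate),
#'   `l2` (weight decay).
#' @param train_fraction Fraction of windows (leading contiguous block) used
#'   for training; the rest is the validation block.
#' @param train_stride_s Spacing of training windows (s); consecutive 0.1-s
#'   windows are nearly redundant, so training subsamples them.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(window_s = 5, bin_s = 0.1, feature_windows = NULL,
                           augmentation = augmentation_config(),
                           model = list(hidden = c(192, 192), epochs = 100,
                                        batch = 128, lr = 1e-3, l2 = 1e-4),
                           train_fraction = 0.8, train_stride_s = 0.5) {
  nb <- window_s / bin_s
  if (abs(nb - round(nb)) > 1e-9) stop("window_s must be a multiple of bin_s")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (is.null(feature_windows)) feature_windows <- c(0.5, 1.5, window_s)
  feature_windows <- sort(unique(pmin(feature_windows, window_s)))
  fb <- feature_windows / bin_s
  if (any(abs(fb - round(fb)) > 1e-9) || any(fb < 1))
    stop("feature_windows must be positive multiples of bin_s")
  structure(list(window_s = window_s, bin_s = bin_s, output_interval_s = 0.1,
                 feature_windows = feature_windows,
                 augmentation = augmentation, model = model,
                 train_fraction = train_fraction,
                 train_stride_s = train_stride_s),
            class = "decoder_config")
}

#' Training-data augmentation configuration
#'
#' Each augmented copy of a count window applies, in order: unit dropout
#' (each unit's row zeroed with probability `unit_dropout_p`),
#' multiplicative rate jitter (each row scaled by `max(0, 1 + e)`,
#' `e ~ Normal(0, count_noise_scale)`), and a circular time shift of the
#' window contents by up to `time_jitter_bins` bins.
#'
#' @param unit_dropout_p Per-unit dropout probability in \[0, 1).
#' @param count_noise_scale SD of the multiplicative jitter (>= 0).
#' @param time_jitter_bins Maximum circular shift (bins).
#' @param n_augmented_copies Augmented copies added per real training
#'   window (>= 0; 0 disables augmentation).
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(unit_dropout_p = 0.4, count_noise_scale = 0.5,
                                time_jitter_bins = 2, n_augmented_copies = 3) {
  if (unit_dropout_p < 0 || unit_dropout_p >= 1)
    stop("unit_dropout_p must be in [0, 1)")
  if (count_noise_scale < 0) stop("count_noise_scale must be >= 0")
  if (n_augmented_copies < 0) stop("n_augmented_copies must be >= 0")
  structure(list(unit_dropout_p = unit_dropout_p,
                 count_noise_scale = count_noise_scale,
                 time_jitter_bins = as.integer(time_jitter_bins),
                 n_augmented_copies = as.integer(n_augmented_copies)),
            class = "augmentation_config")
}

#' Build training windows and position targets from a session
#'
#' One window per 0.1-s step whose trailing edge `t_end` is at least
#' `window_s` after session start; the target is the trajectory position at
#' `t_end` (the current location — no look-ahead). Windows are stored
#' compactly (the rebinned raster plus window end indices); use
#' [get_window()] to materialize one window's counts matrix.
#'
#' @param raster A [spike_raster()].
#' @param trajectory Trajectory data frame covering the same interval.
#' @param config A [decoder_config()].
#' @return An object of class `count_windows` with `end_bins`, `targets`
#'   (n x 2, cm), the rebinned counts and the config; zero windows (with a
#'   warning) if the session is shorter than `window_s`.
#' @export
make_training_windows <- function(raster, trajectory, config = decoder_config()) {
  stopifnot(inherits(raster, "spike_raster"))
  r <- bin_counts(raster, config$bin_s)
  n_t <- min(n_bins(r), nrow(trajectory))
  wb <- as.integer(round(config$window_s / config$bin_s))
  if (n_t < wb) {
    warning("session shorter than window_s; no windows")
    end_bins <- integer(0)
  } else end_bins <- seq.int(wb, n_t)
  targets <- cbind(x_cm = trajectory$x_cm, y_cm = trajectory$y_cm)[end_bins, ,
                                                                  drop = FALSE]
  structure(list(counts = r$counts[, seq_len(n_t), drop = FALSE],
                 bin_s = config$bin_s, window_bins = wb,
                 end_bins = end_bins, targets = targets,
                 unit_ids = r$unit_ids, config = config),
            class = "count_windows")
}

#' @export
print.count_windows <- function(x, ...) {
  cat(sprintf("<count_windows> %d windows of %d units x %d bins (%g s @ %g s)\n",
              length(x$end_bins), length(x$unit_ids), x$window_bins,
              x$config$window_s, x$bin_s))
  invisible(x)
}

#' Materialize one count window
#'
#' @param windows A [make_training_windows()] object.
#' @param i Window index.
#' @return Units x window-bins matrix of counts, with attribute `t_end`.
#' @export
get_window <- function(windows, i) {
  e <- windows$end_bins[i]
  m <- windows$counts[, (e - windows$window_bins + 1L):e, drop = FALSE]
  attr(m, "t_end") <- e * windows$bin_s
  m
}

#' Apply augmentation to a single count window
#'
#' @param window Units x bins count matrix.
#' @param aug An [augmentation_config()].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Augmented window (nonnegative real matrix).
#' @export
augment_window <- function(window, aug, seed = 1L) {
  stopifnot(inherits(aug, "augmentation_config"))
  with_seed(seed, {
    out <- window
    n_u <- nrow(out)
    if (aug$unit_dropout_p > 0) {
      drop <- stats::runif(n_u) < aug$unit_dropout_p
      out[drop, ] <- 0
    }
    if (aug$count_noise_scale > 0) {
      fac <- pmax(0, 1 + stats::rnorm(n_u, 0, aug$count_noise_scale))
      out <- out * fac
    }
    if (aug$time_jitter_bins > 0) {
      s <- sample.int(2L * aug$time_jitter_bins + 1L, 1L) -
        aug$time_jitter_bins - 1L
      if (s != 0) {
        nb <- ncol(out)
        idx <- ((seq_len(nb) - 1L - s) %% nb) + 1L
        out <- out[, idx, drop = FALSE]
      }
    }
    out
  })
}

# Multi-scale window features: per-unit mean rate (Hz) over each trailing
# sub-window in config$feature_windows, concatenated in ascending scale
# order. Returns windows x (units * n_scales) matrix aligned with end_bins.
window_features <- function(counts, end_bins, config) {
  tc <- t(counts)
  blocks <- lapply(config$feature_windows, function(w) {
    k <- as.integer(round(w / config$bin_s))
    f <- rolling_row_sums(tc, k) / w
    # rolling_row_sums rows correspond to end bins k..nrow(tc)
    f[end_bins - k + 1L, , drop = FALSE]
  })
  do.call(cbind, blocks)
}

# Features for the latest tick of an incrementally grown units x ticks
# per-tick count matrix (closed-loop path); identical ordering to
# window_features.
tick_features <- function(tick_counts, tick, config) {
  out <- lapply(config$feature_windows, function(w) {
    k <- as.integer(round(w / config$output_interval_s))
    i0 <- max(1L, tick - k + 1L)
    rowSums(tick_counts[, i0:tick, drop = FALSE]) / w
  })
  matrix(unlist(out), nrow = 1L)
}

# Feature-level augmentation equivalent to augment_window for window-mean
# features (dropout zeroes a unit; jitter scales it; a circular shift leaves
# the window mean unchanged). One independent draw per window and unit,
# applied jointly to all of that unit's scale blocks.
augment_features <- function(feat, aug, n_units) {
  n_scales <- ncol(feat) / n_units
  nw <- nrow(feat)
  if (aug$unit_dropout_p > 0) {
    drop <- matrix(stats::runif(nw * n_units) < aug$unit_dropout_p, nw)
    feat[rep(drop, n_scales)] <- 0
  }
  if (aug$count_noise_scale > 0) {
    fac <- matrix(pmax(0, 1 + stats::rnorm(nw * n_units, 0,
                                           aug$count_noise_scale)), nw)
    feat <- feat * do.call(cbind, rep(list(fac), n_scales))
  }
  feat
}

#' Train the position decoder
#'
#' Fits a single-hidden-layer perceptron mapping per-unit window-mean firing
#' rates to 2-D position. Windows are split into contiguous training and
#' validation blocks (no random shuffling, avoiding temporal leakage);
#' training windows are subsampled at `train_stride_s` and expanded with
#' `n_augmented_copies` augmented copies; validation uses every window,
#' unaugmented. Per-coordinate validation R-squared and the median Euclidean
#' decoding error are stored on the fitted object.
#'
#' @param windows A [make_training_windows()] object (or a feature matrix,
#'   in which case `targets` must be given).
#' @param targets Optional n x 2 target positions (cm) when `windows` is a
#'   plain feature matrix.
#' @param config A [decoder_config()]; defaults to the config embedded in
#'   `windows`.
#' @param arena An [arena_spec()] used to clip decoded output.
#' @param seed Integer seed (network initialization and augmentation).
#' @return An object of class `place_decoder`.
#' @seealso [decode_stream()], [predict.place_decoder()]
#' @export
train_decoder <- function(windows, targets = NULL, config = NULL,
                          arena = arena_spec(), seed = 1L) {
  if (inherits(windows, "count_windows")) {
    if (is.null(config)) config <- windows$config
    feats <- window_features(windows$counts, windows$end_bins, config)
    targets <- windows$targets
    unit_ids <- windows$unit_ids
    n_units <- length(unit_ids)
  } else {
    if (is.null(targets)) stop("targets required with a feature matrix")
    if (is.null(config)) config <- decoder_config()
    feats <- as.matrix(windows)
    n_units <- ncol(feats) / length(config$feature_windows)
    unit_ids <- sprintf("u%03d", seq_len(n_units))
  }
  n <- nrow(feats)
  if (n < 100) stop("need at least 100 windows to train")
  targets <- as_xy_matrix(targets)
  if (any(!is.finite(targets))) stop("targets must be finite")
  if (stats::sd(targets[, 1]) == 0 && stats::sd(targets[, 2]) == 0)
    stop("degenerate targets: no positional variance")
  n_train <- floor(config$train_fraction * n)
  stride <- max(1L, as.integer(round(config$train_stride_s /
                                       config$output_interval_s)))
  tr_idx <- seq.int(1L, n_train, by = stride)
  va_idx <- seq.int(n_train + 1L, n)
  aug <- config$augmentation
  with_seed(seed, {
    x_tr <- feats[tr_idx, , drop = FALSE]
    y_tr <- targets[tr_idx, , drop = FALSE]
    if (aug$n_augmented_copies > 0) {
      for (k in seq_len(aug$n_augmented_copies)) {
        x_tr <- rbind(x_tr, augment_features(feats[tr_idx, , drop = FALSE],
                                             aug, n_units))
        y_tr <- rbind(y_tr, targets[tr_idx, , drop = FALSE])
      }
    }
    ctr <- colMeans(x_tr)
    scl <- pmax(apply(x_tr, 2, stats::sd), 1e-6)
    xs <- sweep(sweep(x_tr, 2, ctr), 2, scl, "/")
    ys <- y_tr / arena$side_cm
    ms <- config$model
    fit <- mlp_fit_cpp(xs, ys, as.integer(ms$hidden), as.integer(ms$epochs),
                       as.integer(ms$batch), ms$lr, ms$l2,
                       sample.int(.Machine$integer.max, 1))
    model <- structure(
      list(fit = fit, config = config, arena = arena, unit_ids = unit_ids,
           feat_center = ctr, feat_scale = scl, n_train = nrow(xs),
           seed = as.integer(seed)),
      class = "place_decoder")
    pred_va <- predict_features(model, feats[va_idx, , drop = FALSE])
    metrics <- r2_score(pred_va, targets[va_idx, , drop = FALSE])
    model$validation_r2 <- metrics$r2
    model$validation_median_error_cm <- metrics$median_error_cm
    model$validation_pred <- pred_va
    model$validation_targets <- targets[va_idx, , drop = FALSE]
    model
  })
}

# Decode a windows x features matrix to clipped positions (cm).
predict_features <- function(model, feats) {
  xs <- sweep(sweep(as.matrix(feats), 2, model$feat_center), 2,
              model$feat_scale, "/")
  p <- mlp_predict_cpp(model$fit, xs) * model$arena$side_cm
  p <- clip_to_arena(model$arena, p)
  colnames(p) <- c("x_cm", "y_cm")
  p
}

#' @export
print.place_decoder <- function(x, ...) {
  cat(sprintf(
    "<place_decoder> %d units, %g-s window; validation R2 = %.3f (x), %.3f (y); median error %.1f cm\n",
    length(x$unit_ids), x$config$window_s, x$validation_r2[1],
    x$validation_r2[2], x$validation_median_error_cm))
  invisible(x)
}

#' @export
summary.place_decoder <- function(object, ...) {
  out <- list(n_units = length(object$unit_ids),
              window_s = object$config$window_s,
              hidden = object$config$model$hidden,
              n_train_windows = object$n_train,
              validation_r2 = object$validation_r2,
              validation_median_error_cm = object$validation_median_error_cm)
  class(out) <- "summary.place_decoder"
  out
}

#' @export
print.summary.place_decoder <- function(x, ...) {
  cat("Place decoder (multi-scale window-rate MLP)\n")
  cat(sprintf("  units: %d   window: %g s   hidden: %s   trained on %d windows\n",
              x$n_units, x$window_s, paste(x$hidden, collapse = "-"),
              x$n_train_windows))
  cat(sprintf("  validation R2: x = %.3f, y = %.3f (mean %.3f)\n",
              x$validation_r2[1], x$validation_r2[2], mean(x$validation_r2)))
  cat(sprintf("  validation median decoding error: %.2f cm\n",
              x$validation_median_error_cm))
  invisible(x)
}

#' Predict positions from count windows, features, or a spike raster
#'
#' @param object A [train_decoder()] model.
#' @param newdata A [spike_raster()] (streamed decode), a `count_windows`
#'   object, or a windows x units feature matrix of window-mean rates (Hz).
#' @param ... Unused.
#' @return For a raster, the [decode_stream()] data frame; otherwise an
#'   n x 2 matrix of positions (cm).
#' @export
predict.place_decoder <- function(object, newdata, ...) {
  if (inherits(newdata, "spike_raster")) return(decode_stream(object, newdata))
  if (inherits(newdata, "count_windows")) {
    feats <- window_features(newdata$counts, newdata$end_bins, object$config)
    return(predict_features(object, feats))
  }
  predict_features(object, newdata)
}

#' @export
residuals.place_decoder <- function(object, ...) {
  object$validation_targets - object$validation_pred
}

#' @export
plot.place_decoder <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (k in 1:2) {
    graphics::plot(x$validation_targets[, k], x$validation_pred[, k],
                   pch = 16, cex = 0.3, col = grDevices::rgb(0, 0, 0, 0.3),
                   xlab = sprintf("actual %s (cm)", c("x", "y")[k]),
                   ylab = sprintf("decoded %s (cm)", c("x", "y")[k]),
                   main = sprintf("R2 = %.3f", x$validation_r2[k]), ...)
    graphics::abline(0, 1, col = "red")
  }
  invisible(x)
}

#' Decode a spike raster as a 100-ms stream
#'
#' Produces one clipped position estimate per 0.1-s step once a full
#' `window_s` of history exists. The raster's unit set must match the
#' model's exactly (same identities, same order); mismatches are an error,
#' never silently reindexed.
#'
#' @param model A [train_decoder()] model.
#' @param raster A [spike_raster()].
#' @return Data frame with `t_s` (window trailing edge), `x_cm`, `y_cm`.
#' @export
decode_stream <- function(model, raster) {
  stopifnot(inherits(model, "place_decoder"), inherits(raster, "spike_raster"))
  if (!identical(raster$unit_ids, model$unit_ids))
    stop("raster unit set does not match the model's unit_ids")
  cfg <- model$config
  r <- bin_counts(raster, cfg$bin_s)
  wb <- as.integer(round(cfg$window_s / cfg$bin_s))
  if (n_bins(r) < wb) stop("raster shorter than one decoder window")
  end_bins <- seq.int(wb, n_bins(r))
  feats <- window_features(r$counts, end_bins, cfg)
  p <- predict_features(model, feats)
  data.frame(t_s = end_bins * cfg$bin_s, x_cm = p[, 1], y_cm = p[, 2])
}

#' Coefficient of determination for decoded positions
#'
#' Standard per-coordinate R-squared, `1 - SS_res / SS_tot`, plus the median
#' Euclidean decoding error.
#'
#' @param predicted,actual n x 2 position matrices (cm), n >= 2.
#' @return List with `r2` (named per-coordinate), `mean_r2`,
#'   `median_error_cm`.
#' @export
r2_score <- function(predicted, actual) {
  predicted <- as_xy_matrix(predicted)
  actual <- as_xy_matrix(actual)
  if (nrow(predicted) != nrow(actual) || nrow(actual) < 2)
    stop("predicted and actual must have equal length >= 2")
  r2 <- vapply(1:2, function(k) {
    ss_tot <- sum((actual[, k] - mean(actual[, k]))^2)
    if (ss_tot == 0) stop("actual positions have zero variance")
    1 - sum((actual[, k] - predicted[, k])^2) / ss_tot
  }, numeric(1))
  names(r2) <- c("x", "y")
  list(r2 = r2, mean_r2 = mean(r2),
       median_error_cm = stats::median(dist_xy(predicted, actual)))
}

#' Serialize a trained decoder to a single file
#'
#' @param model A [train_decoder()] model.
#' @param path File path.
#' @export
write_decoder <- function(model, path) {
  stopifnot(inherits(model, "place_decoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "place_decoder")) stop("file does not contain a place_decoder")
  m
}
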