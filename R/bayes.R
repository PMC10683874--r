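#' Poisson Bayesian MAP position decoding
#'
#' The standard memoryless Poisson decoder over the arena's spatial bins:
#' with per-unit window spike totals `n_i`, window length `tau` (s) and
#' place-field rates `f_i(x)` from the rPV map,
#' `P(x | n) \propto P(x) * prod_i f_i(x)^{n_i} * exp(-tau * sum_i f_i(x))`.
#' The posterior is computed in log space and normalized to sum to 1 over
#' unmasked bins; rates are floored at `rate_floor` to avoid `log(0)`. The
#' MAP estimate is the center of the argmax bin, with ties broken by the
#' lowest (row-major) bin index.
#'
#' @param rpv_map A [compute_rpv_map()] object.
#' @param counts Per-unit spike totals over the window (vector), or a
#'   units x bins count-window matrix (its row sums are used).
#' @param window_s Window length `tau` (s).
#' @param prior Optional per-bin prior over all bins (only unmasked mass is
#'   used; renormalized). Default uniform over unmasked bins.
#' @param rate_floor Minimum rate (Hz) substituted into the likelihood.
#' @return List with `posterior` (full-length vector, `NA` at masked bins,
#'   summing to 1 over unmasked bins), `map_bin`, `map_xy` (bin center, cm).
#' @export
bayesian_map_decode <- function(rpv_map, counts, window_s, prior = NULL,
                                rate_floor = 0.01) {
  stopifnot(inherits(rpv_map, "place_field_map"))
  if (is.matrix(counts)) counts <- rowSums(counts)
  if (length(counts) != nrow(rpv_map$rates))
    stop("counts length does not match the map's unit count")
  if (any(!is.finite(rpv_map$rates[, rpv_map$mask])))
    stop("NaN in rPV rates")
  ok <- which(rpv_map$mask)
  if (!length(ok)) stop("all bins masked")
  f <- pmax(rpv_map$rates[, ok, drop = FALSE], rate_floor)
  lp <- as.numeric(counts %*% log(f)) - window_s * colSums(f)
  if (!is.null(prior)) {
    pr <- prior[ok]
    if (any(pr < 0) || sum(pr) <= 0) stop("invalid prior")
    lp <- lp + log(pr / sum(pr))
  }
  post_ok <- exp(lp - logsumexp(lp))
  posterior <- rep(NA_real_, ncol(rpv_map$rates))
  posterior[ok] <- post_ok
  map_bin <- ok[which.max(post_ok)]
  list(posterior = posterior, map_bin = map_bin,
       map_xy = bin_centers(rpv_map$arena)[map_bin, ])
}

#' Decoder robustness to corrupted rPV probe inputs
#'
#' For every unmasked spatial bin, builds probe windows whose expected
#' counts equal that bin's rPV times the bin width (Poisson draws over a
#' full decoder window), corrupts them with unit dropout (probability =
#' noise level) plus multiplicative rate jitter (SD = noise level), and
#' decodes the same corrupted probe with both the trained regressor and the
#' Bayesian MAP decoder. Reported error is the distance from the probed
#' bin's center, averaged over bins and repeats.
#'
#' @param model A [train_decoder()] model.
#' @param rpv_map A [compute_rpv_map()] object sharing the model's units.
#' @param noise_levels Nonnegative corruption levels (0 = clean probes).
#' @param n_repeats Probe draws per bin and level.
#' @param seed Integer seed.
#' @return Data frame: `noise_level`, `decoder` ("regressor"/"bayesian"),
#'   `mean_error_cm`, `n_probes`.
#' @export
noise_robustness_curve <- function(model, rpv_map,
                                   noise_levels = c(0, 0.25, 0.5, 0.75),
                                   n_repeats = 3, seed = 1L) {
  stopifnot(inherits(model, "place_decoder"),
            inherits(rpv_map, "place_field_map"))
  if (!identical(model$unit_ids, rpv_map$unit_ids))
    stop("model and map unit sets differ")
  if (any(noise_levels < 0)) stop("noise levels must be >= 0")
  ok <- which(rpv_map$mask)
  ctr <- bin_centers(rpv_map$arena)
  cfg <- model$config
  wb <- as.integer(round(cfg$window_s / cfg$bin_s))
  n_u <- length(model$unit_ids)
  f_ok <- pmax(rpv_map$rates[, ok, drop = FALSE], 0.01)
  log_f <- log(f_ok)
  tau <- max(cfg$feature_windows)   # accumulation window of the totals
  neg_tau_f <- -tau * colSums(f_ok)
  with_seed(seed, {
    res <- list()
    fw <- cfg$feature_windows
    fw_bins <- as.integer(round(fw / cfg$bin_s))
    for (lv in noise_levels) {
      n_probe <- length(ok) * n_repeats
      probe_bin <- rep(ok, times = n_repeats)
      # per-bin Poisson draws over a full window, accumulated into each
      # trailing sub-window so probe features match the training features
      lam <- t(rpv_map$rates[, probe_bin, drop = FALSE]) * cfg$bin_s
      accs <- rep(list(matrix(0, n_probe, n_u)), length(fw))
      for (b in seq_len(wb)) {
        m <- matrix(stats::rpois(length(lam), lam), n_probe)
        for (j in seq_along(fw))
          if (b > wb - fw_bins[j]) accs[[j]] <- accs[[j]] + m
      }
      corrupt <- if (lv > 0) {
        matrix(stats::runif(n_probe * n_u) >= lv, n_probe) *
          matrix(pmax(0, 1 + stats::rnorm(n_probe * n_u, 0, lv)), n_probe)
      } else NULL
      if (!is.null(corrupt))
        accs <- lapply(accs, function(a) a * corrupt)
      totals <- accs[[length(fw)]]
      true_xy <- ctr[probe_bin, , drop = FALSE]
      feats <- do.call(cbind, lapply(seq_along(fw),
                                     function(j) accs[[j]] / fw[j]))
      pred_r <- predict_features(model, feats)
      err_r <- mean(dist_xy(pred_r, true_xy))
      # Bayesian MAP, vectorized across probes
      lp <- totals %*% log_f
      lp <- sweep(lp, 2, neg_tau_f, "+")
      map_bin <- ok[max.col(lp, ties.method = "first")]
      err_b <- mean(dist_xy(ctr[map_bin, , drop = FALSE], true_xy))
      res[[length(res) + 1L]] <- data.frame(
        noise_level = lv, decoder = c("regressor", "bayesian"),
        mean_error_cm = c(err_r, err_b), n_probes = n_probe)
    }
    do.call(rbind, res)
  })
}
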