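#' Occupancy-normalized place-field map (reference population vectors)
#'
#' For every unit and spatial bin, divides the spikes emitted while the
#' animal occupied that bin by the time spent there, giving the per-bin mean
#' firing rate. The column of rates at one bin is that location's reference
#' population vector (rPV); the full matrix is the standard place-field map.
#' Bins occupied for less than `occupancy_min_s` are masked and excluded from
#' all downstream statistics. Gaussian spatial smoothing is applied to the
#' rate ratio after masking (mask-aware normalized convolution); the
#' unsmoothed rates are retained, for which
#' `rowSums(rates_raw * occupancy) == total spikes per unit` holds exactly.
#'
#' @param raster A [spike_raster()] covering the session.
#' @param trajectory Trajectory data frame on the 0.1-s grid.
#' @param arena An [arena_spec()].
#' @param occupancy_min_s Mask threshold (s).
#' @param smoothing_sigma_cm Gaussian smoothing width (cm); 0 disables.
#' @return An object of class `place_field_map` with fields `rates`
#'   (units x bins, smoothed, Hz), `rates_raw`, `occupancy` (s), `mask`
#'   (logical, TRUE = usable bin), `mean_rates` (unit session means, Hz),
#'   `arena`, `unit_ids`.
#' @export
compute_rpv_map <- function(raster, trajectory, arena, occupancy_min_s = 0.5,
                            smoothing_sigma_cm = 5) {
  stopifnot(inherits(raster, "spike_raster"), inherits(arena, "arena_spec"))
  dt <- 0.1
  r100 <- bin_counts(raster, dt)
  n_t <- min(n_bins(r100), nrow(trajectory))
  if (n_t < 1) stop("empty session")
  occ_idx <- xy_to_bin(arena, cbind(trajectory$x_cm, trajectory$y_cm)[seq_len(n_t), ,
                                                                     drop = FALSE])
  occupancy <- numeric(arena$n_bins)
  tab <- tabulate(occ_idx, nbins = arena$n_bins)
  occupancy <- tab * dt
  if (sum(occupancy) <= 0) stop("zero total occupancy")
  # spikes per unit per spatial bin
  spk <- rowsum(t(r100$counts[, seq_len(n_t), drop = FALSE]), occ_idx)
  counts_bin <- matrix(0, nrow = nrow(raster$counts), ncol = arena$n_bins,
                       dimnames = list(raster$unit_ids, NULL))
  counts_bin[, as.integer(rownames(spk))] <- t(spk)
  mask <- occupancy >= occupancy_min_s
  rates_raw <- sweep(counts_bin, 2, pmax(occupancy, .Machine$double.eps), "/")
  rates_raw[, !mask] <- NA_real_
  rates <- if (smoothing_sigma_cm > 0)
    smooth_map(rates_raw, mask, arena, smoothing_sigma_cm) else rates_raw
  duration <- n_t * dt
  structure(list(rates = rates, rates_raw = rates_raw, occupancy = occupancy,
                 mask = mask, mean_rates = rowSums(counts_bin) / duration,
                 occupancy_min_s = occupancy_min_s,
                 smoothing_sigma_cm = smoothing_sigma_cm,
                 duration_s = duration, arena = arena,
                 unit_ids = raster$unit_ids),
            class = "place_field_map")
}

# Mask-aware Gaussian smoothing of a units x bins rate matrix on the arena
# grid; masked bins contribute nothing and stay NA.
smooth_map <- function(rates, mask, arena, sigma_cm) {
  ns <- arena$n_side
  h <- arena$spatial_bin_cm
  half <- max(1L, ceiling(3 * sigma_cm / h))
  g <- stats::dnorm(seq(-half, half) * h, sd = sigma_cm)
  centers <- bin_centers(arena)
  out <- rates
  w_mask <- matrix(as.numeric(mask), nrow = ns, byrow = FALSE)
  # separable convolution per unit on the ns x ns grid
  conv1 <- function(m, g) {
    # convolve each column of m with g (same size, zero padding)
    nr <- nrow(m)
    res <- matrix(0, nr, ncol(m))
    for (k in seq_along(g)) {
      off <- k - half - 1L
      src <- seq_len(nr) + off
      ok <- src >= 1 & src <= nr
      res[ok, ] <- res[ok, ] + g[k] * m[src[ok], , drop = FALSE]
    }
    res
  }
  # grid layout: bin = (iy-1)*ns + ix, so matrix(v, ns, ns) has x down rows
  mgrid <- matrix(as.numeric(mask), ns, ns)
  wnorm <- conv1(t(conv1(mgrid, g)), g)        # smoothed mask weight
  for (u in seq_len(nrow(rates))) {
    v <- rates[u, ]
    v[!mask] <- 0
    vg <- matrix(v, ns, ns)
    sm <- conv1(t(conv1(vg, g)), g)
    res <- t(sm) / t(wnorm)
    res_v <- as.numeric(res)
    res_v[!mask] <- NA_real_
    out[u, ] <- res_v
  }
  out
}

#' @export
print.place_field_map <- function(x, ...) {
  cat(sprintf(
    "<place_field_map> %d units x %d bins; %d unmasked; %.1f min occupancy\n",
    nrow(x$rates), ncol(x$rates), sum(x$mask), sum(x$occupancy) / 60))
  invisible(x)
}

#' Reference population vector at a location
#'
#' Returns the (smoothed) rPV at the spatial bin containing `xy`; if that
#' bin is masked, substitutes the nearest unmasked bin with a warning.
#'
#' @param map A [compute_rpv_map()] object.
#' @param xy Position (cm).
#' @param warn Warn on nearest-bin substitution (default TRUE).
#' @return List with `rates` (per-unit Hz), `bin` (index used).
#' @export
rpv_at <- function(map, xy, warn = TRUE) {
  b <- xy_to_bin(map$arena, xy)
  if (!map$mask[b]) {
    ctr <- bin_centers(map$arena)
    cand <- which(map$mask)
    if (!length(cand)) stop("all bins masked")
    d <- dist_xy(ctr[cand, , drop = FALSE], as_xy_matrix(xy))
    b2 <- cand[which.min(d)]
    if (warn)
      warning(sprintf("bin %d is occupancy-masked; using nearest unmasked bin %d",
                      b, b2))
    b <- b2
  }
  list(rates = map$rates[, b], bin = b)
}

#' Population vector over a trailing window
#'
#' Per-unit firing rate (Hz) from counts in `(t_end - window_s, t_end]`.
#'
#' @param raster A [spike_raster()].
#' @param t_end Trailing edge of the window (s, relative to raster start).
#' @param window_s Window length (s), default 0.5.
#' @return Named per-unit rate vector (Hz).
#' @export
population_vector <- function(raster, t_end, window_s = 0.5) {
  stopifnot(inherits(raster, "spike_raster"))
  i_end <- round(t_end / raster$bin_s)
  i_start <- round((t_end - window_s) / raster$bin_s) + 1
  if (i_start < 1 || i_end > n_bins(raster))
    stop("window outside session")
  v <- rowSums(raster$counts[, i_start:i_end, drop = FALSE]) / window_s
  names(v) <- raster$unit_ids
  v
}

#' PV versus rPV correlation profile across integration windows
#'
#' At regularly spaced time points, correlates (across units, Pearson) the
#' population vector computed over each trailing integration window with the
#' rPV of the location attributed to that moment (the animal's actual
#' location in the Running task, or the decoded location in the BMI tasks),
#' and with rPVs of random unmasked locations as a baseline. Bootstrap 95%
#' confidence intervals are taken over time points.
#'
#' @param raster A [spike_raster()].
#' @param locations Data frame with `t_s`, `x_cm`, `y_cm` giving the
#'   location attributed to each 0.1-s step.
#' @param rpv_map A [compute_rpv_map()] object.
#' @param windows Integration windows (s).
#' @param step_s Spacing of evaluated time points (s).
#' @param near_goal_cm Optional: keep only time points whose location is
#'   within this distance of `goal`.
#' @param goal Goal position (cm), required with `near_goal_cm`.
#' @param n_random Random-location draws per time point (averaged).
#' @param n_boot Bootstrap resamples for the CIs.
#' @param seed Integer seed.
#' @return Data frame with one row per window: matched and random mean
#'   correlations with 95% CIs and the number of time points used.
#' @export
pv_rpv_correlation_profile <- function(raster, locations, rpv_map,
                                       windows = c(0.5, 1, 2, 5),
                                       step_s = 0.5, near_goal_cm = NULL,
                                       goal = NULL, n_random = 50,
                                       n_boot = 500, seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"), inherits(rpv_map, "place_field_map"))
  if (any(windows < 0.5 - 1e-9)) stop("integration windows must be >= 0.5 s")
  dur <- raster_duration(raster)
  ok_bins <- which(rpv_map$mask)
  if (length(ok_bins) < 2) stop("too few unmasked bins")
  keep_units <- apply(rpv_map$rates[, ok_bins, drop = FALSE], 1,
                      function(r) stats::sd(r, na.rm = TRUE) > 0)
  if (sum(keep_units) < 3) stop("fewer than 3 units with spatial rate variance")
  with_seed(seed, {
    rows <- lapply(windows, function(w) {
      t_eval <- seq(ceiling(max(windows) / step_s) * step_s, dur, by = step_s)
      loc_idx <- pmin(nrow(locations), pmax(1, round(t_eval / 0.1)))
      xy <- cbind(locations$x_cm, locations$y_cm)[loc_idx, , drop = FALSE]
      if (!is.null(near_goal_cm)) {
        if (is.null(goal)) stop("goal required with near_goal_cm")
        sel <- dist_xy(xy, goal) <= near_goal_cm
        t_eval <- t_eval[sel]
        xy <- xy[sel, , drop = FALSE]
      }
      if (!length(t_eval)) stop("no time points retained")
      m_cor <- r_cor <- rep(NA_real_, length(t_eval))
      for (i in seq_along(t_eval)) {
        pv <- population_vector(raster, t_eval[i], w)[keep_units]
        if (stats::sd(pv) == 0) next
        bin_m <- rpv_at(rpv_map, xy[i, ], warn = FALSE)$bin
        m_cor[i] <- stats::cor(pv, rpv_map$rates[keep_units, bin_m])
        rb <- sample(ok_bins, n_random, replace = TRUE)
        r_cor[i] <- mean(stats::cor(pv, rpv_map$rates[keep_units, rb,
                                                      drop = FALSE]),
                         na.rm = TRUE)
      }
      ok <- is.finite(m_cor) & is.finite(r_cor)
      m_cor <- m_cor[ok]; r_cor <- r_cor[ok]
      boot_ci <- function(v) {
        bm <- replicate(n_boot, mean(v[sample.int(length(v), replace = TRUE)]))
        stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      }
      ci_m <- boot_ci(m_cor); ci_r <- boot_ci(r_cor)
      data.frame(window_s = w, matched_mean = mean(m_cor),
                 matched_lo = ci_m[1], matched_hi = ci_m[2],
                 random_mean = mean(r_cor),
                 random_lo = ci_r[1], random_hi = ci_r[2],
                 n_timepoints = length(m_cor))
    })
    do.call(rbind, rows)
  })
}

#' Detect population burst events (PBEs)
#'
#' Sums counts across units on the base (10-ms) grid, Gaussian-smooths,
#' z-scores over the session, and extracts events whose peak reaches
#' `z_peak_min`, extended on both sides to where the trace falls to
#' `z_edge`. Events are kept when their duration lies in
#' `[min_dur_s, max_dur_s]` and their mean speed is at most
#' `max_speed_cm_s` (bursts are expected during immobility). Returned
#' intervals are disjoint and sorted.
#'
#' @param raster Base-bin [spike_raster()] (10 ms).
#' @param speed_cm_s Speed on the 0.1-s grid, aligned to the raster.
#' @param z_peak_min Peak z threshold.
#' @param z_edge Edge z threshold.
#' @param min_dur_s,max_dur_s Duration bounds (s).
#' @param max_speed_cm_s Immobility cap on the event-mean speed (cm/s);
#'   `Inf` disables.
#' @param smooth_sigma_s Gaussian smoothing SD (s).
#' @return Data frame of class `pbe_intervals`: `t_start_s`, `t_end_s`,
#'   `peak_z`, `mean_speed_cm_s`.
#' @export
detect_pbes <- function(raster, speed_cm_s = NULL, z_peak_min = 3, z_edge = 0,
                        min_dur_s = 0.05, max_dur_s = 0.5,
                        max_speed_cm_s = 5, smooth_sigma_s = 0.01) {
  stopifnot(inherits(raster, "spike_raster"))
  tot <- colSums(raster$counts)
  if (stats::sd(tot) == 0) {
    warning("zero-variance summed activity; no events")
    return(empty_pbes())
  }
  if (smooth_sigma_s > 0) {
    half <- max(1L, ceiling(3 * smooth_sigma_s / raster$bin_s))
    g <- stats::dnorm(seq(-half, half) * raster$bin_s, sd = smooth_sigma_s)
    g <- g / sum(g)
    sm <- stats::filter(tot, g, sides = 2)
    sm[is.na(sm)] <- mean(tot)
    tot <- as.numeric(sm)
  }
  z <- (tot - mean(tot)) / stats::sd(tot)
  above_edge <- z > z_edge
  r <- rle(above_edge)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    pk <- max(z[i0:i1])
    if (pk < z_peak_min) next
    t0 <- (i0 - 1L) * raster$bin_s
    t1 <- i1 * raster$bin_s
    dur <- t1 - t0
    if (dur < min_dur_s || dur > max_dur_s) next
    msp <- if (is.null(speed_cm_s)) NA_real_ else {
      si <- pmin(length(speed_cm_s), pmax(1L, ceiling(seq(i0, i1) *
                                                        raster$bin_s / 0.1)))
      mean(speed_cm_s[si])
    }
    if (!is.null(speed_cm_s) && is.finite(max_speed_cm_s) &&
        msp > max_speed_cm_s) next
    out[[length(out) + 1L]] <- data.frame(t_start_s = t0, t_end_s = t1,
                                          peak_z = pk, mean_speed_cm_s = msp)
  }
  res <- if (length(out)) do.call(rbind, out) else empty_pbes()
  class(res) <- c("pbe_intervals", class(res))
  res
}

empty_pbes <- function() {
  data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
             peak_z = numeric(0), mean_speed_cm_s = numeric(0))
}

#' Excise PBE activity and re-decode
#'
#' Replaces counts inside the given intervals either with each unit's
#' session-mean count per bin (`rule = "mean"`, default: keeps windows in
#' the decoder's training range) or with zeros (`rule = "zero"`), then
#' re-runs [decode_stream()]. Overlapping intervals are merged with a
#' warning. The returned decode carries a per-sample flag marking decode
#' windows that overlap any excised interval; samples whose windows do not
#' overlap are identical to the unmasked decode.
#'
#' @param raster Base-bin [spike_raster()].
#' @param intervals PBE intervals (`t_start_s`, `t_end_s`).
#' @param model A trained [train_decoder()] model.
#' @param rule Elimination rule, `"mean"` or `"zero"`.
#' @return Data frame as from [decode_stream()] plus a logical
#'   `overlaps_pbe` column.
#' @export
mask_pbes_and_redecode <- function(raster, intervals, model,
                                   rule = c("mean", "zero")) {
  rule <- match.arg(rule)
  stopifnot(inherits(raster, "spike_raster"))
  iv <- merge_intervals(intervals)
  masked <- raster
  if (nrow(iv)) {
    repl <- if (rule == "mean") rowMeans(raster$counts) else
      numeric(nrow(raster$counts))
    for (k in seq_len(nrow(iv))) {
      i0 <- max(1L, floor(iv$t_start_s[k] / raster$bin_s) + 1L)
      i1 <- min(n_bins(raster), ceiling(iv$t_end_s[k] / raster$bin_s))
      if (i1 >= i0) masked$counts[, i0:i1] <- repl
    }
  }
  dec <- decode_stream(model, masked)
  w <- model$config$window_s
  dec$overlaps_pbe <- vapply(dec$t_s, function(te) {
    any(iv$t_start_s < te & iv$t_end_s > te - w)
  }, logical(1))
  dec
}

merge_intervals <- function(intervals) {
  if (!nrow(intervals)) return(intervals)
  iv <- intervals[order(intervals$t_start_s), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  overlap <- FALSE
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv$t_start_s[k] <= merged$t_end_s[last]) {
      overlap <- TRUE
      merged$t_end_s[last] <- max(merged$t_end_s[last], iv$t_end_s[k])
    } else merged <- rbind(merged, iv[k, , drop = FALSE])
  }
  if (overlap) warning("overlapping intervals merged")
  merged
}

#' Per-unit mean-rate comparison across two tasks
#'
#' @param raster_a,raster_b Rasters sharing the same unit set.
#' @return List with `mean_rates_a`, `mean_rates_b` (Hz), `pearson_r`,
#'   `median_ratio` (b over a, units with nonzero a-rate).
#' @export
rate_correlation_across_tasks <- function(raster_a, raster_b) {
  stopifnot(inherits(raster_a, "spike_raster"), inherits(raster_b, "spike_raster"))
  if (!identical(raster_a$unit_ids, raster_b$unit_ids))
    stop("unit sets differ")
  if (nrow(raster_a$counts) < 3) stop("need at least 3 units")
  ra <- rowSums(raster_a$counts) / raster_duration(raster_a)
  rb <- rowSums(raster_b$counts) / raster_duration(raster_b)
  ok <- ra > 0
  list(mean_rates_a = ra, mean_rates_b = rb,
       pearson_r = stats::cor(ra, rb),
       median_ratio = stats::median(rb[ok] / ra[ok]))
}
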