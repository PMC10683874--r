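#' Simulated place-cell ensemble
#'
#' Draws a population of units with isotropic 2-D Gaussian spatial tuning:
#' unit i fires at `baseline_i + peak_i * exp(-||x - center_i||^2 / (2 sigma_i^2))`
#' Hz at position x. Field centers are uniform over the arena; widths, peak
#' and baseline rates are uniform over the supplied ranges.
#'
#' @param arena An [arena_spec()].
#' @param n_units Number of units (>= 1).
#' @param sigma_range Range (cm) for the Gaussian field width.
#' @param peak_range Range (Hz) for the in-field peak rate above baseline.
#' @param baseline_range Range (Hz) for the out-of-field baseline rate.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return An object of class `place_ensemble` with fields `n_units`,
#'   `centers` (n x 2, cm), `sigmas`, `peak_rates`, `baseline_rates`, `seed`.
#' @examples
#' ens <- make_ensemble(arena_spec(), 25, seed = 1)
#' ens
#' @export
make_ensemble <- function(arena, n_units,
                          sigma_range = c(8, 15),
                          peak_range = c(10, 20),
                          baseline_range = c(0.1, 0.5),
                          seed = 1L) {
  stopifnot(inherits(arena, "arena_spec"))
  if (n_units < 1) stop("n_units must be >= 1")
  check_range <- function(r, name, min_ok = 0) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < min_ok)
      stop(sprintf("invalid %s", name))
  }
  check_range(sigma_range, "sigma_range", min_ok = 1e-6)
  check_range(peak_range, "peak_range", min_ok = 1e-6)
  check_range(baseline_range, "baseline_range", min_ok = 0)
  n_units <- as.integer(n_units)
  with_seed(seed, {
    centers <- cbind(x = stats::runif(n_units, 0, arena$side_cm),
                     y = stats::runif(n_units, 0, arena$side_cm))
    structure(
      list(n_units = n_units,
           unit_ids = sprintf("u%03d", seq_len(n_units)),
           centers = centers,
           sigmas = stats::runif(n_units, sigma_range[1], sigma_range[2]),
           peak_rates = stats::runif(n_units, peak_range[1], peak_range[2]),
           baseline_rates = stats::runif(n_units, baseline_range[1], baseline_range[2]),
           arena = arena,
           seed = as.integer(seed)),
      class = "place_ensemble")
  })
}

#' @export
print.place_ensemble <- function(x, ...) {
  cat(sprintf("<place_ensemble> %d units; sigma %.1f-%.1f cm; peak %.1f-%.1f Hz\n",
              x$n_units, min(x$sigmas), max(x$sigmas),
              min(x$peak_rates), max(x$peak_rates)))
  invisible(x)
}

#' Gaussian tuning rates at given positions
#'
#' Evaluates every unit's tuning function at one or more positions.
#'
#' @param ensemble A [make_ensemble()] object.
#' @param xy Length-2 vector or n x 2 matrix of positions (cm); must be
#'   inside the arena.
#' @return n x n_units matrix of firing rates (Hz); a single position gives
#'   a 1-row matrix.
#' @export
tuning_rate <- function(ensemble, xy) {
  stopifnot(inherits(ensemble, "place_ensemble"))
  xy <- as_xy_matrix(xy)
  if (!all(in_arena(ensemble$arena, xy))) stop("position outside arena bounds")
  dx <- outer(xy[, 1], ensemble$centers[, 1], "-")
  dy <- outer(xy[, 2], ensemble$centers[, 2], "-")
  d2 <- dx^2 + dy^2
  rates <- sweep(exp(-sweep(d2, 2, 2 * ensemble$sigmas^2, "/")), 2,
                 ensemble$peak_rates, "*")
  rates <- sweep(rates, 2, ensemble$baseline_rates, "+")
  colnames(rates) <- ensemble$unit_ids
  rates
}
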