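#' Square virtual arena specification
#'
#' Defines the square arena every simulation and analysis operates in.
#' Coordinates are in centimetres with the origin at the lower-left corner,
#' x increasing rightward and y upward. The arena is discretized into square
#' spatial bins used by firing-rate maps and the Bayesian decoder; bins are
#' indexed row-major with x varying fastest (bin 1 is the lower-left bin).
#'
#' @param side_cm Side length of the square arena (cm).
#' @param spatial_bin_cm Width of the square spatial bins (cm); `side_cm`
#'   must be an integer multiple, with at least 4 bins per side.
#' @param goal_radius_cm Radius of the circular goal region (cm); must be
#'   positive and smaller than half the arena side.
#' @return An object of class `arena_spec`.
#' @examples
#' a <- arena_spec()
#' a
#' @export
arena_spec <- function(side_cm = 100, spatial_bin_cm = 5, goal_radius_cm = 10) {
  stopifnot(is.numeric(side_cm), length(side_cm) == 1L, is.finite(side_cm))
  if (side_cm <= 0 || spatial_bin_cm <= 0)
    stop("side_cm and spatial_bin_cm must be positive")
  n_side <- side_cm / spatial_bin_cm
  if (abs(n_side - round(n_side)) > 1e-9 || round(n_side) < 4)
    stop("side_cm / spatial_bin_cm must be an integer >= 4")
  if (goal_radius_cm <= 0 || goal_radius_cm >= side_cm / 2)
    stop("goal_radius_cm must lie in (0, side_cm / 2)")
  structure(
    list(side_cm = side_cm,
         spatial_bin_cm = spatial_bin_cm,
         goal_radius_cm = goal_radius_cm,
         n_side = as.integer(round(n_side)),
         n_bins = as.integer(round(n_side)^2)),
    class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm, %g-cm bins (%d x %d), goal radius %g cm\n",
              x$side_cm, x$side_cm, x$spatial_bin_cm, x$n_side, x$n_side,
              x$goal_radius_cm))
  invisible(x)
}

in_arena <- function(arena, xy) {
  xy <- as_xy_matrix(xy)
  xy[, 1] >= 0 & xy[, 1] <= arena$side_cm &
    xy[, 2] >= 0 & xy[, 2] <= arena$side_cm
}

as_xy_matrix <- function(xy) {
  if (is.null(dim(xy))) {
    if (length(xy) != 2L) stop("xy must be a length-2 vector or an n x 2 matrix")
    xy <- matrix(xy, ncol = 2L)
  }
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("xy must have two columns (x, y)")
  storage.mode(xy) <- "double"
  xy
}

#' Map positions to spatial bin indices
#'
#' Bins are indexed row-major with x fastest: `bin = (iy - 1) * n_side + ix`.
#' Positions exactly on the upper/right arena boundary fall in the last bin.
#'
#' @param arena An [arena_spec()].
#' @param xy Length-2 vector or n x 2 matrix of positions (cm).
#' @return Integer vector of bin indices in `1:arena$n_bins`.
#' @export
xy_to_bin <- function(arena, xy) {
  xy <- as_xy_matrix(xy)
  if (!all(in_arena(arena, xy))) stop("position outside arena bounds")
  ix <- pmin(arena$n_side, floor(xy[, 1] / arena$spatial_bin_cm) + 1L)
  iy <- pmin(arena$n_side, floor(xy[, 2] / arena$spatial_bin_cm) + 1L)
  as.integer((iy - 1L) * arena$n_side + ix)
}

#' Centers of the arena's spatial bins
#'
#' @param arena An [arena_spec()].
#' @return `n_bins` x 2 matrix of bin-center coordinates (cm), in bin-index
#'   order (row-major, x fastest).
#' @export
bin_centers <- function(arena) {
  h <- arena$spatial_bin_cm
  g <- seq_len(arena$n_side) * h - h / 2
  cbind(x = rep(g, times = arena$n_side), y = rep(g, each = arena$n_side))
}

clip_to_arena <- function(arena, xy) {
  xy <- as_xy_matrix(xy)
  xy[] <- pmin(pmax(xy, 0), arena$side_cm)
  xy
}

# Euclidean distance between rows of a and a point (or matching rows of) b
dist_xy <- function(a, b) {
  a <- as_xy_matrix(a)
  b <- as_xy_matrix(b)
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}
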