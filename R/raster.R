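#' Spike-count raster
#'
#' A units x time-bins matrix of nonnegative spike counts on a uniform time
#' grid. The simulator emits rasters at a 10-ms base bin; the decoder
#' aggregates them to 100-ms bins with [bin_counts()], which conserves the
#' per-unit total count exactly.
#'
#' @param counts Units x bins matrix of nonnegative counts.
#' @param bin_s Bin width in seconds (default 0.01).
#' @param unit_ids Character vector of unit identifiers (default from rows).
#' @param t0 Session start time (s).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(counts, bin_s = 0.01, unit_ids = NULL, t0 = 0) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and nonnegative")
  if (is.null(unit_ids)) {
    unit_ids <- rownames(counts)
    if (is.null(unit_ids)) unit_ids <- sprintf("u%03d", seq_len(nrow(counts)))
  }
  if (length(unit_ids) != nrow(counts)) stop("unit_ids length must match rows")
  rownames(counts) <- unit_ids
  structure(list(counts = counts, bin_s = bin_s, unit_ids = unit_ids, t0 = t0),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d units x %d bins @ %g ms (%.1f s, %d spikes)\n",
              nrow(x$counts), ncol(x$counts), 1000 * x$bin_s,
              ncol(x$counts) * x$bin_s, sum(x$counts)))
  invisible(x)
}

n_bins <- function(raster) ncol(raster$counts)
raster_duration <- function(raster) ncol(raster$counts) * raster$bin_s

#' Rebin a spike raster to a coarser bin width
#'
#' Sums counts within consecutive groups of base bins. The target width must
#' be an integer multiple of the raster's width; per-unit totals are
#' conserved exactly. Trailing bins that do not fill a whole coarse bin are
#' dropped (none are dropped when the duration is a multiple of `bin_s`).
#'
#' @param raster A [spike_raster()].
#' @param bin_s Target bin width (s).
#' @return A [spike_raster()] at the coarser width.
#' @export
bin_counts <- function(raster, bin_s) {
  stopifnot(inherits(raster, "spike_raster"))
  f <- bin_s / raster$bin_s
  if (abs(f - round(f)) > 1e-8 || round(f) < 1)
    stop("bin_s must be an integer multiple of the raster bin width")
  f <- as.integer(round(f))
  if (f == 1L) return(raster)
  nb <- ncol(raster$counts) %/% f
  if (nb < 1L) stop("raster shorter than one target bin")
  idx <- seq_len(nb * f)
  grp <- rep(seq_len(nb), each = f)
  # rowsum over time groups: operate on transposed counts (bins x units)
  agg <- rowsum(t(raster$counts[, idx, drop = FALSE]), grp, reorder = TRUE)
  spike_raster(t(agg), bin_s = bin_s, unit_ids = raster$unit_ids, t0 = raster$t0)
}

#' Reassign whole spike trains to shuffled unit identities
#'
#' Applies a uniform random permutation to the rows of the raster while
#' keeping the unit-ID labels in place, so each identity receives another
#' unit's complete spike train. Per-bin population sums are unchanged.
#'
#' @param raster A [spike_raster()].
#' @param seed Integer seed.
#' @param perm Optional explicit permutation (overrides `seed`), mainly for
#'   testing.
#' @return A [spike_raster()] with permuted rows.
#' @export
shuffle_unit_identities <- function(raster, seed = 1L, perm = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  n <- nrow(raster$counts)
  if (n < 2L) stop("need at least 2 units to shuffle")
  if (is.null(perm)) perm <- with_seed(seed, sample.int(n))
  if (!identical(sort(perm), seq_len(n))) stop("perm is not a permutation")
  out <- raster
  out$counts <- raster$counts[perm, , drop = FALSE]
  rownames(out$counts) <- raster$unit_ids
  out
}

#' Write / read a spike raster as sparse long-format CSV
#'
#' Plain-text serialization: one row per nonzero (unit, bin) pair with
#' columns `unit_id`, `bin`, `count`, plus a header comment carrying
#' `bin_s`, `t0` and the full unit roster (so silent units round-trip).
#'
#' @param raster A [spike_raster()].
#' @param path Output file path.
#' @return `write_raster_csv` returns `path` invisibly; `read_raster_csv`
#'   returns a [spike_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  nz <- which(raster$counts > 0, arr.ind = TRUE)
  df <- data.frame(unit_id = raster$unit_ids[nz[, 1]], bin = nz[, 2],
                   count = raster$counts[nz])
  df <- df[order(df$bin, df$unit_id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_s=%.17g t0=%.17g n_bins=%d units=%s",
                     raster$bin_s, raster$t0, ncol(raster$counts),
                     paste(raster$unit_ids, collapse = ";")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  get_field <- function(name) sub(sprintf(".*%s=([^ ]+).*", name), "\\1", hdr)
  bin_s <- as.numeric(get_field("bin_s"))
  t0 <- as.numeric(get_field("t0"))
  nb <- as.integer(get_field("n_bins"))
  units <- strsplit(get_field("units"), ";", fixed = TRUE)[[1]]
  df <- utils::read.csv(path, skip = 1L)
  counts <- matrix(0, nrow = length(units), ncol = nb,
                   dimnames = list(units, NULL))
  counts[cbind(match(df$unit_id, units), df$bin)] <- df$count
  spike_raster(counts, bin_s = bin_s, unit_ids = units, t0 = t0)
}
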