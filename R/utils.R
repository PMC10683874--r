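# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed for a named pipeline stage, derived from a master
# seed; always in [0, 2^31 - 2] so it is a valid R integer seed.
derive_seed <- function(master, stage) {
  s <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(as.character(stage)))
    s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

# Trailing moving sum of each column block: given a matrix (rows = time),
# returns rows t = k..n holding colwise sums over rows (t-k+1)..t.
rolling_row_sums <- function(m, k) {
  n <- nrow(m)
  if (k > n) stop("window longer than series")
  cs <- apply(m, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(m))
  out <- cs[k:n, , drop = FALSE]
  if (k < n) out[-1, ] <- out[-1, , drop = FALSE] - cs[1:(n - k), , drop = FALSE]
  out
}

# wrap angle difference to (-180, 180]
wrap_deg <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
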