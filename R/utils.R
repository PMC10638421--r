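# Internal helpers shared across modules.

# 30 kHz acquisition clock; all event times are snapped to this grid at
# generation so that written event tables round-trip exactly.
CLOCK_HZ <- 30000

snap_to_clock <- function(time_s) round(time_s * CLOCK_HZ) / CLOCK_HZ

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL uses the current stream (still reproducible if the caller set one).
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Deterministic per-stage child seeds from one session seed (Lehmer step).
# The modulus leaves headroom below .Machine$integer.max so small offsets can
# be added to a child seed without overflowing set.seed().
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 48271 + 7919 * stage) %% 1999999973)
}

# Truncated normal draws on [lo, hi] via inverse CDF; sd = 0 returns the mean
# (clamped). Used for evoked-spike latencies.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- numeric(n)
  zero <- sd <= 0
  out[zero] <- pmin(pmax(mean[zero], lo), hi)
  if (any(!zero)) {
    m <- mean[!zero]; s <- sd[!zero]
    plo <- stats::pnorm(lo, m, s)
    phi <- stats::pnorm(hi, m, s)
    u <- stats::runif(sum(!zero), plo, phi)
    out[!zero] <- stats::qnorm(u, m, s)
  }
  out
}

# Merge overlapping/abutting half-open intervals given as a two-column matrix
# or data frame (start, end). Returns a tibble sorted by start.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  if (length(start) == 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- numeric(length(start)); me <- numeric(length(start))
  k <- 1L; ms[1] <- start[1]; me[1] <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me[k]) {
      me[k] <- max(me[k], end[i])
    } else {
      k <- k + 1L; ms[k] <- start[i]; me[k] <- end[i]
    }
  }
  tibble::tibble(start_s = ms[seq_len(k)], end_s = me[seq_len(k)])
}

# Count, for each half-open query interval [start, end), events of a sorted
# numeric vector. left.open = TRUE gives the number of elements strictly < x.
count_in_intervals <- function(times_sorted, start, end) {
  findInterval(end, times_sorted, left.open = TRUE) -
    findInterval(start, times_sorted, left.open = TRUE)
}

`%||%` <- rlang::`%||%`
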