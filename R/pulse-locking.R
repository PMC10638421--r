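# Pulse-triggered averages and phase-locking statistics.
#
# The PTA bins spikes within each inter-pulse interval into 0.5-ms bins and
# records, per bin, the fraction of pulses with at least one spike. Bins
# overlapping the 2-ms analysis blank are masked (excluded from statistics,
# not zero-filled). The phase-locking index is the mean of the peak bin and
# its two adjoining valid bins minus the median over all valid bins; it is
# zero for any flat profile and insensitive to uniform rate shifts.

# Per-pulse, per-bin spike indicator matrix for one channel.
# Returns list(ind = n_pulses x n_bins logical, n_bins, bin_ms, first_valid).
pta_indicator <- function(times, pulse_times, ipi_s, bin_ms = 0.5,
                          analysis_blank_ms = 2) {
  n_bins <- floor(ipi_s * 1000 / bin_ms + 1e-9)
  if (n_bins < 1) stop("inter-pulse interval shorter than one bin")
  idx <- findInterval(times, pulse_times, left.open = FALSE)
  ok <- idx >= 1
  phase_ms <- (times[ok] - pulse_times[pmax(idx[ok], 1L)]) * 1000
  keep <- phase_ms < n_bins * bin_ms
  pulse_i <- idx[ok][keep]
  bin_i <- floor(phase_ms[keep] / bin_ms) + 1
  ind <- matrix(FALSE, length(pulse_times), n_bins)
  ind[cbind(pulse_i, bin_i)] <- TRUE
  list(ind = ind, n_bins = n_bins, bin_ms = bin_ms,
       valid = seq_len(n_bins) > ceiling(analysis_blank_ms / bin_ms - 1e-9))
}

#' Pulse-triggered average
#'
#' @param spikes Spike table.
#' @param pulses Pulse table for ONE stimulating channel (its pulse times
#'   define the inter-pulse intervals; the interval is taken from the train's
#'   pulse rate).
#' @param channels Motor channels to profile (default: all in `spikes`).
#' @param bin_ms PTA bin width, ms (default 0.5).
#' @param analysis_blank_ms Bins overlapping this initial window are masked.
#' @return Long tibble: `channel_id`, `bin` (0-based), `t_lo_ms`, `prob`
#'   (fraction of pulses with >= 1 spike in the bin), `valid`; attributes
#'   `n_pulses`, `ipi_ms`, `bin_ms`.
#' @export
compute_pta <- function(spikes, pulses, channels = NULL, bin_ms = 0.5,
                        analysis_blank_ms = 2) {
  if (nrow(pulses) == 0) stop("no pulses supplied")
  stopifnot(dplyr::n_distinct(pulses$stim_channel) == 1)
  freq <- attr(pulses, "frequency_hz") %||%
    (1 / stats::median(diff(sort(pulses$pulse_time_s))))
  ipi_s <- 1 / round(freq)
  channels <- channels %||% sort(unique(spikes$channel_id))
  pt <- sort(pulses$pulse_time_s)
  out <- purrr::map_dfr(channels, function(ch) {
    pp <- pta_indicator(spikes$time_s[spikes$channel_id == ch], pt, ipi_s,
                        bin_ms, analysis_blank_ms)
    tibble::tibble(
      channel_id = ch,
      bin = seq_len(pp$n_bins) - 1L,
      t_lo_ms = (seq_len(pp$n_bins) - 1) * bin_ms,
      prob = colMeans(pp$ind),
      valid = pp$valid
    )
  })
  structure(out, n_pulses = length(pt), ipi_ms = ipi_s * 1000,
            bin_ms = bin_ms, class = c("pta_profile", class(out)))
}

# Index from a probability vector + validity mask; ties go to the earliest bin.
locking_index_vec <- function(prob, valid) {
  v <- which(valid)
  if (length(v) < 3) stop("need at least 3 valid bins")
  pv <- prob[v]
  peak <- which.max(pv)
  nbr <- intersect(c(peak - 1, peak + 1), seq_along(pv))
  mean(pv[c(peak, nbr)]) - stats::median(pv)
}

#' Phase-locking index of a PTA
#'
#' Mean of the peak bin and its (up to two) adjoining valid bins, minus the
#' median probability over all valid bins. At a mask boundary the peak has a
#' single valid neighbor, which is what gets averaged.
#'
#' @param pta A [compute_pta()] result (one or more channels).
#' @return Tibble: `channel_id`, `index`.
#' @export
phase_locking_index <- function(pta) {
  pta |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::summarise(index = locking_index_vec(.data$prob, .data$valid),
                     .groups = "drop")
}

#' Shuffle-surrogate significance of pulse locking
#'
#' Each surrogate samples `sample_frac` of the pulses, keeps their per-
#' interval spike counts, and redistributes those spikes uniformly over the
#' valid (post-blank) part of the inter-pulse interval, yielding a count-
#' matched PTA whose index is computed identically. A pair is significantly
#' pulse-locked when its observed index exceeds the surrogate index in more
#' than a fraction `1 - alpha` of surrogates (empirical p with floor
#' 1/(n_shuffles+1)).
#'
#' @param spikes,pulses,channels,bin_ms,analysis_blank_ms As [compute_pta()].
#' @param n_shuffles Surrogates (default 5000; minimum 100).
#' @param sample_frac Fraction of pulses per surrogate (default 0.2).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed.
#' @return Tibble per channel: `index`, `p`, `significant`, `n_pulses`.
#' @export
locking_significance <- function(spikes, pulses, channels = NULL,
                                 n_shuffles = 5000, sample_frac = 0.2,
                                 alpha = 0.01, bin_ms = 0.5,
                                 analysis_blank_ms = 2, seed = NULL) {
  if (n_shuffles < 100) stop("n_shuffles < 100 gives an unstable percentile")
  stopifnot(dplyr::n_distinct(pulses$stim_channel) == 1)
  freq <- attr(pulses, "frequency_hz") %||%
    (1 / stats::median(diff(sort(pulses$pulse_time_s))))
  ipi_s <- 1 / round(freq)
  channels <- channels %||% sort(unique(spikes$channel_id))
  pt <- sort(pulses$pulse_time_s)
  n_pulses <- length(pt)
  m <- max(1L, ceiling(sample_frac * n_pulses))
  with_seed_opt(seed, {
    purrr::map_dfr(channels, function(ch) {
      pp <- pta_indicator(spikes$time_s[spikes$channel_id == ch], pt, ipi_s,
                          bin_ms, analysis_blank_ms)
      obs <- locking_index_vec(colMeans(pp$ind), pp$valid)
      ## per-pulse spike counts restricted to the valid region
      times <- spikes$time_s[spikes$channel_id == ch]
      idx <- findInterval(times, pt, left.open = FALSE)
      ok <- idx >= 1
      phase_ms <- (times[ok] - pt[pmax(idx[ok], 1L)]) * 1000
      keep <- phase_ms >= analysis_blank_ms & phase_ms < pp$n_bins * bin_ms
      k_per_pulse <- tabulate(idx[ok][keep], nbins = n_pulses)
      v_bins <- which(pp$valid)
      nv <- length(v_bins)
      surr <- surrogate_indices(k_per_pulse, n_pulses, m, n_shuffles, nv,
                                pp$n_bins, pp$valid)
      p <- (1 + sum(surr >= obs)) / (n_shuffles + 1)
      tibble::tibble(channel_id = ch, index = obs, p = p,
                     significant = p <= alpha, n_pulses = n_pulses)
    })
  })
}

# Vectorized surrogate index computation: for each surrogate, sample m pulse
# slots, spread their spikes uniformly over the nv valid bins, and compute the
# locking index of the resulting probability profile.
surrogate_indices <- function(k_per_pulse, n_pulses, m, n_shuffles, nv,
                              n_bins, valid) {
  v_idx <- which(valid)
  vapply(seq_len(n_shuffles), function(s) {
    slots <- sample.int(n_pulses, m, replace = FALSE)
    k <- k_per_pulse[slots]
    tot <- sum(k)
    prob_v <- if (tot == 0) {
      rep(0, nv)
    } else {
      slot_of_spike <- rep.int(seq_len(m), k)
      bin_of_spike <- sample.int(nv, tot, replace = TRUE)
      occ <- !duplicated((slot_of_spike - 1L) * nv + bin_of_spike)
      tabulate(bin_of_spike[occ], nbins = nv) / m
    }
    prob <- numeric(n_bins)
    prob[v_idx] <- prob_v
    locking_index_vec(prob, valid)
  }, numeric(1))
}

#' Latency and jitter of a pulse-locked response
#'
#' Resamples `sample_frac` of the inter-pulse intervals, recomputes the PTA,
#' and takes the center of the maximum-probability valid bin as that
#' resample's latency. The estimate is the mean over `n_resamples` resamples;
#' jitter is their variance (SD also reported).
#'
#' @inheritParams locking_significance
#' @param n_resamples Resamples (default 5000).
#' @param significant Optional logical vector (or single value) marking which
#'   channels are significantly pulse-locked; estimating on a non-significant
#'   pair triggers a warning and flags the row.
#' @return Tibble per channel: `latency_ms`, `jitter_ms2`, `jitter_sd_ms`,
#'   `flagged` (TRUE when computed on a pair not marked significant).
#' @export
latency_jitter <- function(spikes, pulses, channels = NULL,
                           n_resamples = 5000, sample_frac = 0.2,
                           bin_ms = 0.5, analysis_blank_ms = 2,
                           significant = TRUE, seed = NULL) {
  stopifnot(dplyr::n_distinct(pulses$stim_channel) == 1)
  freq <- attr(pulses, "frequency_hz") %||%
    (1 / stats::median(diff(sort(pulses$pulse_time_s))))
  ipi_s <- 1 / round(freq)
  channels <- channels %||% sort(unique(spikes$channel_id))
  significant <- rep_len(significant, length(channels))
  if (any(!significant)) {
    warning("latency/jitter requested for pair(s) not significantly ",
            "pulse-locked; results flagged")
  }
  pt <- sort(pulses$pulse_time_s)
  n_pulses <- length(pt)
  m <- max(1L, ceiling(sample_frac * n_pulses))
  with_seed_opt(seed, {
    purrr::map_dfr(seq_along(channels), function(ci) {
      ch <- channels[ci]
      pp <- pta_indicator(spikes$time_s[spikes$channel_id == ch], pt, ipi_s,
                          bin_ms, analysis_blank_ms)
      v_idx <- which(pp$valid)
      indv <- pp$ind[, v_idx, drop = FALSE] * 1
      lat <- vapply(seq_len(n_resamples), function(s) {
        rows <- sample.int(n_pulses, m, replace = FALSE)
        pv <- colSums(indv[rows, , drop = FALSE])
        (v_idx[which.max(pv)] - 0.5) * pp$bin_ms
      }, numeric(1))
      tibble::tibble(
        channel_id = ch, latency_ms = mean(lat),
        jitter_ms2 = stats::var(lat) * (n_resamples - 1) / n_resamples,
        jitter_sd_ms = sqrt(stats::var(lat) * (n_resamples - 1) / n_resamples),
        flagged = !significant[ci]
      )
    })
  })
}

#' Latency consistency across stimulation frequencies
#'
#' Runs the locking test and latency estimate for the same channel pair at
#' several train frequencies (canonically 25, 50 and 100 Hz) and reports the
#' per-frequency latencies plus the maximum pairwise spread. A response whose
#' true latency exceeds the shortest inter-pulse interval aliases at the high
#' frequency and is exposed by a large spread.
#'
#' @param spikes Spike table.
#' @param pulses_by_freq Named list of pulse tables, names = frequency in Hz.
#' @param channels Channels to test.
#' @param n_shuffles,n_resamples,sample_frac,alpha,seed Passed through.
#' @return Tibble per (channel, frequency) with `index`, `p`, `significant`,
#'   `latency_ms`, plus a `spread_ms` column (max pairwise latency difference
#'   over significant frequencies; NA when < 2 are significant).
#' @export
latency_consistency <- function(spikes, pulses_by_freq, channels = NULL,
                                n_shuffles = 1000, n_resamples = 1000,
                                sample_frac = 0.2, alpha = 0.01, seed = NULL) {
  if (length(pulses_by_freq) < 3) {
    warning("fewer than 3 frequencies supplied; partial result")
  }
  res <- purrr::imap_dfr(pulses_by_freq, function(pl, fq) {
    sig <- locking_significance(spikes, pl, channels = channels,
                                n_shuffles = n_shuffles,
                                sample_frac = sample_frac, alpha = alpha,
                                seed = seed)
    lat <- suppressWarnings(
      latency_jitter(spikes, pl, channels = channels,
                     n_resamples = n_resamples, sample_frac = sample_frac,
                     significant = sig$significant, seed = seed)
    )
    dplyr::mutate(dplyr::left_join(sig, lat, by = "channel_id"),
                  frequency_hz = as.numeric(fq))
  })
  spread <- res |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::summarise(
      spread_ms = if (dplyr::n() >= 2) diff(range(.data$latency_ms))
                  else NA_real_,
      .groups = "drop"
    )
  dplyr::left_join(res, spread, by = "channel_id")
}
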