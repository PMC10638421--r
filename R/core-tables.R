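#' Build a spike event table
#'
#' The universal input to all analyses: one row per threshold-crossing event.
#' `unit_id = 0` denotes unsorted threshold crossings (the default recording
#' mode); sorted units, where available, get positive ids.
#'
#' @param channel_id Integer recording channel per event.
#' @param time_s Non-negative event time in seconds. Times are snapped to the
#'   30-kHz acquisition clock and sorted within channel.
#' @param unit_id Integer unit label (0 = unsorted threshold crossings).
#' @return A tibble with columns `channel_id`, `unit_id`, `time_s`, sorted by
#'   channel then time.
#' @export
spike_table <- function(channel_id, time_s, unit_id = 0L) {
  stopifnot(all(time_s >= 0))
  out <- tibble::tibble(
    channel_id = as.integer(channel_id),
    unit_id = as.integer(unit_id),
    time_s = snap_to_clock(as.numeric(time_s))
  )
  dplyr::arrange(out, .data$channel_id, .data$time_s)
}

#' Build a stimulation pulse table for one or more trains
#'
#' Each train is a constant-frequency sequence of charge-balanced, cathodal-
#' first pulses: a 200-us cathodal phase at the commanded amplitude, a 100-us
#' interphase gap, then a 400-us anodal phase at half the amplitude, so net
#' charge per pulse is exactly zero.
#'
#' @param stim_channel Stimulating (S1) electrode id, one per train.
#' @param onset_s Train onset time(s), seconds.
#' @param duration_s Train duration, seconds (default 1).
#' @param frequency_hz Pulse rate within the train, <= 300 Hz (default 100).
#' @param amplitude_ua Cathodal-phase amplitude in microamps; scalar or one
#'   value per train (default 60).
#' @param train_id Optional integer id per train; defaults to sequence.
#' @return A pulse tibble: `train_id`, `stim_channel`, `pulse_time_s`,
#'   `amplitude_ua`, with pulse-shape parameters stored as attributes
#'   (`cathodal_us`, `interphase_us`, `anodal_us`, `anodal_fraction`,
#'   `frequency_hz`).
#' @export
stim_train <- function(stim_channel, onset_s, duration_s = 1,
                       frequency_hz = 100, amplitude_ua = 60,
                       train_id = seq_along(onset_s)) {
  stopifnot(frequency_hz > 0, frequency_hz <= 300, all(amplitude_ua > 0))
  n_tr <- length(onset_s)
  stim_channel <- rep_len(as.integer(stim_channel), n_tr)
  amplitude_ua <- rep_len(amplitude_ua, n_tr)
  duration_s <- rep_len(duration_s, n_tr)
  n_pulses <- floor(duration_s * frequency_hz)
  out <- tibble::tibble(
    train_id = rep(as.integer(train_id), n_pulses),
    stim_channel = rep(stim_channel, n_pulses),
    pulse_time_s = snap_to_clock(
      rep(onset_s, n_pulses) + unlist(lapply(n_pulses, function(k) {
        seq_len(k) - 1
      })) / frequency_hz
    ),
    amplitude_ua = rep(amplitude_ua, n_pulses)
  )
  stopifnot(!is.unsorted(out$pulse_time_s[order(out$train_id)]))
  structure(out,
    cathodal_us = 200, interphase_us = 100, anodal_us = 400,
    anodal_fraction = 0.5, frequency_hz = frequency_hz
  )
}

#' Net and cathodal charge of stimulation pulses
#'
#' `net_pulse_charge_nc()` returns the per-pulse net charge (cathodal minus
#' anodal) in nanocoulombs; it is identically zero for the asymmetric
#' charge-balanced shape used here (200 us at A vs 400 us at A/2).
#' `cathodal_charge_nc()` sums the cathodal-phase charge over all pulses of a
#' pulse table, the natural measure of total stimulation delivered.
#'
#' @param amplitude_ua Cathodal amplitude(s), microamps.
#' @param cathodal_us,anodal_us,anodal_fraction Pulse-shape parameters.
#' @return Charge in nC (1 uA * 1 us = 1e-3 nC).
#' @export
net_pulse_charge_nc <- function(amplitude_ua, cathodal_us = 200,
                                anodal_us = 400, anodal_fraction = 0.5) {
  (cathodal_us * amplitude_ua - anodal_us * anodal_fraction * amplitude_ua) / 1000
}

#' @rdname net_pulse_charge_nc
#' @param pulses A pulse table from [stim_train()] or [build_stim_train()].
#' @export
cathodal_charge_nc <- function(pulses, cathodal_us = 200) {
  sum(pulses$amplitude_ua * cathodal_us) / 1000
}

#' Post-pulse blanking windows
#'
#' Recording is suppressed for a fixed window after every stimulation pulse:
#' 1.6 ms by the amplifier's sample-and-hold circuit (hardware blanking), and
#' the first 2 ms are additionally discarded in analyses to avoid residual
#' artifact. Windows are half-open `[pulse, pulse + blank_ms)` and merged when
#' they overlap.
#'
#' @param pulse_times_s Pulse onset times, seconds.
#' @param blank_ms Window length in ms (1.6 hardware, 2.0 analysis).
#' @return Tibble of merged windows (`start_s`, `end_s`).
#' @export
blank_windows <- function(pulse_times_s, blank_ms = 1.6) {
  merge_intervals(pulse_times_s, pulse_times_s + blank_ms / 1000)
}

#' Remove spike events falling inside blanking windows
#'
#' Idempotent: events inside any window are dropped; the number removed is
#' recorded in the `n_removed` attribute.
#'
#' @param spikes A spike table.
#' @param windows Merged blank windows from [blank_windows()].
#' @return The filtered spike table.
#' @export
apply_blanking <- function(spikes, windows) {
  if (nrow(windows) == 0 || nrow(spikes) == 0) {
    return(structure(spikes, n_removed = 0L))
  }
  idx <- findInterval(spikes$time_s, windows$start_s, left.open = FALSE)
  inside <- idx >= 1 & spikes$time_s < windows$end_s[pmax(idx, 1L)]
  structure(spikes[!inside, , drop = FALSE], n_removed = sum(inside))
}

#' Bin spikes into firing rates
#'
#' Counts per channel in consecutive half-open bins over `span`, converted to
#' Hz. A spike exactly on a bin edge belongs to the later bin; a trailing
#' partial bin is dropped.
#'
#' @param spikes A spike table.
#' @param span Length-2 numeric, `c(start_s, end_s)`.
#' @param bin_width_ms Bin width in ms (default 20, the decoding bin).
#' @param channels Optional integer vector of channels that must appear in the
#'   output; channels with no events get all-zero rows (with a warning).
#' @return Long tibble: `channel_id`, `bin` (0-based), `t_start_s`, `rate_hz`.
#' @export
bin_spikes <- function(spikes, span, bin_width_ms = 20, channels = NULL) {
  stopifnot(length(span) == 2, bin_width_ms > 0)
  if (diff(span) <= 0) stop("empty span: end must exceed start")
  w <- bin_width_ms / 1000
  n_bins <- floor(diff(span) / w + 1e-9)
  if (n_bins < 1) stop("span shorter than one bin")
  chans <- sort(unique(c(spikes$channel_id, channels)))
  missing <- setdiff(channels, spikes$channel_id)
  if (length(missing) > 0) {
    warning("no events on channel(s) ", paste(missing, collapse = ", "),
            "; returning zero rates")
  }
  s <- dplyr::filter(spikes, .data$time_s >= span[1],
                     .data$time_s < span[1] + n_bins * w)
  bin <- floor((s$time_s - span[1]) / w)
  counts <- table(factor(s$channel_id, levels = chans),
                  factor(bin, levels = 0:(n_bins - 1)))
  bin_idx <- rep(0:(n_bins - 1), each = length(chans))
  tibble::tibble(
    channel_id = rep(as.integer(chans), times = n_bins),
    bin = bin_idx,
    t_start_s = span[1] + bin_idx * w,
    rate_hz = as.vector(counts) / w
  )
}

#' Convert binned rates to a channels-by-bins matrix
#'
#' @param binned Output of [bin_spikes()].
#' @return Numeric matrix, rownames = channel ids.
#' @export
as_rates_matrix <- function(binned) {
  wide <- tidyr::pivot_wider(binned[c("channel_id", "bin", "rate_hz")],
                             names_from = "bin", values_from = "rate_hz",
                             values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$channel_id
  m
}
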