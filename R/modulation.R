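#' Bootstrap null distribution of baseline rate fluctuations
#'
#' For each motor channel, repeatedly samples pairs of consecutive 1-s
#' intervals inside the intertrial periods, takes the firing-rate difference
#' (second minus first), and averages `n_pairs_per_draw` of these differences
#' per draw. The 1000 draw means form the null against which stimulation-
#' evoked rate changes are judged. Post-pulse blanking is simulated in the
#' second interval of every pair (events within `blank_ms` of a virtual pulse
#' grid at `blank_at_hz` are discarded), mirroring the blanking that deflates
#' the measured in-train rate.
#'
#' Candidate interval starts are aligned to the virtual pulse grid so the
#' simulated blanking has the same duty cycle as during real trains.
#'
#' @param spikes Spike table.
#' @param iti Tibble of intertrial periods (`start_s`, `end_s`), e.g. from
#'   [intertrial_periods()]; each must be >= 2 s.
#' @param n_resamples Number of null draws (default 1000).
#' @param n_pairs_per_draw Interval pairs averaged per draw; defaults to the
#'   number of stimulation trains per channel in the matching protocol (15).
#' @param blank_at_hz Virtual pulse rate for blank simulation (default 100;
#'   set to 0 to disable).
#' @param blank_ms Simulated blank length per pulse (default 2, the analysis
#'   blank).
#' @param channels Channels to build nulls for (default: all in `spikes`).
#' @param seed Integer seed.
#' @return Tibble: `channel_id`, `null_mean`, `null_sd`, `n_draws`,
#'   `degenerate`, and a `draws` list-column with the raw draw means (Hz).
#' @export
baseline_null <- function(spikes, iti, n_resamples = 1000,
                          n_pairs_per_draw = 15, blank_at_hz = 100,
                          blank_ms = 2, channels = NULL, seed = NULL) {
  stopifnot(nrow(iti) > 0)
  if (any(iti$end_s - iti$start_s < 2)) {
    stop("intertrial periods must be at least 2 s long")
  }
  grid_s <- if (blank_at_hz > 0) 1 / blank_at_hz else 0.01
  ## candidate starts u such that [u, u+2) fits inside one period
  cand <- unlist(purrr::map2(iti$start_s, iti$end_s, function(a, b) {
    u0 <- ceiling(a / grid_s) * grid_s
    if (u0 + 2 > b) return(numeric(0))
    seq(u0, b - 2, by = grid_s)
  }))
  if (length(cand) == 0) stop("no intertrial interval can host a 2-s window")
  if (length(cand) < n_pairs_per_draw) {
    warning("fewer candidate interval pairs (", length(cand),
            ") than n_pairs_per_draw; sampling with replacement")
  }
  channels <- channels %||% sort(unique(spikes$channel_id))
  with_seed_opt(seed, {
    ## candidates may be reused across draws (bootstrap); within a draw they
    ## are distinct whenever enough exist
    idx <- vapply(seq_len(n_resamples), function(s) {
      sample.int(length(cand), n_pairs_per_draw,
                 replace = length(cand) < n_pairs_per_draw)
    }, integer(n_pairs_per_draw))
    purrr::map_dfr(channels, function(ch) {
      t_all <- spikes$time_s[spikes$channel_id == ch]
      t_blank <- if (blank_at_hz > 0) {
        t_all[(t_all - floor(t_all / grid_s) * grid_s) >= blank_ms / 1000]
      } else {
        t_all
      }
      d_cand <- count_in_intervals(t_blank, cand + 1, cand + 2) -
        count_in_intervals(t_all, cand, cand + 1)
      draws <- colMeans(matrix(d_cand[idx], nrow = n_pairs_per_draw))
      sdv <- stats::sd(draws)
      if (sdv == 0) {
        warning("degenerate null (SD = 0) on channel ", ch)
      }
      tibble::tibble(
        channel_id = ch, null_mean = mean(draws), null_sd = sdv,
        n_draws = n_resamples, degenerate = sdv == 0, draws = list(draws)
      )
    })
  })
}

#' Stimulation-evoked rate modulation against the baseline null
#'
#' For every (motor channel, stimulating channel) pair, the change in firing
#' rate between the 1-s interval preceding each train and the rate during the
#' train (events within `analysis_blank_ms` of any pulse discarded) is
#' averaged across trains, expressed as a z-score against the channel's
#' baseline null, and tested two-sidedly against the empirical null draws
#' (p floor 1/(n_draws+1); significance means the centered statistic exceeds
#' every centered null draw in magnitude).
#'
#' @param spikes Spike table.
#' @param pulses Pulse table (all stimulating channels).
#' @param null Output of [baseline_null()].
#' @param analysis_blank_ms Post-pulse discard window (default 2 ms).
#' @param alpha Significance level (default 0.001).
#' @param min_trains Minimum trains per stim channel (warn below; protocol
#'   minimum 15).
#' @return Tibble per pair: `motor_channel`, `stim_channel`, `n_trains`,
#'   `delta_rate_hz`, `z`, `p`, `significant`, `sign`
#'   (excitatory/inhibitory/none), `usable`.
#' @export
stim_modulation <- function(spikes, pulses, null, analysis_blank_ms = 2,
                            alpha = 0.001, min_trains = 15) {
  trains <- pulses |>
    dplyr::group_by(.data$train_id, .data$stim_channel) |>
    dplyr::summarise(
      onset = min(.data$pulse_time_s),
      dur = round((max(.data$pulse_time_s) - min(.data$pulse_time_s)) /
                    (1 - 1 / dplyr::n()), 3),
      .groups = "drop"
    )
  n_by_stim <- dplyr::count(trains, .data$stim_channel)
  if (any(n_by_stim$n < min_trains)) {
    warning("some stim channels have fewer than ", min_trains, " trains")
  }
  blk <- blank_windows(pulses$pulse_time_s, blank_ms = analysis_blank_ms)
  channels <- null$channel_id
  purrr::map_dfr(channels, function(ch) {
    t_all <- spikes$time_s[spikes$channel_id == ch]
    tb <- apply_blanking(
      tibble::tibble(channel_id = ch, unit_id = 0L, time_s = t_all), blk
    )$time_s
    r_stim <- count_in_intervals(tb, trains$onset, trains$onset + trains$dur) /
      trains$dur
    r_pre <- count_in_intervals(t_all, trains$onset - 1, trains$onset)
    nr <- null[null$channel_id == ch, ]
    draws <- nr$draws[[1]]
    per_stim <- tibble::tibble(stim_channel = trains$stim_channel,
                               d = r_stim - r_pre) |>
      dplyr::group_by(.data$stim_channel) |>
      dplyr::summarise(n_trains = dplyr::n(), delta_rate_hz = mean(.data$d),
                       .groups = "drop")
    usable <- !nr$degenerate
    ctr <- abs(draws - nr$null_mean)
    z <- (per_stim$delta_rate_hz - nr$null_mean) /
      ifelse(usable, nr$null_sd, NA_real_)
    p <- vapply(per_stim$delta_rate_hz, function(d) {
      (1 + sum(ctr >= abs(d - nr$null_mean))) / (nr$n_draws + 1)
    }, numeric(1))
    significant <- usable & p < alpha
    tibble::tibble(
      motor_channel = ch,
      stim_channel = per_stim$stim_channel,
      n_trains = per_stim$n_trains,
      delta_rate_hz = per_stim$delta_rate_hz,
      z = z, p = p,
      significant = significant,
      sign = dplyr::case_when(
        significant & z > 0 ~ "excitatory",
        significant & z < 0 ~ "inhibitory",
        TRUE ~ "none"
      ),
      usable = usable
    )
  })
}

#' Per-channel prevalence of ICMS-evoked modulation
#'
#' Summarises [stim_modulation()] results into the map shown over the motor
#' array: for each motor channel, the proportion of stimulating channels that
#' significantly modulated it, the mean modulation z across stimulating
#' channels, and whether the channel exhibited both excitatory and inhibitory
#' effects (mixed sign).
#'
#' @param results Output of [stim_modulation()].
#' @param arraymap Array map (as from [array_map()]).
#' @return Tibble per motor channel with `prop_modulating`, `mean_z`,
#'   `mixed_sign` and grid coordinates (unwired electrodes appear with NA
#'   values for grid completeness).
#' @export
summarize_prevalence <- function(results, arraymap) {
  per_ch <- results |>
    dplyr::group_by(channel_id = .data$motor_channel) |>
    dplyr::summarise(
      n_stim = dplyr::n(),
      prop_modulating = mean(.data$significant),
      mean_z = mean(.data$z, na.rm = TRUE),
      mixed_sign = any(.data$sign == "excitatory") &
        any(.data$sign == "inhibitory"),
      .groups = "drop"
    )
  m1 <- dplyr::filter(arraymap, .data$region == "M1")
  dplyr::left_join(
    dplyr::select(m1, channel_id = "electrode_id", "grid_row", "grid_col",
                  "wired"),
    per_ch, by = "channel_id"
  )
}
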