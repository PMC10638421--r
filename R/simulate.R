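# Session simulators: passive stimulation and behavioral protocols.
# Spiking is (inhomogeneous) Poisson with additive indirect shifts rectified
# at 0 Hz, plus Bernoulli-per-pulse direct evoked events at truncated-normal
# latencies. Hardware blanking (1.6 ms per pulse) is applied to the emitted
# event stream, as the amplifier would.

# Homogeneous Poisson events on [t0, t1).
gen_poisson <- function(rate_hz, t0, t1) {
  if (rate_hz <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate_hz * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# Direct evoked events for one (pair, pulse set): Bernoulli(p) per pulse,
# latency ~ N(mu, sigma) truncated to [blank_ms, ipi_ms).
gen_direct_events <- function(pulse_times, p, mu_ms, sigma_ms, ipi_ms,
                              blank_ms = 2) {
  hit <- stats::runif(length(pulse_times)) < p
  n <- sum(hit)
  if (n == 0) return(numeric(0))
  lat <- rtruncnorm(n, mu_ms, sigma_ms, blank_ms, ipi_ms - 1e-6)
  pulse_times[hit] + lat / 1000
}

#' Simulate a passive stimulation session
#'
#' Every S1 channel is stimulated `n_trains_per_channel` times with 1-s,
#' 100-Hz trains at 60 uA (the standard passive mapping protocol), in shuffled
#' order with inter-train intervals drawn uniformly from `iti_range_s`.
#' M1 spiking is baseline Poisson plus the ground truth's indirect rate shifts
#' during trains and direct pulse-locked events; 1.6-ms hardware blanking is
#' applied after every pulse.
#'
#' @param truth An [ground_truth()] object.
#' @param n_trains_per_channel Trains per stimulating channel (>= 15).
#' @param amplitude_ua,frequency_hz,train_s Train parameters.
#' @param iti_range_s Inter-train interval range, seconds.
#' @param s1_channels Stimulating channels to include (default: all S1
#'   channels in the truth); restricting shortens the session.
#' @param seed Integer seed.
#' @return An `icms_session` carrying the truth and generator metadata.
#' @export
simulate_passive_session <- function(truth, n_trains_per_channel = 15,
                                     amplitude_ua = 60, frequency_hz = 100,
                                     train_s = 1, iti_range_s = c(3, 4),
                                     s1_channels = NULL, seed = NULL) {
  stopifnot(inherits(truth, "icms_truth"))
  if (any(truth$pairs$p_direct < 0 | truth$pairs$p_direct > 1)) {
    stop("p_direct must lie in [0, 1]")
  }
  with_seed_opt(seed, {
    s1_ids <- s1_channels %||% truth$s1$electrode_id
    order_sched <- sample(rep(s1_ids, n_trains_per_channel))
    n_tr <- length(order_sched)
    itis <- stats::runif(n_tr, iti_range_s[1], iti_range_s[2])
    onsets <- 2.5 + cumsum(c(0, (train_s + itis)[-n_tr]))
    pulses <- stim_train(order_sched, onsets, duration_s = train_s,
                         frequency_hz = frequency_hz,
                         amplitude_ua = amplitude_ua)
    t_end <- max(onsets) + train_s + 2.5
    ipi_ms <- 1000 / frequency_hz
    a_scale <- amp_response(amplitude_ua, truth)
    lag <- truth$params$indirect_onset_s
    tau <- truth$params$indirect_adapt_tau_s

    spikes <- purrr::map_dfr(seq_len(nrow(truth$m1)), function(i) {
      ch <- truth$m1$channel_id[i]
      lam0 <- truth$m1$lambda0_hz[i]
      base <- gen_poisson(lam0, 0, t_end)
      pr <- truth$pairs[truth$pairs$m1_channel == ch, ]
      g <- pr$g_base_hz[match(order_sched, pr$s1_channel)] * a_scale
      extra <- numeric(0)
      ## indirect: additive extra events (g > 0) or thinning (g < 0)
      eff_dur <- if (is.finite(tau)) {
        tau * (1 - exp(-(train_s - lag) / tau))
      } else {
        train_s - lag
      }
      pos <- which(g > 0)
      if (length(pos) > 0) {
        counts <- stats::rpois(length(pos), g[pos] * eff_dur)
        tot <- sum(counts)
        if (tot > 0) {
          rel <- if (is.finite(tau)) {
            -tau * log(1 - stats::runif(tot) *
                         (1 - exp(-(train_s - lag) / tau)))
          } else {
            stats::runif(tot, 0, train_s - lag)
          }
          extra <- rep(onsets[pos] + lag, counts) + rel
        }
      }
      neg <- which(g < 0)
      if (length(neg) > 0 && length(base) > 0) {
        neg <- neg[order(onsets[neg])]
        w_idx <- findInterval(base, onsets[neg] + lag, left.open = FALSE)
        in_win <- w_idx >= 1 &
          base < (onsets[neg] + train_s)[pmax(w_idx, 1L)]
        if (any(in_win)) {
          gi <- g[neg][w_idx[in_win]]
          rel_t <- base[in_win] - (onsets[neg] + lag)[w_idx[in_win]]
          decay <- if (is.finite(tau)) exp(-rel_t / tau) else 1
          p_drop <- pmin(1, -gi * decay / lam0)
          drop <- rep(FALSE, length(base))
          drop[in_win] <- stats::runif(sum(in_win)) < p_drop
          base <- base[!drop]
        }
      }
      ev <- c(base, extra)
      ## direct evoked events
      dp <- pr[pr$direct & pr$p_direct > 0, ]
      if (nrow(dp) > 0) {
        for (j in seq_len(nrow(dp))) {
          pt <- pulses$pulse_time_s[pulses$stim_channel == dp$s1_channel[j]]
          ev <- c(ev, gen_direct_events(pt, dp$p_direct[j] * a_scale,
                                        dp$mu_lat_ms[j], dp$sigma_lat_ms[j],
                                        ipi_ms))
        }
      }
      tibble::tibble(channel_id = ch, unit_id = 0L, time_s = sort(ev))
    })
    spikes <- spike_table(spikes$channel_id, spikes$time_s)
    hw <- blank_windows(pulses$pulse_time_s, blank_ms = 1.6)
    spikes <- apply_blanking(spikes, hw)

    train_tbl <- dplyr::distinct(pulses, .data$train_id, .data$stim_channel)
    trials <- tibble::tibble(
      trial_id = train_tbl$train_id,
      condition = "passive",
      phase_start_s = onsets,
      phase_end_s = onsets + train_s,
      amplitude_level_ua = amplitude_ua,
      cued_digit = NA_integer_,
      target_id = NA_integer_,
      baseline_start_s = onsets - 1,
      baseline_end_s = onsets
    )
    icms_session(spikes, pulses, trials, array_map(truth), truth = truth,
                 meta = list(seed = seed, protocol = "passive",
                             n_trains_per_channel = n_trains_per_channel,
                             amplitude_ua = amplitude_ua,
                             frequency_hz = frequency_hz, train_s = train_s))
  })
}

#' Intertrial (inter-train) quiet periods of a session
#'
#' @param session An `icms_session`.
#' @param min_s Keep only periods at least this long (default 2 s).
#' @return Tibble of half-open periods (`start_s`, `end_s`).
#' @export
intertrial_periods <- function(session, min_s = 2) {
  tr <- dplyr::arrange(session$trials, .data$phase_start_s)
  start <- tr$phase_end_s[-nrow(tr)]
  end <- tr$phase_start_s[-1]
  keep <- (end - start) >= min_s
  tibble::tibble(start_s = start[keep], end_s = end[keep])
}

phase_gain_cols <- c(squeeze = "gain_squeeze", grasp = "gain_grasp",
                     transport = "gain_transport")
phase_base_cols <- c(squeeze = "base_squeeze", grasp = "base_grasp",
                     transport = "base_transport", reach = "base_reach")

#' Simulate a behavioral session
#'
#' Four protocols:
#' \describe{
#'   \item{digit_flexion}{One cued digit per trial; movement onset is the cue
#'     plus a fixed 200-ms reaction lag, and firing is scaled by the channel's
#'     digit-preference profile during the 500-ms flexion epoch.}
#'   \item{squeeze}{Virtual-object squeeze; ICMS through `stim_channels` at one
#'     of four amplitudes (20/32/44/56 uA) for 1 s after contact.}
#'   \item{grasp_transport}{Reach (1 s, velocity-tuned), grasp (1 s, ICMS),
#'     transport (1 s, ICMS continues, velocity-tuned), to one of 8 cube-corner
#'     targets.}
#'   \item{center_out}{Planar center-out reaches to 8 targets (0.5-s cue,
#'     1.5-s reach), cosine-tuned via the velocity-tuning vectors.}
#' }
#' Indirect ICMS effects scale with the per-channel task gain of the ongoing
#' phase and with the amplitude response; direct effects are task-invariant.
#'
#' @param truth An [ground_truth()] object.
#' @param protocol One of `"digit_flexion"`, `"squeeze"`, `"grasp_transport"`,
#'   `"center_out"`.
#' @param n_trials Number of trials (defaults: 125, 208, 208, 80).
#' @param stim_channels Two S1 electrode ids used for ICMS feedback (default:
#'   the first channel with PF on digit 1 and on digit 2).
#' @param frequency_hz ICMS pulse rate (default 100).
#' @param vmax_ms Peak hand speed, m/s (default 0.3).
#' @param seed Integer seed.
#' @return An `icms_session`.
#' @export
simulate_behavior_session <- function(truth,
                                      protocol = c("digit_flexion", "squeeze",
                                                   "grasp_transport",
                                                   "center_out"),
                                      n_trials = NULL, stim_channels = NULL,
                                      frequency_hz = 100, vmax_ms = 0.3,
                                      seed = NULL) {
  protocol <- match.arg(protocol)
  defaults <- c(digit_flexion = 125, squeeze = 208, grasp_transport = 208,
                center_out = 80)
  n_trials <- n_trials %||% defaults[[protocol]]
  if (is.null(stim_channels)) {
    stim_channels <- c(
      truth$s1$electrode_id[truth$s1$pf_digit == 1][1],
      truth$s1$electrode_id[truth$s1$pf_digit == 2][1]
    )
    stim_channels <- stim_channels[!is.na(stim_channels)]
  }
  with_seed_opt(seed, {
    builder <- switch(protocol,
      digit_flexion = build_flexion_trials,
      squeeze = build_squeeze_trials,
      grasp_transport = build_grasp_transport_trials,
      center_out = build_center_out_trials
    )
    layout <- builder(truth, n_trials, stim_channels, frequency_hz, vmax_ms)
    spikes <- gen_segment_spikes(truth, layout, frequency_hz)
    hw <- blank_windows(layout$pulses$pulse_time_s, blank_ms = 1.6)
    spikes <- apply_blanking(spikes, hw)
    icms_session(spikes, layout$pulses, layout$trials, array_map(truth),
                 truth = truth,
                 meta = list(seed = seed, protocol = protocol,
                             n_trials = n_trials,
                             stim_channels = stim_channels))
  })
}

# ---- protocol layouts ------------------------------------------------------
# A layout is a list(segments, trials, pulses). Segments tile the active parts
# of the session: start_s, end_s, phase (indexes engagement/task-gain columns),
# cued_digit, amplitude_ua (NA when no ICMS), vx/vy/vz (intended velocity).

empty_pulses <- function() {
  tibble::tibble(train_id = integer(), stim_channel = integer(),
                 pulse_time_s = numeric(), amplitude_ua = numeric())
}

build_flexion_trials <- function(truth, n_trials, stim_channels,
                                 frequency_hz, vmax_ms) {
  digits <- truth$params$digits
  cued <- sample(rep(1:5, length.out = n_trials))
  t0 <- 2 + (seq_len(n_trials) - 1) * 3
  onset <- t0 + 0.2   # fixed reaction lag after cue
  segments <- tibble::tibble(
    start_s = onset, end_s = onset + 0.5, phase = "move",
    cued_digit = cued, amplitude_ua = NA_real_, vx = 0, vy = 0, vz = 0
  )
  trials <- tibble::tibble(
    trial_id = seq_len(n_trials), condition = "digit_flexion",
    phase_start_s = onset, phase_end_s = onset + 0.5,
    amplitude_level_ua = NA_real_, cued_digit = cued,
    target_id = NA_integer_,
    baseline_start_s = onset - 1, baseline_end_s = onset
  )
  list(segments = segments, trials = trials, pulses = empty_pulses(),
       t_end = max(onset) + 2.5)
}

amp_levels <- function(n) sample(rep(c(20, 32, 44, 56), length.out = n))

two_channel_pulses <- function(stim_channels, onsets, durations, amps,
                               frequency_hz, id_offset = 0L) {
  purrr::map_dfr(seq_along(stim_channels), function(k) {
    p <- stim_train(stim_channels[k], onsets, duration_s = durations,
                    frequency_hz = frequency_hz, amplitude_ua = amps,
                    train_id = id_offset + seq_along(onsets))
    tibble::as_tibble(p)
  })
}

build_squeeze_trials <- function(truth, n_trials, stim_channels,
                                 frequency_hz, vmax_ms) {
  amps <- amp_levels(n_trials)
  t0 <- 2 + (seq_len(n_trials) - 1) * 3
  contact <- t0 + 0.5
  segments <- dplyr::bind_rows(
    tibble::tibble(start_s = t0, end_s = contact, phase = "squeeze",
                   cued_digit = NA_integer_, amplitude_ua = NA_real_,
                   vx = 0, vy = 0, vz = 0),
    tibble::tibble(start_s = contact, end_s = contact + 1, phase = "squeeze",
                   cued_digit = NA_integer_, amplitude_ua = amps,
                   vx = 0, vy = 0, vz = 0)
  )
  trials <- tibble::tibble(
    trial_id = seq_len(n_trials), condition = "squeeze",
    phase_start_s = contact, phase_end_s = contact + 1,
    amplitude_level_ua = amps, cued_digit = NA_integer_,
    target_id = NA_integer_,
    baseline_start_s = t0, baseline_end_s = contact
  )
  pulses <- two_channel_pulses(stim_channels, contact, 1, amps, frequency_hz)
  list(segments = segments, trials = trials, pulses = pulses,
       t_end = max(contact) + 2.5)
}

cube_corners <- function(side = 0.3) {
  g <- tidyr::expand_grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  as.matrix(g) * side / 2
}

build_grasp_transport_trials <- function(truth, n_trials, stim_channels,
                                         frequency_hz, vmax_ms) {
  amps <- amp_levels(n_trials)
  targets <- sample(rep(1:8, length.out = n_trials))
  corners <- cube_corners()
  dirs <- corners / sqrt(rowSums(corners^2))
  t0 <- 2 + (seq_len(n_trials) - 1) * 4.5
  contact <- t0 + 1
  v_reach <- dirs[targets, , drop = FALSE] * vmax_ms
  segments <- dplyr::bind_rows(
    tibble::tibble(start_s = t0, end_s = contact, phase = "reach",
                   cued_digit = NA_integer_, amplitude_ua = NA_real_,
                   vx = v_reach[, 1], vy = v_reach[, 2], vz = v_reach[, 3]),
    tibble::tibble(start_s = contact, end_s = contact + 1, phase = "grasp",
                   cued_digit = NA_integer_, amplitude_ua = amps,
                   vx = 0, vy = 0, vz = 0),
    tibble::tibble(start_s = contact + 1, end_s = contact + 2,
                   phase = "transport", cued_digit = NA_integer_,
                   amplitude_ua = amps,
                   vx = -v_reach[, 1], vy = -v_reach[, 2], vz = -v_reach[, 3])
  )
  trials <- dplyr::bind_rows(
    tibble::tibble(
      trial_id = seq_len(n_trials), condition = "grasp",
      phase_start_s = contact, phase_end_s = contact + 1,
      amplitude_level_ua = amps, cued_digit = NA_integer_,
      target_id = targets,
      baseline_start_s = contact - 0.5, baseline_end_s = contact
    ),
    tibble::tibble(
      trial_id = seq_len(n_trials), condition = "transport",
      phase_start_s = contact + 1, phase_end_s = contact + 2,
      amplitude_level_ua = amps, cued_digit = NA_integer_,
      target_id = targets,
      baseline_start_s = t0, baseline_end_s = t0 + 0.5
    )
  )
  pulses <- two_channel_pulses(stim_channels, contact, 2, amps, frequency_hz)
  list(segments = segments, trials = trials, pulses = pulses,
       t_end = max(contact) + 3.5)
}

build_center_out_trials <- function(truth, n_trials, stim_channels,
                                    frequency_hz, vmax_ms) {
  targets <- sample(rep(1:8, length.out = n_trials))
  theta <- 2 * pi * (targets - 1) / 8
  t0 <- 2 + (seq_len(n_trials) - 1) * 3.5
  onset <- t0 + 0.5
  segments <- tibble::tibble(
    start_s = onset, end_s = onset + 1.5, phase = "reach",
    cued_digit = NA_integer_, amplitude_ua = NA_real_,
    vx = vmax_ms * cos(theta), vy = vmax_ms * sin(theta), vz = 0
  )
  trials <- tibble::tibble(
    trial_id = seq_len(n_trials), condition = "center_out",
    phase_start_s = onset, phase_end_s = onset + 1.5,
    amplitude_level_ua = NA_real_, cued_digit = NA_integer_,
    target_id = targets,
    baseline_start_s = onset - 0.4, baseline_end_s = onset
  )
  list(segments = segments, trials = trials, pulses = empty_pulses(),
       t_end = max(onset) + 3)
}

# Generate the spike table for a behavioral layout.
gen_segment_spikes <- function(truth, layout, frequency_hz) {
  seg <- layout$segments
  t_end <- layout$t_end
  pulses <- layout$pulses
  ipi_ms <- 1000 / frequency_hz
  stim_ids <- unique(pulses$stim_channel)
  durs <- seg$end_s - seg$start_s
  a_seg <- ifelse(is.na(seg$amplitude_ua), 0,
                  amp_response(seg$amplitude_ua, truth))
  w_cols <- paste0("w", 1:5)

  purrr::map_dfr(seq_len(nrow(truth$m1)), function(i) {
    m1_row <- truth$m1[i, ]
    ch <- m1_row$channel_id
    lam0 <- m1_row$lambda0_hz
    ## indirect drive from the stimulating electrodes at reference amplitude
    pr <- truth$pairs[truth$pairs$m1_channel == ch &
                        truth$pairs$s1_channel %in% stim_ids, ]
    g_ref <- sum(pr$g_base_hz)
    ## per-segment multiplier and additive terms (vectorized over segments)
    base_add <- vapply(seg$phase, function(ph) {
      if (ph %in% names(phase_base_cols)) m1_row[[phase_base_cols[[ph]]]] else 0
    }, numeric(1))
    digit_add <- ifelse(is.na(seg$cued_digit), 0,
                        as.numeric(as.matrix(m1_row[w_cols]))[
                          pmax(seg$cued_digit, 1)])
    tune_add <- seg$vx * m1_row$tune_x + seg$vy * m1_row$tune_y +
      seg$vz * m1_row$tune_z
    gain_seg <- vapply(seg$phase, function(ph) {
      if (ph %in% names(phase_gain_cols)) m1_row[[phase_gain_cols[[ph]]]] else 0
    }, numeric(1))
    lam_seg <- pmax(0, lam0 * (1 + base_add + digit_add) + tune_add +
                      g_ref * gain_seg * a_seg)
    ## baseline outside segments is lam0; generate baseline everywhere, then
    ## replace events inside segments by segment-rate events
    base_ev <- gen_poisson(lam0, 0, t_end)
    if (length(base_ev) > 0 && nrow(seg) > 0) {
      o <- order(seg$start_s)
      idx <- findInterval(base_ev, seg$start_s[o], left.open = FALSE)
      inside <- idx >= 1 & base_ev < seg$end_s[o][pmax(idx, 1L)]
      base_ev <- base_ev[!inside]
    }
    counts <- stats::rpois(nrow(seg), lam_seg * durs)
    tot <- sum(counts)
    seg_ev <- if (tot > 0) {
      rep(seg$start_s, counts) + stats::runif(tot) * rep(durs, counts)
    } else {
      numeric(0)
    }
    ev <- c(base_ev, seg_ev)
    ## direct evoked events, task-invariant, amplitude-scaled
    dp <- pr[pr$direct & pr$p_direct > 0, ]
    if (nrow(dp) > 0 && nrow(pulses) > 0) {
      for (j in seq_len(nrow(dp))) {
        pj <- pulses[pulses$stim_channel == dp$s1_channel[j], ]
        p_eff <- dp$p_direct[j] * amp_response(pj$amplitude_ua, truth)
        hit <- stats::runif(nrow(pj)) < p_eff
        n_hit <- sum(hit)
        if (n_hit > 0) {
          lat <- rtruncnorm(n_hit, dp$mu_lat_ms[j], dp$sigma_lat_ms[j],
                            2, ipi_ms - 1e-6)
          ev <- c(ev, pj$pulse_time_s[hit] + lat / 1000)
        }
      }
    }
    tibble::tibble(channel_id = ch, unit_id = 0L, time_s = sort(ev))
  }) |>
    (\(d) spike_table(d$channel_id, d$time_s))()
}
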