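test_that("deterministic direct coupling evokes one spike per pulse at the set latency", {
  tr <- ground_truth(p_couple = 0, p_direct_pair = 0, lambda0_mean_hz = 1e-9,
                     seed = 31)
  s1c <- tr$s1$electrode_id[1]
  m1c <- tr$m1$channel_id[1]
  tr <- set_pair_coupling(tr, s1c, m1c, direct = TRUE, p_direct = 1,
                          mu_lat_ms = 4, sigma_lat_ms = 0)
  ses <- simulate_passive_session(tr, n_trains_per_channel = 1,
                                  s1_channels = s1c, seed = 32)
  ev <- ses$spikes[ses$spikes$channel_id == m1c, ]
  expect_equal(nrow(ev), 100)
  pt <- ses$pulses$pulse_time_s
  lat <- (ev$time_s - pt[findInterval(ev$time_s, pt)]) * 1000
  expect_equal(lat, rep(4, 100), tolerance = 0.05)
})

test_that("indirect shifts obey the thinning oracle within Poisson error", {
  ## +30 Hz on a 10-Hz baseline during 1-s trains
  tr <- ground_truth(p_couple = 0, p_direct_pair = 0, lambda0_mean_hz = 10,
                     lambda0_shape = 1e6, seed = 33)
  s1c <- tr$s1$electrode_id[1]
  tr <- set_pair_coupling(tr, s1c, tr$m1$channel_id, g_base_hz = 30)
  ses <- simulate_passive_session(tr, n_trains_per_channel = 15,
                                  s1_channels = s1c, seed = 34)
  trains <- dplyr::distinct(ses$pulses, .data$train_id)
  onsets <- ses$trials$phase_start_s
  ## expected in-train rate: (10 + 30) Hz minus the 16% hardware-blank loss
  expected <- 40 * (1 - 0.0016 * 100)
  counts <- vapply(unique(ses$spikes$channel_id), function(ch) {
    t_ch <- ses$spikes$time_s[ses$spikes$channel_id == ch]
    sum(corticolink:::count_in_intervals(t_ch, onsets, onsets + 1))
  }, numeric(1))
  total <- sum(counts)
  n_win <- length(onsets) * length(counts)
  expect_lt(abs(total / n_win - expected), 4 * sqrt(expected * n_win) / n_win)

  ## inhibition: -8 Hz on 10 Hz -> about 2 Hz in train (before blanking)
  tr2 <- set_pair_coupling(tr, s1c, tr$m1$channel_id, g_base_hz = -8)
  ses2 <- simulate_passive_session(tr2, n_trains_per_channel = 15,
                                   s1_channels = s1c, seed = 35)
  on2 <- ses2$trials$phase_start_s
  c2 <- sum(vapply(unique(ses2$spikes$channel_id), function(ch) {
    t_ch <- ses2$spikes$time_s[ses2$spikes$channel_id == ch]
    sum(corticolink:::count_in_intervals(t_ch, on2, on2 + 1))
  }, numeric(1)))
  exp2 <- 2 * (1 - 0.16)
  expect_lt(abs(c2 / n_win - exp2), 4 * sqrt(exp2 * n_win) / n_win)
})

test_that("out-of-range per-pulse probabilities are rejected", {
  tr <- ground_truth(seed = 36)
  expect_error(set_pair_coupling(tr, tr$s1$electrode_id[1],
                                 tr$m1$channel_id[1], p_direct = 1.2),
               "p_direct")
  tr$pairs$p_direct[1] <- 1.5
  expect_error(simulate_passive_session(tr, seed = 1), "p_direct")
})

test_that("digit preference profiles drive flexion-epoch rates", {
  tr <- ground_truth(seed = 37)
  ## channel with profile peaked on digit 5
  ch <- tr$m1$channel_id[1]
  tr$m1[1, paste0("w", 1:5)] <- as.list(c(-0.5, -0.5, -0.5, -0.5, 2))
  flex <- simulate_behavior_session(tr, "digit_flexion", n_trials = 100,
                                    seed = 38)
  rates <- vapply(1:5, function(d) {
    trl <- flex$trials[flex$trials$cued_digit == d, ]
    t_ch <- flex$spikes$time_s[flex$spikes$channel_id == ch]
    mean(corticolink:::count_in_intervals(t_ch, trl$phase_start_s,
                                          trl$phase_end_s))
  }, numeric(1))
  expect_equal(which.max(rates), 5)
})

test_that("center-out cosine tuning recovers preferred directions within 15 degrees", {
  tr <- ground_truth(seed = 39)
  co <- simulate_behavior_session(tr, "center_out", n_trials = 80, seed = 40)
  theta_t <- 2 * pi * (0:7) / 8
  err <- vapply(seq_len(20), function(i) {
    ch <- tr$m1$channel_id[i]
    t_ch <- co$spikes$time_s[co$spikes$channel_id == ch]
    r <- vapply(1:8, function(tg) {
      trl <- co$trials[co$trials$target_id == tg, ]
      mean(corticolink:::count_in_intervals(t_ch, trl$phase_start_s,
                                            trl$phase_end_s) / 1.5)
    }, numeric(1))
    fit <- stats::lm(r ~ cos(theta_t) + sin(theta_t))
    pd <- atan2(stats::coef(fit)[3], stats::coef(fit)[2])
    pd_true <- atan2(tr$m1$tune_y[i], tr$m1$tune_x[i])
    d <- abs(pd - pd_true) %% (2 * pi)
    min(d, 2 * pi - d) * 180 / pi
  }, numeric(1))
  ## strongly planar-tuned channels recover their preferred direction
  strong <- vapply(seq_len(20), function(i) {
    sqrt(tr$m1$tune_x[i]^2 + tr$m1$tune_y[i]^2) > 15
  }, logical(1))
  expect_true(all(err[strong] < 15))
})

test_that("generated spike counts match integrated intensity in arbitrary windows", {
  fix <- null_session()
  ses <- fix$session
  lam <- fix$truth$m1$lambda0_hz
  wins <- tibble::tibble(start = c(10, 50, 100), end = c(12, 55, 101))
  for (i in seq_len(5)) {
    ch <- fix$truth$m1$channel_id[i]
    t_ch <- ses$spikes$time_s[ses$spikes$channel_id == ch]
    for (k in seq_len(nrow(wins))) {
      n <- corticolink:::count_in_intervals(t_ch, wins$start[k], wins$end[k])
      mu <- lam[i] * (wins$end[k] - wins$start[k])
      expect_lt(abs(n - mu), 3 * sqrt(mu) + 3)
    }
  }
})
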