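mk_pulses <- function(n = 100, freq = 100, onset = 1) {
  stim_train(101L, onset_s = onset, duration_s = n / freq, frequency_hz = freq)
}

test_that("the PTA measures per-bin spike probability with a masked blank", {
  pl <- mk_pulses(100)
  ## no spikes -> all probabilities 0
  empty <- spike_table(integer(), numeric())
  p0 <- compute_pta(empty, pl, channels = 1L)
  expect_true(all(p0$prob == 0))
  expect_equal(nrow(p0), 20)           # 10 ms / 0.5 ms
  expect_equal(sum(!p0$valid), 4)      # first 2 ms masked

  ## one spike at pulse + 3.2 ms after every pulse -> bin [3.0, 3.5) prob 1
  sp <- spike_table(1L, pl$pulse_time_s + 0.0032)
  p1 <- compute_pta(sp, pl)
  expect_equal(p1$prob[p1$t_lo_ms == 3.0], 1)
  expect_equal(sum(p1$prob), 1)

  expect_error(compute_pta(sp, pl[0, ]), "pulses")
})

test_that("Poisson background gives the closed-form bin probability", {
  ## P(>=1 spike in 0.5 ms at 20 Hz) = 1 - exp(-20 * 5e-4)
  pl <- mk_pulses(1500, onset = 0.5)
  sp <- poisson_spikes(20, 16)
  p <- compute_pta(sp, pl)
  pv <- p$prob[p$valid]
  theo <- 1 - exp(-20 * 5e-4)
  expect_lt(abs(mean(pv) - theo), 4 * sqrt(theo / (1500 * 16)))
})

test_that("the locking index is peak-region mean minus median, ties earliest", {
  flat <- tibble::tibble(channel_id = 1L, bin = 0:19,
                         t_lo_ms = (0:19) * 0.5,
                         prob = 0.05, valid = rep(c(FALSE, TRUE), c(4, 16)))
  expect_equal(phase_locking_index(flat)$index, 0)

  single <- flat
  single$prob <- 0
  single$prob[10] <- 0.9
  expect_equal(phase_locking_index(single)$index, 0.3)

  ## two equal peaks: the earlier one is used (same index here by symmetry,
  ## but the peak bin must be deterministic)
  double <- flat
  double$prob <- 0
  double$prob[c(8, 14)] <- 0.6
  expect_equal(phase_locking_index(double)$index, 0.2)
})

test_that("locking significance separates direct from indirect drive", {
  tr <- ground_truth(p_couple = 0, p_direct_pair = 0, seed = 61)
  s1c <- tr$s1$electrode_id[1]
  direct_ch <- tr$m1$channel_id[1]
  indirect_ch <- tr$m1$channel_id[2]
  tr <- set_pair_coupling(tr, s1c, direct_ch, direct = TRUE, p_direct = 0.3,
                          mu_lat_ms = 4, sigma_lat_ms = 0.3)
  tr <- set_pair_coupling(tr, s1c, indirect_ch, g_base_hz = 30)
  ses <- simulate_passive_session(tr, s1_channels = s1c, seed = 62)
  pl <- ses$pulses
  res <- locking_significance(ses$spikes, pl,
                              channels = c(direct_ch, indirect_ch,
                                           tr$m1$channel_id[3]),
                              n_shuffles = 1000, seed = 63)
  expect_true(res$significant[res$channel_id == direct_ch])
  ## a strong rate increase without pulse locking must NOT be flagged
  expect_false(res$significant[res$channel_id == indirect_ch])
  expect_false(res$significant[res$channel_id == tr$m1$channel_id[3]])
  expect_error(locking_significance(ses$spikes, pl, n_shuffles = 50), "100")
})

test_that("latency and jitter estimates recover injected timing", {
  tr <- ground_truth(p_couple = 0, p_direct_pair = 0, seed = 64)
  s1c <- tr$s1$electrode_id[1]
  chans <- tr$m1$channel_id[1:3]
  for (i in 1:3) {
    tr <- set_pair_coupling(tr, s1c, chans[i], direct = TRUE, p_direct = 0.5,
                            mu_lat_ms = c(3, 4, 5)[i], sigma_lat_ms = 0.5)
  }
  ses <- simulate_passive_session(tr, s1_channels = s1c, seed = 65)
  lat <- latency_jitter(ses$spikes, ses$pulses, channels = chans,
                        n_resamples = 2000, seed = 66)
  expect_equal(lat$latency_ms, c(3, 4, 5), tolerance = 0.5 / 3)
  expect_equal(order(lat$latency_ms), 1:3)

  ## all evoked spikes at exactly pulse + 4.1 ms -> latency 4.25, jitter 0
  pl <- mk_pulses(200)
  sp <- spike_table(1L, pl$pulse_time_s + 0.0041)
  l2 <- latency_jitter(sp, pl, n_resamples = 200, seed = 67)
  expect_equal(l2$latency_ms, 4.25)
  expect_equal(l2$jitter_ms2, 0)

  expect_warning(
    latency_jitter(sp, pl, n_resamples = 50, significant = FALSE, seed = 68),
    "not significantly"
  )
})

test_that("latency is consistent across frequencies unless the response aliases", {
  withr::local_seed(69)
  ## genuine 4-ms responder
  onsets <- list(`25` = 40, `50` = 20, `100` = 10)
  mk <- function(freq, n) stim_train(101L, 1, duration_s = n / freq,
                                     frequency_hz = freq)
  pls <- list(`25` = mk(25, 500), `50` = mk(50, 1000), `100` = mk(100, 2000))
  sp_true <- spike_table(1L, unlist(lapply(pls, function(p) {
    hit <- runif(nrow(p)) < 0.4
    p$pulse_time_s[hit] + 0.004 + rnorm(sum(hit), 0, 2e-4)
  })))
  res <- latency_consistency(sp_true, pls, channels = 1L, n_shuffles = 500,
                             n_resamples = 500, seed = 70)
  expect_true(all(res$significant))
  expect_lt(max(res$spread_ms), 0.5)

  ## 12-ms responder: at 100 Hz the apparent latency wraps to 2 ms
  sp_alias <- spike_table(1L, unlist(lapply(pls, function(p) {
    hit <- runif(nrow(p)) < 0.4
    p$pulse_time_s[hit] + 0.012 + rnorm(sum(hit), 0, 2e-4)
  })))
  res2 <- latency_consistency(sp_alias, pls, channels = 1L, n_shuffles = 500,
                              n_resamples = 500, seed = 71)
  lat100 <- res2$latency_ms[res2$frequency_hz == 100]
  lat50 <- res2$latency_ms[res2$frequency_hz == 50]
  expect_lt(lat100, 3)
  expect_gt(lat50, 11)
  expect_gt(max(res2$spread_ms, na.rm = TRUE), 5)
})
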