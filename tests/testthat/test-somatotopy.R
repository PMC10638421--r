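# A tiny deterministic flexion session: channel rates set exactly per digit.
mk_flexion_fixture <- function(rates_by_digit, reps = 12) {
  ## rates_by_digit: named list channel -> numeric(5) Hz during flexion
  digits <- rep(1:5, each = reps)
  onset <- 2 + (seq_along(digits) - 1) * 3
  trials <- tibble::tibble(
    trial_id = seq_along(digits), condition = "digit_flexion",
    phase_start_s = onset, phase_end_s = onset + 0.5,
    cued_digit = digits
  )
  sp <- purrr::imap_dfr(rates_by_digit, function(r5, ch) {
    times <- unlist(lapply(seq_along(digits), function(k) {
      rate <- r5[digits[k]]
      if (rate == 0) return(numeric(0))
      ## regular spacing aligned to the 20-ms bins: integer count per bin
      seq(onset[k] + 0.5 / rate, onset[k] + 0.5 - 1e-9, by = 1 / rate)
    }))
    tibble::tibble(channel_id = as.integer(ch), time_s = times)
  })
  list(spikes = spike_table(sp$channel_id, sp$time_s), trials = trials)
}

test_that("motor map modulation follows its defining arithmetic", {
  ## rates in a 1:1:1:1:6 pattern, e.g. (10,10,10,10,60) Hz, give
  ## modulations (-0.5, -0.5, -0.5, -0.5, +2); multiples of 50 Hz make every
  ## 20-ms PETH bin carry an exact integer count so the result is exact
  fx <- mk_flexion_fixture(list(`2` = c(50, 50, 50, 50, 300)))
  ## channel 3 fires at a constant 100 Hz throughout (mid-bin phase so no
  ## spike sits exactly on a PETH bin edge): no digit preference
  const <- regular_spikes(100, max(fx$trials$phase_end_s) + 2, channel = 3L)
  spikes <- spike_table(c(fx$spikes$channel_id, const$channel_id),
                        c(fx$spikes$time_s, const$time_s + 0.005))
  mm <- motor_map(spikes, fx$trials)
  v2 <- mm$value[mm$channel_id == 2]
  expect_equal(v2, c(-0.5, -0.5, -0.5, -0.5, 2.0))
  ## equal rates across digits -> all modulations 0
  v3 <- mm$value[mm$channel_id == 3]
  expect_equal(v3, rep(0, 5))
})

test_that("projection maps normalize within digit and demand PF labels", {
  am <- array_map(ground_truth(seed = 91))
  ## uniform coupling: every normalized value must be 1
  s1 <- am$electrode_id[am$region == "S1"]
  res <- tidyr::expand_grid(motor_channel = c(2L, 3L, 4L), stim_channel = s1)
  res$z <- 5
  pm <- projection_map(res, am)
  expect_true(all(abs(pm$value - 1) < 1e-12))

  ## no labels -> error
  am2 <- am
  am2$pf_digit <- NA_integer_
  expect_error(projection_map(res, am2), "projected-field")

  ## a digit with no stimulating channels is excluded with a warning
  am3 <- am
  am3$pf_digit[am3$pf_digit %in% 3] <- 2L
  expect_warning(pm3 <- projection_map(res, am3, digits_included = 1:4),
                 "no stimulating channels")
  expect_false(3 %in% pm3$digit)
})

test_that("grid smoothing is mass-preserving and leak-free", {
  tr <- ground_truth(seed = 92)
  am <- array_map(tr)
  chans <- tr$m1$channel_id
  const <- new_digit_map_for_test(chans, value = 1.5)
  sm <- smooth_map(const, am)
  expect_equal(sm$value, rep(1.5, length(chans)))

  ## delta at an interior electrode: 4-fold symmetric neighbors equal
  delta <- new_digit_map_for_test(chans, value = 0)
  center <- chans[tr$m1$grid_row == 5 & tr$m1$grid_col == 5]
  delta$value[delta$channel_id == center] <- 1
  sm2 <- smooth_map(delta, am)
  nb <- function(dr, dc) {
    id <- chans[tr$m1$grid_row == 5 + dr & tr$m1$grid_col == 5 + dc]
    sm2$value[sm2$channel_id == id]
  }
  ## the wired grid is exactly symmetric across its main diagonal, so
  ## row-neighbors and column-neighbors of a diagonal cell are exactly equal;
  ## opposite neighbors agree up to the tiny edge-renormalization difference
  expect_equal(nb(1, 0), nb(0, 1))
  expect_equal(nb(-1, 0), nb(0, -1))
  expect_equal(nb(1, 0), nb(-1, 0), tolerance = 1e-3)
  expect_gt(sm2$value[sm2$channel_id == center], nb(1, 0))
})

test_that("gradient maps give +/-1 for monotone profiles and mask constants", {
  chans <- c(2L, 3L, 4L)
  inc <- tibble::tibble(channel_id = rep(chans, each = 5),
                        digit = rep(1:5, 3),
                        value = c(1:5, 5:1, rep(2, 5)))
  g <- gradient_map(inc)
  expect_equal(g$rho[g$channel_id == 2], 1)
  expect_equal(g$rho[g$channel_id == 3], -1)
  expect_true(is.na(g$rho[g$channel_id == 4]))
})

test_that("somatotopic bias doubles matched-digit activation after normalization", {
  ## beta = 2 generator: matched cells ~ 2x unmatched after within-digit
  ## normalization, recovered through the full modulation pipeline
  fx <- beta2_fixture()
  tr <- fx$truth
  pm <- fx$pm
  pref <- tr$m1$pref_digit[match(pm$channel_id, tr$m1$channel_id)]
  matched <- pm$value[pm$digit == pref]
  unmatched <- pm$value[pm$digit != pref]
  ratio <- mean(matched) / mean(unmatched)
  expect_gt(ratio, 1.4)
})

test_that("matched/unmatched and preference-profile tests detect the linkage", {
  fx <- beta2_fixture()
  flex <- simulate_behavior_session(fx$truth, "digit_flexion", seed = 96)
  mm_raw <- motor_map(flex$spikes, flex$trials)
  pm_raw <- projection_map(fx$mod, fx$session$array)
  mvu <- matched_vs_unmatched(mm_raw, pm_raw)
  expect_lt(mvu$p_value, 0.001)
  expect_gt(mvu$median_matched, mvu$median_unmatched)

  ## destruction control: shuffling the motor map across channels kills it
  mm_shuf <- mm_raw
  perm <- withr::with_seed(97, sample(unique(mm_raw$channel_id)))
  mm_shuf$channel_id <- perm[match(mm_shuf$channel_id,
                                   unique(mm_raw$channel_id))]
  mvu_shuf <- matched_vs_unmatched(mm_shuf, pm_raw)
  expect_gt(mvu_shuf$p_value, 0.001)

  prof <- preference_profile_analysis(mm_raw, pm_raw, fx$session$array,
                                      n_shuffles = 500, seed = 98)
  expect_lt(prof$p_shuffle, 0.01)
  expect_lt(prof$kruskal_p, 0.001)
  ## Monotone-decreasing mean susceptibility by preference rank
  expect_true(all(diff(prof$rank_curve$mean_value) < 0))
  ## smoothing-order robustness: smoothed maps reach the same conclusion
  mvu_sm <- matched_vs_unmatched(
    smooth_map(mm_raw, fx$session$array),
    smooth_map(pm_raw, fx$session$array)
  )
  expect_lt(mvu_sm$p_value, 0.001)

  ## exact-identity case: projection profile equal to motor profile -> r = 1
  prof_id <- preference_profile_analysis(mm_raw, mm_raw, fx$session$array,
                                         n_shuffles = 100, seed = 99)
  expect_true(all(abs(prof_id$per_channel$r - 1) < 1e-12))
})

test_that("activation-pattern correlations reflect array membership and distance", {
  fx <- beta2_fixture()
  pc <- pattern_correlation(fx$mod, fx$session$array)
  expect_lt(pc$within_vs_between$p.value, 0.001)
  expect_gt(mean(pc$pairs$r[pc$pairs$same_array]),
            mean(pc$pairs$r[!pc$pairs$same_array]))
  slope <- stats::coef(pc$distance_fit)["dist_um"]
  expect_lt(slope, 0)

  ## identical activation vectors correlate perfectly
  zz <- withr::with_seed(100, rnorm(40))
  res <- tidyr::expand_grid(motor_channel = 1:40,
                            stim_channel = c(101L, 102L))
  res$z <- rep(zz, each = 2)
  same <- stats::cor(res$z[res$stim_channel == 101],
                     res$z[res$stim_channel == 102])
  expect_equal(same, 1)
})
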