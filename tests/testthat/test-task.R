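# Deterministic rate-table builder for the ANOVA/classifier arithmetic.
mk_rate_table <- function(n_trials_per_cell = 10, effect = function(ph, a) 0,
                          noise_sd = 1, baseline = function(ph) 10,
                          channels = 1:4, seed = 1) {
  withr::with_seed(seed, {
    design <- tidyr::expand_grid(
      phase = c("squeeze", "grasp", "transport"),
      amplitude_ua = c(20, 32, 44, 56),
      rep = seq_len(n_trials_per_cell)
    )
    design$trial_id <- seq_len(nrow(design))
    purrr::map_dfr(channels, function(ch) {
      mu <- mapply(effect, design$phase, design$amplitude_ua) + ch
      tibble::tibble(
        channel_id = ch, trial_id = design$trial_id, phase = design$phase,
        amplitude_ua = design$amplitude_ua,
        rate_hz = mu + rnorm(nrow(design), 0, noise_sd),
        baseline_hz = vapply(design$phase, baseline, numeric(1)) +
          rnorm(nrow(design), 0, noise_sd / 4)
      )
    })
  })
}

test_that("phase rates extract exact windows and baselines", {
  trials <- tibble::tibble(
    trial_id = 1:2, condition = "squeeze",
    phase_start_s = c(10, 20), phase_end_s = c(11, 21),
    amplitude_level_ua = c(20, 56),
    baseline_start_s = c(9.5, 19.5), baseline_end_s = c(10, 20)
  )
  sp <- regular_spikes(10, 30)   # constant 10 Hz
  pr <- phase_rates(sp, trials)
  expect_equal(pr$rate_hz, c(10, 10))
  expect_equal(pr$baseline_hz, c(10, 10))

  ## short phase dropped with a warning
  trials2 <- trials
  trials2$phase_end_s[2] <- 20.4
  expect_warning(pr2 <- phase_rates(sp, trials2), "dropped")
  expect_equal(nrow(pr2), 1)
})

test_that("the two-factor ANOVA calibrates and detects interactions", {
  ## additive effects: interaction significant in about 5% of channels
  rt_add <- mk_rate_table(effect = function(ph, a) {
    2 * (ph == "transport") + 0.05 * a
  }, channels = 1:40, seed = 2)
  an <- anova_task_amp(rt_add)
  expect_lt(mean(an$p_interaction < 0.05), 0.18)
  expect_gt(mean(an$p_amp < 0.05), 0.95)
  expect_lt(median(an$td_index, na.rm = TRUE), 0.25)

  ## task-gated amplitude slope: interaction large
  rt_int <- mk_rate_table(effect = function(ph, a) {
    (0.02 + 0.25 * (ph == "transport")) * a
  }, channels = 1:10, seed = 3)
  an2 <- anova_task_amp(rt_int)
  expect_true(all(an2$p_interaction < 0.001))
  expect_gt(median(an2$td_index, na.rm = TRUE),
            median(an$td_index, na.rm = TRUE))

  ## zero-variance channel masked
  rt0 <- mk_rate_table(channels = 1, noise_sd = 0,
                       effect = function(ph, a) 0, seed = 4)
  rt0$rate_hz <- 5
  expect_true(anova_task_amp(rt0)$masked)
})

test_that("modulation-vs-baseline analysis is null for baseline-independent gating", {
  rt <- mk_rate_table(effect = function(ph, a) 0.05 * a, channels = 1:30,
                      baseline = function(ph) 10, seed = 5)
  mv <- modulation_vs_baseline(rt)
  expect_true(all(abs(mv$per_channel_phase$baseline_norm - 1) < 0.1))
  expect_gt(mv$friedman$p.value, 0.05)

  ## saturation generator: modulation inversely related to baseline
  rt_sat <- mk_rate_table(
    effect = function(ph, a) 0.002 * a * (100 - 6 * (ph == "transport") * 10),
    baseline = function(ph) 10 + 30 * (ph == "transport"),
    channels = 1:30, seed = 6
  )
  mv2 <- modulation_vs_baseline(rt_sat)
  expect_lt(mv2$correlation, -0.2)
  expect_lt(mv2$friedman$p.value, 0.05)
})

test_that("amplitude classifiers score perfectly on separable data and at chance on shuffles", {
  ## perfectly separable: rate encodes amplitude exactly
  rt <- mk_rate_table(effect = function(ph, a) a, noise_sd = 0.01,
                      channels = 1:4, seed = 7)
  acc <- amplitude_classifier(rt)
  expect_true(all(acc$accuracy[acc$train_condition == acc$test_condition] == 1))

  ## shuffled labels: near chance (1/4)
  rt_shuf <- rt
  rt_shuf$amplitude_ua <- withr::with_seed(8, {
    unsplit(lapply(split(rt_shuf$amplitude_ua, rt_shuf$channel_id), sample),
            rt_shuf$channel_id)
  })
  ## one shared shuffle across channels to keep trials coherent
  perm <- withr::with_seed(9, sample(unique(rt$trial_id)))
  lut <- rt$amplitude_ua[match(perm, rt$trial_id)]
  rt_shuf <- rt
  rt_shuf$amplitude_ua <- lut[match(rt_shuf$trial_id, unique(rt$trial_id))]
  acc2 <- amplitude_classifier(rt_shuf)
  within <- acc2$accuracy[acc2$train_condition == acc2$test_condition]
  expect_true(all(abs(within - 0.25) < 3.5 * sqrt(0.25 * 0.75 / 40)))
})

test_that("the target classifier is perfect for a perfectly coding channel", {
  ## one channel whose rate equals 10 * target id during the decision window
  targets <- rep(1:8, each = 6)
  onset <- 2 + (seq_along(targets) - 1) * 3
  trials <- tibble::tibble(
    trial_id = seq_along(targets), condition = "grasp",
    phase_start_s = onset, phase_end_s = onset + 1,
    target_id = targets
  )
  times <- unlist(lapply(seq_along(targets), function(k) {
    seq(onset[k] - 0.4, onset[k] + 0.6 - 1e-9,
        length.out = 10 * targets[k] + 10)
  }))
  sp <- spike_table(1L, times)
  tc <- target_classifier(sp, trials, min_rate_hz = 0.5)
  expect_equal(tc$accuracy, 1)
  expect_equal(tc$chance, 1 / 8)
  ## rate filter: no channel passes an absurd threshold
  expect_error(target_classifier(sp, trials, min_rate_hz = 1e6), "rate filter")
})

test_that("the center-out variant decodes direction-tuned populations", {
  tr <- ground_truth(seed = 101)
  co <- simulate_behavior_session(tr, "center_out", n_trials = 80, seed = 102)
  tc <- target_classifier(co$spikes, co$trials, variant = "lda_pc")
  expect_gt(tc$accuracy, 0.5)   # chance 0.125
})
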