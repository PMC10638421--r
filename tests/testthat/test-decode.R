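test_that("the indirect OLE inverts a noiseless linear population exactly", {
  withr::local_seed(111)
  n_ch <- 30; n_bins <- 400
  B <- matrix(rnorm(n_ch * 3, sd = 20), n_ch, 3)
  b0 <- runif(n_ch, 5, 25)
  V <- matrix(rnorm(n_bins * 3, sd = 0.2), n_bins, 3)
  R <- rep(1, n_bins) %*% t(b0) + V %*% t(B)
  dec <- fit_ole(R, V, lambda = 0)
  expect_equal(decode_velocity(dec, R), V, tolerance = 1e-8)
  ## all-baseline rates decode to zero velocity
  R0 <- rep(1, 5) %*% t(b0)
  expect_equal(decode_velocity(dec, R0), matrix(0, 5, 3), tolerance = 1e-8)
  ## rank-deficient inversion at lambda = 0 is refused
  B1 <- B; B1[, 2] <- B1[, 1]; B1[, 3] <- B1[, 1]
  R1 <- rep(1, n_bins) %*% t(b0) + (V %*% t(B1))
  expect_error(fit_ole(R1, V, lambda = 0), "lambda")
})

test_that("ridge shrinkage monotonically contracts decoded velocity", {
  withr::local_seed(112)
  n_ch <- 20
  B <- matrix(rnorm(n_ch * 3, sd = 20), n_ch, 3)
  b0 <- runif(n_ch, 5, 25)
  V <- matrix(rnorm(200 * 3, sd = 0.2), 200, 3)
  R <- rep(1, 200) %*% t(b0) + V %*% t(B) + matrix(rnorm(200 * n_ch), 200)
  norms <- vapply(c(0, 1, 10, 100, 1000), function(l) {
    dec <- fit_ole(R, V, lambda = l)
    mean(sqrt(rowSums(decode_velocity(dec, R)^2)))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("tidy and glance expose the decoder's encoding model", {
  withr::local_seed(113)
  V <- matrix(rnorm(300), 100, 3)
  R <- matrix(rpois(100 * 6, 10), 100, 6) + V %*% t(matrix(rnorm(18), 6, 3))
  dec <- fit_ole(R, V)
  td <- generics::tidy(dec)
  expect_equal(nrow(td), 6)
  expect_named(td, c("channel", "b0_hz", "bx", "by", "bz", "r2"))
  gl <- generics::glance(dec)
  expect_equal(gl$n_channels, 6)
  expect_equal(gl$lambda, dec$lambda)
})

test_that("feedback trains follow the stated amplitude schedules", {
  lin <- build_stim_train("linear", c(0, 1))
  expect_equal(nrow(lin), 100)
  expect_true(all(lin$amplitude_ua == 52))

  bio <- build_stim_train("biomimetic", c(0, 1))
  expect_equal(sum(bio$amplitude_ua == 72), 40)
  expect_equal(sum(bio$amplitude_ua == 32), 60)
  expect_equal(bio$amplitude_ua[1:20], rep(72, 20))
  expect_equal(bio$amplitude_ua[81:100], rep(72, 20))

  ## short contact: onset transient takes precedence, offset truncated
  short <- build_stim_train("biomimetic", c(0, 0.3))
  expect_equal(nrow(short), 30)
  expect_true(all(short$amplitude_ua == 72))

  expect_equal(nrow(build_stim_train("none", c(0, 1))), 0)
})

test_that("cathodal charge favors biomimetic trains only beyond the crossover", {
  charge <- function(policy, dur) {
    cathodal_charge_nc(build_stim_train(policy, c(0, dur)))
  }
  ## the paper's 1-s contact: 40*72 + 60*32 = 4800 vs 100*52 = 5200 uA-pulses
  expect_equal(charge("biomimetic", 1), 4800 * 200 / 1000)
  expect_equal(charge("linear", 1), 5200 * 200 / 1000)
  ## equality at 0.8 s, biomimetic strictly cheaper beyond
  expect_equal(charge("biomimetic", 0.8), charge("linear", 0.8))
  for (d in c(0.9, 1, 2, 5)) {
    expect_lt(charge("biomimetic", d), charge("linear", d))
  }
  ## and the gap grows with contact duration
  gaps <- vapply(c(1, 2, 5, 10), function(d) {
    charge("linear", d) - charge("biomimetic", d)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  ## below the crossover the transients dominate and linear is cheaper
  expect_gt(charge("biomimetic", 0.5), charge("linear", 0.5))
})

test_that("outcome statistics handle identical and contrasting outcome sets", {
  oc <- tibble::tibble(
    condition = rep(c("none", "linear"), each = 60),
    trial = rep(1:60, 2), target_id = 1L,
    success = TRUE, path_length_m = rep(seq(0.2, 0.3, length.out = 60), 2)
  )
  st <- outcome_stats(oc)
  expect_equal(st$failure_tests$p_value, 1)
  expect_equal(st$path_tests$ks_stat, 0)

  ## 23/60 vs 7/60 failures: chi-squared matches the closed form
  oc2 <- oc
  oc2$success[oc2$condition == "linear"][1:23] <- FALSE
  oc2$success[oc2$condition == "none"][1:7] <- FALSE
  st2 <- outcome_stats(oc2)
  tab <- matrix(c(7, 53, 23, 37), 2, byrow = TRUE)
  exp_chi <- sum((tab - outer(rowSums(tab), colSums(tab)) / 120)^2 /
                   (outer(rowSums(tab), colSums(tab)) / 120))
  expect_equal(st2$failure_tests$chisq, exp_chi)
  expect_lt(st2$failure_tests$p_value, 0.001)

  ## shifted path-length distributions are detected by KS
  oc3 <- oc
  oc3$path_length_m[oc3$condition == "linear"] <-
    oc3$path_length_m[oc3$condition == "linear"] + 0.2
  expect_lt(outcome_stats(oc3)$path_tests$ks_p, 1e-6)
})

test_that("zero contamination makes the three policies indistinguishable", {
  sc <- feedback_scenario_truth(seed = 115, mean_shift_hz = 0, sd_shift_hz = 0,
                                bias_ref_ms = 0)
  tr <- sc$truth
  tr$pairs$g_base_hz <- 0
  train <- simulate_decode_training(tr, n_trials = 24, seed = 116)
  dec <- fit_ole(train$rates, train$kinematics)
  oc <- dplyr::bind_rows(lapply(c("none", "linear", "biomimetic"), function(p) {
    run_closed_loop(tr, dec, p, n_trials = 24,
                    stim_channels = sc$stim_channels, seed = 117)
  }))
  st <- outcome_stats(oc)
  expect_true(all(st$failure_tests$p_value > 0.05))
  expect_true(all(st$path_tests$ks_p > 0.05))
})
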