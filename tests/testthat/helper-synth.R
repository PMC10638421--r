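# Shared synthetic fixtures, built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, fixture_env)) {
    assign(name, force(expr), fixture_env)
  }
  get(name, fixture_env)
}

# A small uncoupled cortex and passive session (4 stim channels).
null_session <- function() {
  memo("null_session", {
    tr <- ground_truth(p_couple = 0, p_direct_pair = 0, seed = 1001)
    ses <- simulate_passive_session(tr, s1_channels = tr$s1$electrode_id[1:4],
                                    seed = 1002)
    list(truth = tr, session = ses)
  })
}

# Homogeneous Poisson spike table on one channel.
poisson_spikes <- function(rate_hz, t_end, seed = 1, channel = 1L) {
  withr::with_seed(seed, {
    n <- rpois(1, rate_hz * t_end)
    spike_table(channel, sort(runif(n, 0, t_end)))
  })
}

# Deterministic regular spike train.
regular_spikes <- function(rate_hz, t_end, channel = 1L) {
  spike_table(channel, seq(0, t_end - 1 / rate_hz, by = 1 / rate_hz))
}

# Single-digit map with a given constant value (for smoothing tests).
new_digit_map_for_test <- function(channels, value) {
  corticolink:::new_digit_map(
    tibble::tibble(channel_id = channels, digit = 1L, value = value),
    source = "motor"
  )
}

# A beta = 2 cortex with its passive session and modulation results,
# shared by the somatotopy tests.
beta2_fixture <- function() {
  memo("beta2", {
    tr <- ground_truth(beta = 2, seed = 93)
    ses <- simulate_passive_session(tr, seed = 94)
    null <- baseline_null(ses$spikes, intertrial_periods(ses),
                          n_pairs_per_draw = 15, seed = 95)
    mod <- stim_modulation(ses$spikes, ses$pulses, null)
    list(truth = tr, session = ses, mod = mod,
         pm = projection_map(mod, ses$array))
  })
}
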