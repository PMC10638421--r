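# corticolink

Analysis of cortico-cortical signaling under intracortical microstimulation
(ICMS): how stimulating the hand representation of somatosensory cortex (S1)
modulates spiking in primary motor cortex (M1), and what that does to a
brain-computer interface that decodes movement from M1 while delivering ICMS
feedback.

The package is for electrophysiologists and BCI researchers working with
multielectrode event data (threshold crossings with stimulation pulse
tables). It implements, as tested tibble-in/tibble-out functions:

* **Modulation detection** — the change in firing rate between the second
  preceding a stimulation train and the train itself, z-scored against a
  bootstrap null of baseline fluctuations built from pairs of consecutive
  1-s intertrial intervals (with post-pulse blanking simulated in the null,
  so the 1.6-ms hardware blank and the 2-ms analysis blank do not bias the
  test): `baseline_null()`, `stim_modulation()`, `summarize_prevalence()`.
* **Pulse locking** — pulse-triggered averages in 0.5-ms bins, a
  phase-locking index (mean of the peak bin and its neighbors minus the
  median over valid bins), count-matched shuffle-surrogate significance, and
  latency/jitter estimation by resampling 20% of inter-pulse intervals:
  `compute_pta()`, `phase_locking_index()`, `locking_significance()`,
  `latency_jitter()`, `latency_consistency()`.
* **Somatotopy** — motor maps from attempted single-digit movements, sensory
  projection maps from ICMS-evoked modulation grouped by projected-field
  digit, Gaussian smoothing over the array, and the matched-vs-unmatched and
  preference-profile tests of the S1-to-M1 somatotopic linkage:
  `motor_map()`, `projection_map()`, `smooth_map()`,
  `matched_vs_unmatched()`, `preference_profile_analysis()`,
  `gradient_map()`, `pattern_correlation()`.
* **Task dependence** — per-phase rate extraction, the two-factor
  (phase x amplitude) ANOVA with the interaction-to-main-effect F ratio
  (`td_index`), the modulation-vs-baseline control, and amplitude/target
  classifiers: `phase_rates()`, `anova_task_amp()`,
  `modulation_vs_baseline()`, `amplitude_classifier()`,
  `target_classifier()`.
* **Closed-loop decoding** — an indirect optimal linear estimator
  (`rate = b0 + B v` fit per channel; decoding by ridge-regularized
  inversion `v = (B'B + lambda I)^-1 B'(r - b0)`) driving a simulated
  reach-grasp-transport task under three feedback policies (none, linear
  52 uA, biomimetic 72/32/72 uA): `fit_ole()`, `build_stim_train()`,
  `run_closed_loop()`, `outcome_stats()`.
* **A synthetic cortex** with known ground truth — baseline rates, direct
  pulse-locked coupling (per-pulse probability, latency, jitter), indirect
  task-gated rate shifts, somatotopic bias, velocity tuning — so every
  stage is verified by parameter recovery: `ground_truth()`,
  `simulate_passive_session()`, `simulate_behavior_session()`,
  `feedback_scenario_truth()`.

`run_pipeline()` orchestrates the whole chain from one seed;
`inst/cli/corticolink.R` is a thin Rscript wrapper. The methods vignette
(`vignettes/corticolink-methods.Rmd`) documents the models, parameter
choices and limitations.

## Worked example

Simulate a passive stimulation session (four S1 channels, 15 one-second
100-Hz trains each at 60 uA), detect modulated pairs, and characterize the
pulse-locked ones:

```r
library(corticolink)
library(dplyr)

truth   <- ground_truth(beta = 2, seed = 42)
session <- simulate_passive_session(truth,
                                    s1_channels = truth$s1$electrode_id[1:4],
                                    seed = 43)
session
#> <icms_session>
#>   spikes: 401472 events on 96 channels
#>   pulses: 6000 in 60 trains
#>   trials: 60

null <- baseline_null(session$spikes, intertrial_periods(session),
                      n_pairs_per_draw = 15, seed = 44)
mod  <- stim_modulation(session$spikes, session$pulses, null)
count(mod, sign)
#>   sign           n
#> 1 excitatory   112
#> 2 inhibitory     4
#> 3 none         268
```

112 of 384 pairs are significantly excited and 4 inhibited at the empirical
p < 0.001 level — the mostly-excitatory mix the generator draws. Pulse
locking on the first stimulating channel:

```r
pl   <- filter(session$pulses, stim_channel == truth$s1$electrode_id[1])
lock <- locking_significance(session$spikes, pl, n_shuffles = 1000, seed = 45)
filter(lock, significant)
#>   channel_id  index        p significant n_pulses
#> 1          7 0.0596 0.000999 TRUE            1500
#> 2         21 0.187  0.000999 TRUE            1500
#> 3         38 0.117  0.000999 TRUE            1500
#> 4         58 0.0987 0.000999 TRUE            1500

latency_jitter(session$spikes, pl, channels = c(7, 21, 38, 58),
               n_resamples = 1000, seed = 46)
#>   channel_id latency_ms jitter_ms2 jitter_sd_ms
#> 1          7       3.24    0.00662       0.0813
#> 2         21       3.25    0            0
#> 3         38       5.25    0            0
#> 4         58       3.52    0.0620       0.249
```

Exactly the four direct pairs the ground truth planted on that channel are
recovered, with latencies within a quarter millisecond of the injected
values (3.14, 3.21, 5.34 and 3.44 ms) and sub-millisecond jitter. The index
stays at zero for channels that receive only indirect drive, however
strong: a uniform rate increase does not move a PTA's peak above its
median.

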