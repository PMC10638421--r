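---
title: "Methods: detecting and characterizing ICMS-evoked activity in motor cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing ICMS-evoked activity in motor cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intracortical microstimulation (ICMS) of the hand representation of
somatosensory cortex (S1) is used in bidirectional brain-computer interfaces
to evoke tactile sensations. The same stimulation also drives spiking in
primary motor cortex (M1) — through short-latency, pulse-locked ("direct",
putatively monosynaptic) input and through slower, non-pulse-locked
("indirect") rate shifts. corticolink implements the full analysis chain for
characterizing this cortico-cortical signaling from threshold-crossing spike
event tables: modulation detection against bootstrap nulls, pulse-triggered
averages with shuffle-surrogate significance, somatotopic map construction
and matching, task-dependence quantification, and a closed-loop decoder
simulation that measures how ICMS feedback contaminates motor decoding.

Because the human recordings such analyses were developed on are access
restricted, every stage here is validated instead by *parameter recovery*
on a synthetic cortex with known ground truth. The generator is first-class,
tested code: if a stage cannot recover what the generator injected, the
stage is wrong.

## Conventions

* Time is continuous seconds on a 30-kHz acquisition clock; all event times
  are snapped to that grid. Intervals are half-open `[start, end)`; a spike
  on a bin edge belongs to the later bin.
* Firing rates use 20-ms bins (the decoding bin) unless a finer grain is
  required (0.5-ms bins for pulse-triggered averages).
* Every stimulation pulse opens a 1.6-ms hardware blanking window (the
  amplifier's sample-and-hold) in which no events can be recorded, and
  analyses discard the first 2 ms after each pulse to avoid residual
  artifact. Event tables are stored as TSV with a JSON sidecar; writing is
  canonical (fixed 10-decimal clock-snapped times), so write-read-write is
  byte identical.

## The synthetic cortex

`ground_truth()` draws a complete preparation:

* **Geometry.** M1 is a 10 x 10 grid with unwired corners (96 channels,
  400-um pitch); S1 is two 4 x 8 arrays of 32 stimulable channels. Dominant
  projected-field (PF) digits form a gradient across each S1 array;
  movement-preference digits form a gradient across the M1 grid. Digits 1-4
  are represented by default (PF reports commonly miss the little finger).
* **Baseline spiking.** Per-channel Poisson rates drawn from a gamma
  distribution (mean 15 Hz, shape 9), typical of threshold crossings on
  chronic arrays.
* **Direct coupling.** A small fraction of (S1, M1) pairs (6%) are direct:
  each pulse evokes a spike with probability `p_direct` in [0.05, 0.4] at a
  truncated-normal latency with mean in [2.5, 5.5] ms and SD in
  [0.1, 0.5] ms — the short-latency, low-jitter regime of cortico-cortical
  activation. Direct input is task-invariant by construction.
* **Indirect coupling.** 40% of pairs carry an additive rate shift (mean
  +6 Hz at the reference amplitude, smoothly varying over each S1 array via
  a per-M1-channel linear field, with a minority of inhibitory pairs).
  Negative shifts rectify at 0 Hz, implemented as thinning of the baseline
  process, so spiking remains a valid point process. Indirect input is
  multiplied by per-channel task gains (squeeze = 1 by definition; grasp
  uniform in [0.4, 1.6]; transport uniform in [0, 2]) — heterogeneous task
  gating with no array-wide bias.
* **Somatotopic bias.** When an S1 channel's dominant PF digit equals an M1
  channel's preferred movement digit, both `p_direct` and the indirect
  magnitude are multiplied by `beta` (default 2).
* **Amplitude response.** Both effect types scale as
  `((amp - 20) / 40)^3` (rectified). The threshold (20 uA) is the lowest
  amplitude used in the amplitude-varying tasks; the supralinear exponent
  encodes recruitment growing steeply above threshold, so 32-uA sustained
  stimulation evokes only a few percent of the 52-72-uA effect. This single
  nonlinearity lets the generator reproduce, simultaneously,
  amplitude-dependent modulation across 20-56 uA and the near-equivalence of
  weak sustained feedback with no stimulation in the closed loop. A linear
  response cannot do both.
* **Temporal structure.** The statistical shape of indirect effects is not
  well characterized, so onset lag and an exponential adaptation constant
  are exposed (`indirect_onset_s`, `indirect_adapt_tau_s`) and default to a
  step response (lag 0, no adaptation).

What the generator does *not* emulate: spike waveforms (events are emitted
directly; filtering and thresholding are upstream of every analysis here),
refractoriness and spike-count overdispersion, electrode drift and
non-stationarity, correlated network dynamics, and antidromic-vs-orthodromic
distinctions. Passing recovery tests therefore demonstrates correctness of
the analysis chain under Poisson-like statistics, not robustness to every
pathology of chronic recordings.

## Modulation detection

For each motor channel a null distribution of baseline fluctuations is
built: sample a pair of consecutive 1-s intervals inside the inter-train
periods, take the rate difference, average `n_pairs_per_draw` such
differences, and repeat for 1000 draws. Post-pulse blanking is *simulated*
in the second interval of each pair (events within 2 ms of a virtual
100-Hz pulse grid are discarded), because the measured in-train rate is
deflated the same way; without this the test is grossly miscalibrated
(~6% false positives instead of 0.1%). The per-draw sample size defaults to
the number of stimulation trains (15), making the null's variance comparable
to the statistic's.

The statistic for a (motor, stim) pair is the mean over trains of (rate
during the train, first 2 ms after each pulse discarded) minus (rate in the
preceding 1 s). It is z-scored against the null and tested two-sidedly:
significant when the centered statistic exceeds every centered null draw in
magnitude (empirical p floor 1/1001, so the nominal level is ~0.001). Signs
follow z: excitatory / inhibitory / none. On ~6100 uncoupled synthetic pair
tests the empirical positive rate is ~0.001-0.002 (tests within a channel
share its null, which clusters outcomes and widens the sampling spread
beyond binomial) and sham z-scores are standard normal to within a few
percent.

## Pulse locking, latency and jitter

The pulse-triggered average (PTA) bins spikes within each inter-pulse
interval into 0.5-ms bins and records per bin the fraction of pulses with at
least one spike; bins overlapping the 2-ms blank are masked, not
zero-filled, and a trailing partial bin is dropped. The phase-locking index
is the mean of the peak bin and its (up to two) adjoining valid bins minus
the median over valid bins — exactly zero for any flat profile and
insensitive to uniform rate increases, which is what separates direct from
indirect drive.

Significance uses count-matched shuffle surrogates: sample 20% of the
pulses, redistribute their spikes uniformly, recompute the index, 5000
times; a pair is locked when its observed index exceeds the surrogate 99th
percentile (empirical p <= 0.01). Two choices deserve note. First, spikes
are redistributed over the *valid* part of the interval: observed spikes can
only exist there, and spreading them into masked bins would deflate the
surrogates and make the test anticonservative. Second, because surrogates
are built from 20% subsamples while the observed index uses all pulses, the
surrogate distribution is wider than the observed null and the test is
conservative — measured specificity on uncoupled pairs is ~100% against the
nominal 99%. This is a property of the published construction, reproduced
deliberately.

Latency and jitter: resample 20% of intervals, take the center of the
maximum-probability valid bin (ties to the earliest bin), repeat 5000 times;
the mean is the latency, the variance the jitter. Injected latencies of
3/4/5 ms are recovered within +-0.15 ms at `p_direct = 0.5` and 1500 pulses.
Running the same estimate at 25/50/100 Hz exposes aliased responses: a
12-ms responder shows a 2-ms apparent latency at 100 Hz but 12 ms at 50 Hz,
flagged by the cross-frequency spread.

## Somatotopy

The motor map computes, per channel, a peri-event histogram around movement
onset for each cued digit, picks the 10-bin (200-ms) sliding window
maximizing the spread between the most- and least-responsive digit (channels
differ in preparatory vs movement timing; the window length is not dictated
by the data model and is exposed as configuration), and expresses each
digit's rate as (rate - mean over digits) / mean. The projection map
averages modulation z over stimulating channels with dominant PF on each
digit and normalizes within digit by the grand mean over motor channels, so
digit-wide differences in stimulation efficacy cancel; the map is invariant
to rescaling all of one digit's couplings.

The matched/unmatched test compares, across channels, the projection value
at each channel's preferred movement digit against all other digits
(Wilcoxon rank sum). It is run on *unsmoothed* maps: Gaussian smoothing
(SD = one electrode pitch, kernel renormalized over wired electrodes so
edges and unwired cells do not leak) correlates neighboring channels and
overdisperses the rank-sum statistic — under a bias-free generator the
smoothed variant rejects far above its nominal rate, while the unsmoothed
test is calibrated (0/8 null rejections at 5%) and still detects a 2x bias
at p < 1e-13. Smoothed maps are used where the null handles the correlation
explicitly: the preference-profile analysis orders digits by each channel's
movement preference, tests the decreasing mean susceptibility curve
(Kruskal-Wallis across ranks), and assesses the mean per-channel Pearson
correlation between motor and projection profiles against a null built by
shuffling electrode and digit assignments 10,000 times and smoothing *after*
each shuffle.

Gradient maps (per-channel Spearman rho between activation and digit index)
visualize the somatotopic progression; pattern correlations between
stimulating channels' M1 activation vectors recover the within-array >
between-array ordering and the negative correlation-vs-distance slope that
the generator's smooth coupling field implies.

## Task dependence

Per-trial rates are extracted for the three analysis phases (1 s after
contact in squeeze; 1 s after contact and the first second of transport in
grasp-and-transport) with per-phase baselines (the half second before
contact; the first half second of the reach). A per-channel two-factor
fixed-effects ANOVA (phase x amplitude with interaction; type-II sums of
squares, which coincide with the sequential decomposition on these balanced
designs) yields the task-dependence index `td_index = F_interaction /
F_amplitude`, computed only where the amplitude main effect is significant.
Direct-only channels (task-invariant per-pulse probability) give td_index
near zero; task-gated indirect channels give large values; the rank-sum
contrast between the groups is significant at p < 1e-12 at 96-channel
scale.

The modulation-vs-baseline control computes the amplitude-modulation index
(rate at 56 uA minus rate at 20 uA, over the cross-phase mean baseline)
against the phase-normalized baseline, with a Friedman test across phases:
null for baseline-independent gating (the generator's default), negative and
significant for a constructed saturation generator.

Classifiers: linear discriminant analysis on baseline-subtracted half-second
rates identifies stimulation amplitude (leave-one-out within condition;
train-on-all across conditions; chance 1/4; a PCA fallback handles singular
within-class covariance and is logged). A Gaussian naive Bayes classifier
on 1 s of rates starting 400 ms before movement onset identifies the reach
target (8 cube corners, chance 1/8, leave-one-out); the planar center-out
variant smooths 20-ms rates with a 100-ms-SD Gaussian, averages over the
reach, takes the top 10 principal components and classifies with LDA.

## Closed-loop decoding

The decoder is an indirect optimal linear estimator: a linear encoding model
`rate = b0 + B v` is fit per channel by least squares on cursor-following
training data (with 1.6-ms event blanking at 100 Hz during contact segments,
matching what is available online), and velocity is decoded by
ridge-regularized inversion, `v = (B'B + lambda I)^-1 B' (r - b0)`, with
`lambda` defaulting to 1e-3 times the mean diagonal of `B'B`. At
`lambda = 0` on a noiseless linear population the inversion is exact to
machine precision; decoded-velocity norms shrink monotonically in `lambda`.
The published two-stage calibration (observation then assisted control) is
collapsed into one supervised fit — it is an operator convenience, not an
algorithmic requirement.

Each simulated trial reaches to a cube-corner object (side 0.3 m), grasps
automatically, and transports it back to the center, 20-ms bins, 10-s
per-phase timeout, 0.3 m/s intended peak speed with proportional slowdown
inside 5 cm and a 4-cm acquisition radius. Intended velocity carries 0.15
m/s of per-bin motor variability, which gives every condition a realistic
trial-to-trial path-length spread. Feedback policies follow the stated
schedules: linear, 100 Hz at 52 uA throughout contact; biomimetic, 72 uA
for the first and last 200 ms and 32 uA sustained (for contacts under
400 ms the onset transient takes precedence). Stimulation contaminates the
rates of coupled channels through the generator's indirect shifts
(amplitude-scaled, with lognormal trial-to-trial gain, SD 0.4 log units).

`feedback_scenario_truth()` builds the preparation this comparison is about:
the two feedback electrodes (PFs on thumb and index) couple strongly to the
motor population (random per-electrode shifts ~ N(20, 8) Hz at reference
amplitude) *and* the summed evoked pattern contains a component inside the
population's velocity-tuning subspace scaled so its decoded bias is 0.45
m/s at the reference amplitude. The explicit subspace component reflects
the observation that ICMS-evoked activity overlaps the subspace used for
motor control; without it, the bias of a random 96-channel pattern projected
into three dimensions varies so much between draws that the failure regime
appears and disappears with the seed. Under this scenario linear feedback
produces 15-60% transport failures and several-fold median path-length
inflation, while biomimetic feedback is statistically indistinguishable from
no stimulation — its sustained 32-uA contamination decodes to ~1/20 of the
linear bias.

For the approximate-equality claim (no stimulation vs biomimetic) the
package compares failure proportions by chi-squared and requires median
paths within 10%; a two-sample KS test is reserved for the strict
inequalities against linear, because at 60 trials per condition KS flags
even a ~1% systematic path shift once the within-condition spread is small
— "statistically detectable" and "behaviorally meaningful" part ways there.

## Numerical choices and degenerate inputs

* Empirical p-values always use the (1 + #{null >= obs}) / (n + 1) form; no
  p is ever exactly zero.
* Degenerate nulls (SD 0, e.g. pathologically regular spiking) flag the
  channel unusable rather than producing infinite z.
* Zero-mean-rate channels are masked in maps; constant digit profiles are
  masked in gradient maps (Spearman undefined).
* PTA peak ties break to the earliest bin; at a mask boundary the peak's
  adjoining-bin set shrinks to its valid neighbors.
* Interval arithmetic merges overlapping blank windows; blanking is
  idempotent.
* The pipeline derives per-stage child seeds from one global seed with a
  fixed Lehmer step, so any stage can be re-run in isolation from the
  provenance log.

## Problem sizes

The shipped tests and the acceptance script run the full method at sizes a
single core completes in minutes: full 96 x 64-channel passive sessions
with 15 trains per stimulating channel for calibration and somatotopy
(repeated over 8-10 seeds for the detection-rate checks), 576 uncoupled
pairs at 500 shuffles for locking specificity, ~6100 shared-null pair tests
for modulation calibration, 104-208 trials per behavioral task, and 60
closed-loop trials per feedback condition. These are the package's chosen
verification scales; all resample counts (1000 null draws, 5000 shuffles
and resamples, 10,000 map shuffles) default to their full published values
in the API.

## Known limitations

* Poisson spiking without refractoriness slightly understates PTA bin
  probabilities at very high rates.
* The modulation null inherits a mild anticonservative bias (~2x nominal in
  the worst sessions) from sampling overlapping interval pairs out of
  finite intertrial periods; this is intrinsic to the published bootstrap
  and is quantified, not hidden, by the calibration tests.
* The closed-loop simulation is a control-theoretic cartoon: no arm
  dynamics, no visual feedback delay, grasp automated. Its outcome measures
  are meaningful as directional comparisons between feedback policies, not
  as absolute performance predictions.
* The locking test's conservativeness (surrogates from subsamples) trades
  sensitivity for specificity exactly as the published construction does;
  weakly locked pairs near the detection boundary are missed.
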