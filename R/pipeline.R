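#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates simulate -> modulation -> pulse locking -> somatotopy ->
#' task dependence -> closed-loop decode on one synthetic cortex, with one
#' global seed spawning deterministic per-stage child seeds so any stage can
#' be re-run in isolation. Stage outputs are written as TSV/JSON under
#' `out_dir` when given, together with a provenance log of every stage's
#' parameters and child seed.
#'
#' @param seed Global integer seed.
#' @param out_dir Optional output directory.
#' @param config Nested list of stage parameter blocks overriding the
#'   defaults; unknown keys are ignored, missing keys fall back to defaults
#'   (recorded in the provenance log).
#' @return List of stage results: `truth`, `modulation`, `prevalence`,
#'   `locking`, `somatotopy`, `task`, `decode`, `provenance`.
#' @export
run_pipeline <- function(seed, out_dir = NULL, config = list()) {
  cfg <- utils::modifyList(list(
    truth = list(beta = 2),
    passive = list(n_trains_per_channel = 15, n_s1 = 16),
    modulation = list(n_resamples = 1000, alpha = 0.001),
    locking = list(n_shuffles = 1000, n_channels = 8),
    somatotopy = list(n_flexion_trials = 125, n_shuffles = 2000),
    task = list(n_trials = 104),
    decode = list(n_trials = 20)
  ), config)
  prov <- list(seed = seed, config = cfg)
  log_msg <- function(...) message("[corticolink] ", ...)

  log_msg("stage 1/6: synthetic cortex + passive session")
  truth <- do.call(ground_truth, c(cfg$truth, list(seed = child_seed(seed, 1))))
  ## round-robin across PF digits so every digit keeps stimulating channels
  by_digit <- split(truth$s1$electrode_id, truth$s1$pf_digit)
  s1_use <- unlist(lapply(seq_len(max(lengths(by_digit))), function(i) {
    unlist(lapply(by_digit, function(v) if (i <= length(v)) v[i]))
  }), use.names = FALSE)
  s1_use <- s1_use[seq_len(min(cfg$passive$n_s1, length(s1_use)))]
  passive <- simulate_passive_session(
    truth, n_trains_per_channel = cfg$passive$n_trains_per_channel,
    s1_channels = s1_use, seed = child_seed(seed, 2)
  )

  log_msg("stage 2/6: modulation vs baseline null")
  iti <- intertrial_periods(passive)
  null <- baseline_null(passive$spikes, iti,
                        n_resamples = cfg$modulation$n_resamples,
                        n_pairs_per_draw = cfg$passive$n_trains_per_channel,
                        seed = child_seed(seed, 3))
  mod <- stim_modulation(passive$spikes, passive$pulses, null,
                         alpha = cfg$modulation$alpha)
  prev <- summarize_prevalence(mod, passive$array)

  log_msg("stage 3/6: pulse locking")
  stim_ch <- s1_use[1]
  pl <- dplyr::filter(passive$pulses, .data$stim_channel == stim_ch)
  chans <- sort(unique(passive$spikes$channel_id))
  chans <- chans[seq_len(min(cfg$locking$n_channels, length(chans)))]
  locking <- locking_significance(passive$spikes, pl, channels = chans,
                                  n_shuffles = cfg$locking$n_shuffles,
                                  seed = child_seed(seed, 4))
  lat <- suppressWarnings(
    latency_jitter(passive$spikes, pl, channels = chans, n_resamples = 1000,
                   significant = locking$significant,
                   seed = child_seed(seed, 4))
  )
  locking <- dplyr::left_join(locking, lat, by = "channel_id")

  log_msg("stage 4/6: somatotopy")
  flex <- simulate_behavior_session(truth, "digit_flexion",
                                    n_trials = cfg$somatotopy$n_flexion_trials,
                                    seed = child_seed(seed, 5))
  mm_raw <- motor_map(flex$spikes, flex$trials)
  pm_raw <- projection_map(mod, passive$array)
  mm <- smooth_map(mm_raw, passive$array)
  pm <- smooth_map(pm_raw, passive$array)
  mvu <- matched_vs_unmatched(mm_raw, pm_raw)
  prof <- preference_profile_analysis(mm_raw, pm_raw, passive$array,
                                      n_shuffles = cfg$somatotopy$n_shuffles,
                                      seed = child_seed(seed, 6))
  somato <- list(motor_map = mm, projection_map = pm,
                 matched_vs_unmatched = mvu, profile = prof,
                 gradient = gradient_map(mm))

  log_msg("stage 5/6: task dependence")
  sq <- simulate_behavior_session(truth, "squeeze", n_trials = cfg$task$n_trials,
                                  seed = child_seed(seed, 7))
  gt <- simulate_behavior_session(truth, "grasp_transport",
                                  n_trials = cfg$task$n_trials,
                                  seed = child_seed(seed, 8))
  rt <- dplyr::bind_rows(
    phase_rates(sq$spikes, sq$trials),
    phase_rates(gt$spikes, gt$trials)
  )
  task <- list(anova = anova_task_amp(rt),
               mod_vs_baseline = modulation_vs_baseline(rt))

  log_msg("stage 6/6: closed-loop decode")
  train <- simulate_decode_training(truth, seed = child_seed(seed, 9))
  dec <- fit_ole(train$rates, train$kinematics)
  outcomes <- dplyr::bind_rows(lapply(
    c("none", "linear", "biomimetic"),
    function(pol) run_closed_loop(truth, dec, pol,
                                  n_trials = cfg$decode$n_trials,
                                  seed = child_seed(seed, 10))
  ))
  decode <- list(decoder = dec, outcomes = outcomes,
                 stats = outcome_stats(outcomes))

  res <- list(truth = truth, modulation = mod, prevalence = prev,
              locking = locking, somatotopy = somato, task = task,
              decode = decode, provenance = prov)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(mod, file.path(out_dir, "modulation_results.tsv"))
    readr::write_tsv(prev, file.path(out_dir, "prevalence_map.tsv"))
    readr::write_tsv(locking, file.path(out_dir, "locking_results.tsv"))
    readr::write_tsv(mm, file.path(out_dir, "motor_map.tsv"))
    readr::write_tsv(pm, file.path(out_dir, "projection_map.tsv"))
    readr::write_tsv(task$anova, file.path(out_dir, "task_dependence.tsv"))
    readr::write_tsv(outcomes, file.path(out_dir, "outcomes.tsv"))
    jsonlite::write_json(
      list(
        somatotopy = list(
          matched_p = mvu$p_value, mean_r = prof$mean_r,
          profile_p = prof$p_shuffle, kruskal_p = prof$kruskal_p
        ),
        decode = decode$stats$by_condition,
        provenance = prov
      ),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
  }
  res
}
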