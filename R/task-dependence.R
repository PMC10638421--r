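# Task dependence of ICMS-evoked activity: per-phase rate extraction,
# two-factor (phase x amplitude) ANOVA with the interaction/main-effect
# F-ratio index, the modulation-vs-baseline control, and the amplitude and
# target classifiers.

#' Per-trial firing rates for the analysis phases
#'
#' Extracts one rate per (channel, trial, phase) over a `window_s`-long window
#' from the phase start, plus the per-phase baseline rate: the half second
#' preceding object contact for squeeze and grasp, and the first half second
#' of the reach for transport (taken from the trial table's
#' `baseline_start_s`/`baseline_end_s` columns).
#'
#' @param spikes Spike table.
#' @param trials Trial table with per-phase rows (conditions among squeeze /
#'   grasp / transport, or any labeled phases).
#' @param window_s Analysis window from phase start (default 1 s).
#' @param baseline_s Baseline window length (default 0.5 s).
#' @param channels Channels to extract (default: all in `spikes`).
#' @return Tibble: `channel_id`, `trial_id`, `phase`, `amplitude_ua`,
#'   `rate_hz`, `baseline_hz` (plus `target_id` when present).
#' @export
phase_rates <- function(spikes, trials, window_s = 1, baseline_s = 0.5,
                        channels = NULL) {
  channels <- channels %||% sort(unique(spikes$channel_id))
  too_short <- (trials$phase_end_s - trials$phase_start_s) < window_s - 1e-9
  if (any(too_short)) {
    warning(sum(too_short), " trial phase(s) shorter than the analysis ",
            "window; dropped")
    trials <- trials[!too_short, , drop = FALSE]
  }
  has_base <- all(c("baseline_start_s", "baseline_end_s") %in% names(trials))
  purrr::map_dfr(channels, function(ch) {
    t_ch <- spikes$time_s[spikes$channel_id == ch]
    r <- count_in_intervals(t_ch, trials$phase_start_s,
                            trials$phase_start_s + window_s) / window_s
    b <- if (has_base) {
      bs <- trials$baseline_start_s
      be <- pmin(trials$baseline_end_s, trials$baseline_start_s + baseline_s)
      count_in_intervals(t_ch, bs, be) / (be - bs)
    } else {
      NA_real_
    }
    out <- tibble::tibble(
      channel_id = ch, trial_id = trials$trial_id, phase = trials$condition,
      amplitude_ua = trials$amplitude_level_ua, rate_hz = r, baseline_hz = b
    )
    if ("target_id" %in% names(trials)) out$target_id <- trials$target_id
    out
  })
}

#' Two-factor ANOVA of phase and stimulation amplitude
#'
#' Per channel, a fixed-effects ANOVA of firing rate on task phase,
#' stimulation amplitude and their interaction (type-II sums of squares via
#' model comparison; with the balanced designs generated here this equals the
#' sequential decomposition). The task-dependence index is the ratio of the
#' interaction F to the amplitude main-effect F, computed only for channels
#' with a significant amplitude effect. Zero-variance channels are masked.
#'
#' @param rate_table Output of [phase_rates()].
#' @param alpha Significance level (default 0.05).
#' @return Tibble per channel: F and p for task, amplitude and interaction,
#'   `td_index` (NA unless the amplitude effect is significant), `masked`.
#' @export
anova_task_amp <- function(rate_table, alpha = 0.05) {
  rate_table |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::group_modify(function(d, key) {
      if (stats::var(d$rate_hz) == 0 ||
          dplyr::n_distinct(d$phase) < 2 ||
          dplyr::n_distinct(d$amplitude_ua) < 2) {
        return(tibble::tibble(
          F_task = NA_real_, p_task = NA_real_, F_amp = NA_real_,
          p_amp = NA_real_, F_interaction = NA_real_,
          p_interaction = NA_real_, td_index = NA_real_, masked = TRUE
        ))
      }
      d$phase <- factor(d$phase)
      d$amp <- factor(d$amplitude_ua)
      full <- stats::lm(rate_hz ~ phase * amp, data = d)
      ## type-II: each term against the model without it (interaction last)
      no_task <- stats::lm(rate_hz ~ amp, data = d)
      no_amp <- stats::lm(rate_hz ~ phase, data = d)
      additive <- stats::lm(rate_hz ~ phase + amp, data = d)
      rss_full <- stats::deviance(full)
      df_res <- stats::df.residual(full)
      ms_res <- rss_full / df_res
      f_of <- function(reduced, extra_df) {
        ((stats::deviance(reduced) - stats::deviance(additive)) / extra_df) /
          ms_res
      }
      n_ph <- nlevels(d$phase); n_am <- nlevels(d$amp)
      F_task <- f_of(no_task, n_ph - 1)
      F_amp <- f_of(no_amp, n_am - 1)
      df_int <- (n_ph - 1) * (n_am - 1)
      F_int <- ((stats::deviance(additive) - rss_full) / df_int) / ms_res
      p_task <- stats::pf(F_task, n_ph - 1, df_res, lower.tail = FALSE)
      p_amp <- stats::pf(F_amp, n_am - 1, df_res, lower.tail = FALSE)
      p_int <- stats::pf(F_int, df_int, df_res, lower.tail = FALSE)
      tibble::tibble(
        F_task = F_task, p_task = p_task, F_amp = F_amp, p_amp = p_amp,
        F_interaction = F_int, p_interaction = p_int,
        td_index = ifelse(p_amp < alpha, F_int / F_amp, NA_real_),
        masked = FALSE
      )
    }) |>
    dplyr::ungroup()
}

#' Modulation strength vs task-dependent baseline rate
#'
#' Computes, per channel and phase, the amplitude-modulation index (mean rate
#' at the highest amplitude minus mean rate at the lowest, divided by the
#' cross-phase mean baseline) and the baseline rate normalized by its cross-
#' phase mean, then tests whether modulation tracks baseline across phases
#' with a Friedman test (channels as blocks). A negative relationship would
#' indicate saturation; task-gated modulation independent of baseline yields
#' a non-significant result.
#'
#' @param rate_table Output of [phase_rates()].
#' @return List: `per_channel_phase` tibble (`amp_mod_index`,
#'   `baseline_norm`), `friedman` htest, `correlation` (Pearson r between
#'   index and normalized baseline).
#' @export
modulation_vs_baseline <- function(rate_table) {
  amps <- range(rate_table$amplitude_ua, na.rm = TRUE)
  per <- rate_table |>
    dplyr::group_by(.data$channel_id, .data$phase) |>
    dplyr::summarise(
      hi = mean(.data$rate_hz[.data$amplitude_ua == amps[2]]),
      lo = mean(.data$rate_hz[.data$amplitude_ua == amps[1]]),
      baseline = mean(.data$baseline_hz),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::mutate(
      base_grand = mean(.data$baseline),
      amp_mod_index = (.data$hi - .data$lo) / .data$base_grand,
      baseline_norm = .data$baseline / .data$base_grand
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(is.finite(.data$amp_mod_index))
  fr <- stats::friedman.test(
    amp_mod_index ~ phase | channel_id,
    data = per[per$channel_id %in%
                 names(which(table(per$channel_id) ==
                               dplyr::n_distinct(per$phase))), ]
  )
  list(
    per_channel_phase = dplyr::select(per, "channel_id", "phase",
                                      "amp_mod_index", "baseline_norm"),
    friedman = fr,
    correlation = stats::cor(per$amp_mod_index, per$baseline_norm)
  )
}

# Features for the amplitude classifier: per-trial channel rate vectors after
# subtracting the per-channel, per-phase mean baseline.
amp_features <- function(rate_table, window_s = 0.5) {
  rate_table |>
    dplyr::group_by(.data$channel_id, .data$phase) |>
    dplyr::mutate(rate_adj = .data$rate_hz - mean(.data$baseline_hz)) |>
    dplyr::ungroup()
}

lda_loo_accuracy <- function(X, y) {
  n <- nrow(X)
  keep <- apply(X, 2, stats::var) > 1e-12
  X <- X[, keep, drop = FALSE]
  correct <- vapply(seq_len(n), function(i) {
    fit <- fit_lda_safe(X[-i, , drop = FALSE], y[-i])
    pred <- stats::predict(fit, X[i, , drop = FALSE])$class
    as.character(pred) == as.character(y[i])
  }, logical(1))
  mean(correct)
}

# MASS::lda with a ridge fallback for singular within-class covariance:
# if lda errors, project onto the principal components carrying 99.9% of the
# variance and refit (logged via message).
fit_lda_safe <- function(X, y) {
  fit <- try(suppressWarnings(MASS::lda(X, grouping = y)), silent = TRUE)
  if (!inherits(fit, "try-error")) return(fit)
  message("singular within-class covariance; refitting on principal ",
          "components")
  pc <- stats::prcomp(X)
  k <- max(1, which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= 0.999)[1] - 1)
  Xp <- pc$x[, seq_len(k), drop = FALSE]
  fit <- suppressWarnings(MASS::lda(Xp, grouping = y))
  structure(list(fit = fit, rot = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center), class = "lda_pc")
}

#' @export
predict.lda_pc <- function(object, newdata, ...) {
  Xp <- scale(newdata, center = object$center, scale = FALSE) %*% object$rot
  stats::predict(object$fit, Xp, ...)
}

#' Cross-condition stimulation-amplitude classifier
#'
#' Linear discriminant analysis identifying stimulation amplitude from the
#' motor population's baseline-subtracted rates (half-second windows after
#' contact for squeeze/grasp and after transport onset). Within-condition
#' accuracy uses leave-one-out cross-validation; cross-condition accuracy
#' trains on all trials of one condition and tests on all trials of another.
#' Chance is 1/number of amplitude levels (1/4 here).
#'
#' @param rate_table Output of [phase_rates()] on half-second windows
#'   (pass `window_s = 0.5` there to mirror the analysis).
#' @param conditions Conditions to include (default: all phases present).
#' @return Tibble: `train_condition`, `test_condition`, `accuracy`, `n_test`;
#'   diagonal entries are cross-validated.
#' @export
amplitude_classifier <- function(rate_table, conditions = NULL) {
  feat <- amp_features(rate_table)
  conditions <- conditions %||% sort(unique(feat$phase))
  mats <- purrr::map(conditions, function(cond) {
    d <- dplyr::filter(feat, .data$phase == cond)
    wide <- tidyr::pivot_wider(
      dplyr::select(d, "trial_id", "channel_id", "rate_adj", "amplitude_ua"),
      names_from = "channel_id", values_from = "rate_adj"
    )
    list(X = as.matrix(dplyr::select(wide, -"trial_id", -"amplitude_ua")),
         y = factor(wide$amplitude_ua))
  })
  names(mats) <- conditions
  tidyr::expand_grid(train_condition = conditions,
                     test_condition = conditions) |>
    dplyr::mutate(purrr::map2_dfr(
      .data$train_condition, .data$test_condition,
      function(a, b) {
        if (a == b) {
          tibble::tibble(accuracy = lda_loo_accuracy(mats[[a]]$X, mats[[a]]$y),
                         n_test = length(mats[[a]]$y))
        } else {
          keep <- apply(mats[[a]]$X, 2, stats::var) > 1e-12
          fit <- fit_lda_safe(mats[[a]]$X[, keep, drop = FALSE], mats[[a]]$y)
          pred <- stats::predict(fit, mats[[b]]$X[, keep, drop = FALSE])$class
          tibble::tibble(accuracy = mean(as.character(pred) ==
                                           as.character(mats[[b]]$y)),
                         n_test = length(mats[[b]]$y))
        }
      }
    ))
}

#' Reach-target classifier
#'
#' Confirms task engagement by decoding the intended target from M1 activity.
#' Two variants:
#' \describe{
#'   \item{naive_bayes}{Gaussian naive Bayes on mean rates over 1 s starting
#'     400 ms before movement onset, using all channels with overall mean rate
#'     above `min_rate_hz` (8 cube-corner targets; chance 1/8). Leave-one-out
#'     cross-validated.}
#'   \item{lda_pc}{Center-out variant: 20-ms binned rates smoothed with a
#'     100-ms-SD Gaussian, averaged over the reach, top 10 principal
#'     components, linear discriminant classification, leave-one-out.}
#' }
#'
#' @param spikes Spike table.
#' @param trials Trial rows carrying `target_id`; `phase_start_s` must be the
#'   movement (reach) onset. For grasp/transport tables, pass the rows of one
#'   phase so each trial appears once.
#' @param variant `"naive_bayes"` or `"lda_pc"`.
#' @param min_rate_hz Channel inclusion threshold (default 5).
#' @param n_pc Principal components for the lda_pc variant (default 10).
#' @return List: `accuracy`, `chance`, `n_trials`, `n_channels`, `variant`.
#' @export
target_classifier <- function(spikes, trials,
                              variant = c("naive_bayes", "lda_pc"),
                              min_rate_hz = 5, n_pc = 10) {
  variant <- match.arg(variant)
  trials <- trials[!is.na(trials$target_id), , drop = FALSE]
  trials <- trials[!duplicated(trials$trial_id), , drop = FALSE]
  stopifnot(nrow(trials) > 0)
  span <- range(spikes$time_s)
  overall <- spikes |>
    dplyr::count(.data$channel_id) |>
    dplyr::mutate(rate = .data$n / diff(span))
  chans <- overall$channel_id[overall$rate > min_rate_hz]
  if (length(chans) == 0) stop("no channel exceeds the rate filter")
  y <- factor(trials$target_id)
  if (variant == "naive_bayes") {
    X <- vapply(chans, function(ch) {
      t_ch <- spikes$time_s[spikes$channel_id == ch]
      count_in_intervals(t_ch, trials$phase_start_s - 0.4,
                         trials$phase_start_s + 0.6)
    }, numeric(nrow(trials)))
    correct <- vapply(seq_len(nrow(X)), function(i) {
      fit <- e1071::naiveBayes(X[-i, , drop = FALSE], y[-i])
      as.character(stats::predict(fit, X[i, , drop = FALSE])) ==
        as.character(y[i])
    }, logical(1))
    acc <- mean(correct)
  } else {
    ## smoothed binned rates averaged over the reach phase
    sm_sd_bins <- 100 / 20
    kern <- stats::dnorm(seq(-15, 15), sd = sm_sd_bins)
    kern <- kern / sum(kern)
    X <- vapply(chans, function(ch) {
      t_ch <- spikes$time_s[spikes$channel_id == ch]
      vapply(seq_len(nrow(trials)), function(k) {
        brks <- seq(trials$phase_start_s[k], trials$phase_end_s[k], by = 0.02)
        tt <- t_ch[t_ch >= brks[1] & t_ch < brks[length(brks)]]
        br <- graphics::hist(tt, breaks = brks, plot = FALSE)$counts / 0.02
        mean(stats::filter(br, kern, sides = 2), na.rm = TRUE)
      }, numeric(1))
    }, numeric(nrow(trials)))
    ## per-channel 0-1 normalization, then PCA + LDA, leave-one-out
    rng <- apply(X, 2, function(v) diff(range(v)))
    X <- sweep(sweep(X, 2, apply(X, 2, min)), 2, pmax(rng, 1e-9), "/")
    pc <- stats::prcomp(X)
    k <- min(n_pc, ncol(pc$x))
    Xp <- pc$x[, seq_len(k), drop = FALSE]
    acc <- lda_loo_accuracy(Xp, y)
  }
  list(accuracy = acc, chance = 1 / nlevels(y), n_trials = nrow(trials),
       n_channels = length(chans), variant = variant)
}
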