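# Somatotopic maps: motor maps from attempted digit flexions, sensory
# projection maps from ICMS-evoked modulation, Gaussian smoothing over the
# array, and the matched/unmatched and preference-profile tests of the
# S1->M1 somatotopic linkage.

new_digit_map <- function(tbl, source, smoothed = FALSE) {
  structure(tbl, source = source, smoothed = smoothed,
            class = c("digit_map", class(tbl)))
}

#' Motor map: digit selectivity of M1 channels
#'
#' For each motor channel, a peri-event time histogram (20-ms bins over a 2-s
#' window centered on movement start) is computed per cued digit. A sliding
#' response window of `response_window_bins` bins is chosen per channel to
#' maximize the spread between the most- and least-responsive digit (channels
#' differ in whether they are most active during preparation or movement).
#' The modulation value for digit d is (rate_d - mean over digits) / (mean
#' over digits); rows therefore sum to ~0 across digits. Channels with zero
#' mean rate are masked (NA).
#'
#' @param spikes Spike table.
#' @param flexion_trials Trial table rows with `condition == "digit_flexion"`;
#'   `phase_start_s` is the movement onset.
#' @param window_s PETH window length centered on movement start (default 2).
#' @param bin_ms PETH bin width (default 20).
#' @param response_window_bins Response-window length in bins (default 10,
#'   i.e. 200 ms).
#' @param channels Channels to map (default: all in `spikes`).
#' @return A `digit_map`: long tibble (`channel_id`, `digit`, `value`).
#' @export
motor_map <- function(spikes, flexion_trials, window_s = 2, bin_ms = 20,
                      response_window_bins = 10, channels = NULL) {
  tr <- dplyr::filter(flexion_trials, .data$condition == "digit_flexion")
  stopifnot(nrow(tr) > 0)
  digits <- sort(unique(tr$cued_digit))
  if (any(table(tr$cued_digit) < 10)) {
    warning("fewer than 10 flexions for some digit(s)")
  }
  channels <- channels %||% sort(unique(spikes$channel_id))
  w <- bin_ms / 1000
  n_bins <- floor(window_s / w + 1e-9)
  half <- window_s / 2
  ## accumulate counts[channel, bin, digit]
  acc <- array(0, dim = c(length(channels), n_bins, length(digits)))
  for (k in seq_len(nrow(tr))) {
    t0 <- tr$phase_start_s[k] - half
    d_i <- match(tr$cued_digit[k], digits)
    sel <- spikes$time_s >= t0 & spikes$time_s < t0 + n_bins * w &
      spikes$channel_id %in% channels
    if (!any(sel)) next
    ch_i <- match(spikes$channel_id[sel], channels)
    bin_i <- floor((spikes$time_s[sel] - t0) / w) + 1
    for (u in seq_along(ch_i)) {
      acc[ch_i[u], bin_i[u], d_i] <- acc[ch_i[u], bin_i[u], d_i] + 1
    }
  }
  n_per_digit <- as.numeric(table(factor(tr$cued_digit, levels = digits)))
  purrr::map_dfr(seq_along(channels), function(ci) {
    peth <- sweep(acc[ci, , , drop = TRUE], 2, n_per_digit, "/") / w  # Hz
    if (length(digits) == 1) peth <- matrix(peth, ncol = 1)
    ## window means per digit at each start position
    cs <- rbind(0, apply(peth, 2, cumsum))
    n_pos <- n_bins - response_window_bins + 1
    wm <- (cs[response_window_bins + seq_len(n_pos), , drop = FALSE] -
             cs[seq_len(n_pos), , drop = FALSE]) / response_window_bins
    score <- apply(wm, 1, max) - apply(wm, 1, min)
    best <- which.max(score)  # earliest on ties
    rate_d <- wm[best, ]
    mbar <- mean(rate_d)
    val <- if (mbar > 0) (rate_d - mbar) / mbar else rep(NA_real_,
                                                         length(digits))
    tibble::tibble(channel_id = channels[ci], digit = digits, value = val)
  }) |>
    new_digit_map("motor")
}

#' Sensory projection map from modulation results
#'
#' For each digit with at least one stimulating channel whose dominant
#' projected field lies on it, the ICMS-evoked modulation (z) of every motor
#' channel is averaged over those stimulating channels, then normalized by
#' the grand mean across motor channels for that digit. The within-digit
#' normalization removes incidental digit-wide differences in stimulation
#' efficacy.
#'
#' @param modulation_results Output of [stim_modulation()].
#' @param arraymap Array map with S1 `pf_digit` labels.
#' @param digits_included Optional digit subset.
#' @return A `digit_map` (`channel_id` = motor channel, `digit`, `value`).
#' @export
projection_map <- function(modulation_results, arraymap,
                           digits_included = NULL) {
  s1 <- dplyr::filter(arraymap, .data$region == "S1", .data$wired,
                      !is.na(.data$pf_digit))
  if (nrow(s1) == 0) stop("no S1 channels carry projected-field labels")
  res <- dplyr::inner_join(
    modulation_results,
    dplyr::select(s1, stim_channel = "electrode_id", "pf_digit"),
    by = "stim_channel"
  )
  digits <- sort(unique(res$pf_digit))
  if (!is.null(digits_included)) {
    dropped <- setdiff(digits_included, digits)
    if (length(dropped) > 0) {
      warning("digit(s) ", paste(dropped, collapse = ", "),
              " have no stimulating channels; excluded")
    }
    digits <- intersect(digits_included, digits)
  }
  res |>
    dplyr::filter(.data$pf_digit %in% digits) |>
    dplyr::group_by(channel_id = .data$motor_channel, digit = .data$pf_digit) |>
    dplyr::summarise(raw = mean(.data$z), .groups = "drop") |>
    dplyr::group_by(.data$digit) |>
    dplyr::mutate(value = .data$raw / mean(.data$raw)) |>
    dplyr::ungroup() |>
    dplyr::select("channel_id", "digit", "value") |>
    new_digit_map("projection")
}

# Gaussian smoothing matrix over the wired electrodes of the M1 grid.
# K[i, j]: contribution of channel j to channel i; rows renormalized over the
# channels actually present so edges and unwired cells cause no leakage.
smoothing_kernel <- function(arraymap, channels, sigma_elec = 1) {
  m1 <- dplyr::filter(arraymap, .data$region == "M1", .data$wired)
  pos <- m1[match(channels, m1$electrode_id), c("grid_row", "grid_col")]
  if (anyNA(pos$grid_row)) stop("channel(s) missing from the M1 array map")
  d2 <- outer(pos$grid_row, pos$grid_row, "-")^2 +
    outer(pos$grid_col, pos$grid_col, "-")^2
  exp(-d2 / (2 * sigma_elec^2))
}

#' Smooth a digit map over the electrode grid
#'
#' Convolves each digit's map with a 2D Gaussian whose SD is
#' `sigma_elec` electrode spacings (default 1), renormalizing the kernel over
#' the wired electrodes present so that edges and unwired cells do not leak
#' signal; constant maps are unchanged. Masked (NA) channels neither
#' contribute nor receive.
#'
#' @param map A `digit_map`.
#' @param arraymap Array map supplying grid geometry.
#' @param sigma_elec Kernel SD in units of electrode pitch.
#' @return The smoothed `digit_map`.
#' @export
smooth_map <- function(map, arraymap, sigma_elec = 1) {
  channels <- sort(unique(map$channel_id))
  K <- smoothing_kernel(arraymap, channels, sigma_elec)
  wide <- tidyr::pivot_wider(map, names_from = "digit",
                             values_from = "value")
  wide <- wide[match(channels, wide$channel_id), ]
  V <- as.matrix(wide[-1])
  ok <- !is.na(V)
  V0 <- ifelse(ok, V, 0)
  num <- K %*% V0
  den <- K %*% ok
  S <- ifelse(ok, num / den, NA_real_)
  out <- tibble::tibble(
    channel_id = rep(channels, times = ncol(V)),
    digit = rep(as.integer(colnames(V)), each = length(channels)),
    value = as.vector(S)
  )
  new_digit_map(dplyr::arrange(out, .data$channel_id, .data$digit),
                attr(map, "source"), smoothed = TRUE)
}

digit_map_wide <- function(map) {
  wide <- tidyr::pivot_wider(map, names_from = "digit", values_from = "value")
  wide <- wide[order(wide$channel_id), ]
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$channel_id
  m
}

#' Matched vs unmatched somatotopic activation test
#'
#' Each motor channel's preferred movement digit is the argmax of its motor-
#' map profile. The ICMS-evoked activation (projection-map value) from
#' stimulating channels whose dominant PF lies on that digit ("matched") is
#' compared against the activation from all other digits ("unmatched") with a
#' Wilcoxon rank-sum test across channels.
#'
#' @param motor,projection `digit_map`s on the same channels and digits.
#'   Unsmoothed maps are recommended here: smoothing correlates neighboring
#'   channels and overdisperses the rank-sum statistic, whereas the unsmoothed
#'   test is calibrated (and, per the smoothing-robustness check, reaches the
#'   same conclusion when the linkage is real).
#' @return One-row tibble: `statistic`, `p_value`, `median_matched`,
#'   `median_unmatched`, `n_matched`, `n_unmatched`; the per-channel values
#'   are attached as attribute `data`.
#' @export
matched_vs_unmatched <- function(motor, projection) {
  M <- digit_map_wide(motor)
  P <- digit_map_wide(projection)
  common_d <- intersect(colnames(M), colnames(P))
  common_c <- intersect(rownames(M), rownames(P))
  M <- M[common_c, common_d, drop = FALSE]
  P <- P[common_c, common_d, drop = FALSE]
  keep <- stats::complete.cases(M) & stats::complete.cases(P)
  M <- M[keep, , drop = FALSE]; P <- P[keep, , drop = FALSE]
  pref <- apply(M, 1, which.max)
  matched <- P[cbind(seq_len(nrow(P)), pref)]
  sel <- matrix(TRUE, nrow(P), ncol(P))
  sel[cbind(seq_len(nrow(P)), pref)] <- FALSE
  unmatched <- P[sel]
  if (length(matched) < 5 || length(unmatched) < 5) {
    warning("fewer than 5 observations per group; low power")
  }
  wt <- stats::wilcox.test(matched, unmatched, exact = FALSE)
  structure(
    tibble::tibble(
      statistic = unname(wt$statistic), p_value = wt$p.value,
      median_matched = stats::median(matched),
      median_unmatched = stats::median(unmatched),
      n_matched = length(matched), n_unmatched = length(unmatched)
    ),
    data = tibble::tibble(
      channel_id = as.integer(rownames(P)),
      pref_digit = as.integer(colnames(M))[pref],
      matched_value = matched
    )
  )
}

#' Digit preference-profile analysis with shuffle-then-smooth null
#'
#' Tests whether the full digit-preference profile of a motor channel's
#' movement responses predicts its susceptibility to ICMS through S1 channels
#' with PFs on each digit. Projection-map values are ordered by each
#' channel's movement-digit preference rank; a monotone-decreasing mean curve
#' is tested with a Kruskal-Wallis test across ranks. Per-channel Pearson
#' correlations between the two profiles are summarized by their mean, whose
#' significance comes from a null built by shuffling both the electrode and
#' digit assignments of the raw projection map `n_shuffles` times and
#' smoothing after each shuffle (so smoothing artifacts cannot drive the
#' result).
#'
#' @param motor_raw,projection_raw UNsmoothed `digit_map`s.
#' @param arraymap Array map (for smoothing geometry).
#' @param sigma_elec Smoothing SD in electrode pitches (default 1).
#' @param n_shuffles Shuffles for the null (default 10000).
#' @param seed Integer seed.
#' @return List: `mean_r`, `p_shuffle`, `kruskal_p`, `rank_curve` (tibble of
#'   mean +/- SEM by preference rank), `per_channel` (tibble of r), `n_shuffles`.
#' @export
preference_profile_analysis <- function(motor_raw, projection_raw, arraymap,
                                        sigma_elec = 1, n_shuffles = 10000,
                                        seed = NULL) {
  motor <- smooth_map(motor_raw, arraymap, sigma_elec)
  projection <- smooth_map(projection_raw, arraymap, sigma_elec)
  M <- digit_map_wide(motor)
  P <- digit_map_wide(projection)
  common_d <- intersect(colnames(M), colnames(P))
  if (length(common_d) < 3) stop("need at least 3 digits in common")
  common_c <- intersect(rownames(M), rownames(P))
  M <- M[common_c, common_d, drop = FALSE]
  P <- P[common_c, common_d, drop = FALSE]
  keep <- stats::complete.cases(M) & stats::complete.cases(P)
  M <- M[keep, , drop = FALSE]; P <- P[keep, , drop = FALSE]
  nd <- ncol(M)
  ## projection values ordered by movement-preference rank
  ord <- t(apply(M, 1, order, decreasing = TRUE))
  by_rank <- matrix(P[cbind(rep(seq_len(nrow(P)), nd), as.vector(ord))],
                    nrow(P), nd)
  rank_curve <- tibble::tibble(
    rank = seq_len(nd),
    mean_value = colMeans(by_rank),
    sem = apply(by_rank, 2, stats::sd) / sqrt(nrow(by_rank))
  )
  kw <- stats::kruskal.test(as.vector(by_rank),
                            rep(seq_len(nd), each = nrow(by_rank)))
  r_obs <- vapply(seq_len(nrow(M)), function(i) {
    stats::cor(M[i, ], P[i, ])
  }, numeric(1))
  mean_r <- mean(r_obs)
  ## shuffle-then-smooth null for the mean correlation
  K <- smoothing_kernel(arraymap, as.integer(rownames(P)), sigma_elec)
  Praw <- digit_map_wide(projection_raw)[common_c, common_d,
                                         drop = FALSE][keep, , drop = FALSE]
  null_r <- with_seed_opt(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      Ps <- Praw[sample.int(nrow(Praw)), sample.int(nd), drop = FALSE]
      Ps <- (K %*% Ps) / rowSums(K)
      mean(vapply(seq_len(nrow(M)), function(i) {
        stats::cor(M[i, ], Ps[i, ])
      }, numeric(1)))
    }, numeric(1))
  })
  list(
    mean_r = mean_r,
    p_shuffle = (1 + sum(null_r >= mean_r)) / (n_shuffles + 1),
    kruskal_p = kw$p.value,
    rank_curve = rank_curve,
    per_channel = tibble::tibble(channel_id = as.integer(rownames(P)),
                                 r = r_obs),
    n_shuffles = n_shuffles
  )
}

#' Somatotopic gradient map
#'
#' Spearman correlation, per motor channel, between its digit-map values and
#' the digit index (thumb = 1 ... pinky = 5). Positive rho marks preference
#' for the lateral digits, negative for the medial ones; constant profiles
#' are masked.
#'
#' @param map A `digit_map`.
#' @return Tibble: `channel_id`, `rho`.
#' @export
gradient_map <- function(map) {
  stopifnot(dplyr::n_distinct(map$digit) >= 3)
  map |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::summarise(
      rho = if (dplyr::n_distinct(.data$value) <= 1 || anyNA(.data$value)) {
        NA_real_
      } else {
        suppressWarnings(stats::cor(.data$value, .data$digit,
                                    method = "spearman"))
      },
      .groups = "drop"
    )
}

#' Spatial structure of ICMS-evoked activation patterns
#'
#' Treats each stimulating channel's vector of modulation z over motor
#' channels as its "activation pattern", computes all pairwise Pearson
#' correlations between stimulating channels, compares within-array vs
#' between-array pairs with a Wilcoxon rank-sum test, and regresses
#' within-array correlation on inter-electrode grid distance.
#'
#' @param modulation_results Output of [stim_modulation()].
#' @param arraymap Array map (S1 geometry).
#' @return List: `pairs` (tibble of pairwise correlations with `same_array`
#'   and `dist_um`), `within_vs_between` (wilcox htest), `distance_fit`
#'   (lm of r on distance, within-array pairs).
#' @export
pattern_correlation <- function(modulation_results, arraymap) {
  Z <- modulation_results |>
    dplyr::select("motor_channel", "stim_channel", "z") |>
    tidyr::pivot_wider(names_from = "motor_channel", values_from = "z")
  s1_ids <- Z$stim_channel
  Zm <- as.matrix(Z[-1])
  C <- suppressWarnings(stats::cor(t(Zm)))
  s1 <- dplyr::filter(arraymap, .data$region == "S1")
  info <- s1[match(s1_ids, s1$electrode_id), ]
  ut <- which(upper.tri(C), arr.ind = TRUE)
  same <- info$array_id[ut[, 1]] == info$array_id[ut[, 2]]
  dist_um <- ifelse(
    same,
    sqrt((info$grid_row[ut[, 1]] - info$grid_row[ut[, 2]])^2 +
           (info$grid_col[ut[, 1]] - info$grid_col[ut[, 2]])^2) *
      info$pitch_um[ut[, 1]],
    NA_real_
  )
  pairs <- tibble::tibble(
    s1_a = s1_ids[ut[, 1]], s1_b = s1_ids[ut[, 2]],
    r = C[ut], same_array = same, dist_um = dist_um
  )
  wt <- stats::wilcox.test(pairs$r[pairs$same_array],
                           pairs$r[!pairs$same_array], exact = FALSE)
  fit <- stats::lm(r ~ dist_um, data = pairs[pairs$same_array, ])
  list(pairs = pairs, within_vs_between = wt, distance_fit = fit)
}
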