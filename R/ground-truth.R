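#' Ground truth for a synthetic cortical session
#'
#' Draws a complete parameterization of a simulated M1/S1 preparation:
#' baseline rates, digit-preference profiles and a somatotopic gradient on the
#' M1 grid, 3D velocity tuning, per-(S1, M1) pair coupling (direct pulse-locked
#' input with per-pulse spike probability, latency and jitter; indirect
#' additive rate shifts), task-gain multipliers for the indirect input, and a
#' somatotopic bias that strengthens coupling between projected-field-matched
#' digit pairs.
#'
#' The M1 population sits on a 10 x 10 grid with the four corner shanks
#' unwired (96 active channels). S1 comprises `n_s1_arrays` 4 x 8 arrays of 32
#' stimulable channels each, with a gradient of dominant projected-field (PF)
#' digits across the grid columns. Indirect coupling magnitudes vary smoothly
#' across each S1 array (a per-M1-channel linear field plus noise), so that
#' neighboring stimulating electrodes evoke similar M1 activation patterns and
#' different arrays evoke uncorrelated ones.
#'
#' Direct (pulse-locked) input is task-invariant by construction; indirect
#' input is scaled per channel by task gains and by a rectified power-law
#' amplitude response that is zero at `amp_threshold_ua` and one at
#' `amp_ref_ua` (see `amp_gamma`).
#'
#' @param n_s1_arrays Number of S1 arrays (default 2).
#' @param digits Digits represented across S1 PFs (default 1:4; the little
#'   finger is commonly unrepresented in PF reports).
#' @param lambda0_shape,lambda0_mean_hz Gamma parameters of baseline rates.
#' @param p_couple Probability a pair carries indirect coupling (default 0.4).
#' @param g0_hz,g_field_sd_hz,g_noise_sd_hz Indirect shift: mean, smooth
#'   spatial-field SD and pairwise-noise SD, in Hz at the reference amplitude.
#'   With the defaults most coupled pairs are excitatory and a minority
#'   inhibitory.
#' @param beta Somatotopic bias multiplying both `p_direct` and the indirect
#'   magnitude for PF-matched digit pairs (>= 1; default 2).
#' @param p_direct_pair Probability a pair is direct (default 0.06).
#' @param p_direct_range Per-pulse spike probability range for direct pairs.
#' @param latency_range_ms,jitter_range_ms Direct-response latency mean and SD
#'   ranges (truncated to the 2-6 ms / 0.05-1 ms windows typical of
#'   short-latency cortico-cortical activation).
#' @param tuning_gain_range Velocity-tuning gain range, Hz per m/s.
#' @param task_gain_grasp_range,task_gain_transport_range Ranges of the
#'   per-channel multiplicative task gains on the indirect input (squeeze is
#'   the reference task, gain 1).
#' @param phase_base_sd SD of per-channel, per-phase baseline engagement
#'   (multiplicative, mean 0).
#' @param amp_threshold_ua,amp_ref_ua,amp_gamma Amplitude response: effects
#'   scale as `((amp - threshold) / (ref - threshold))^gamma` (rectified at
#'   zero). The default exponent 3 captures supralinear recruitment above
#'   threshold, so weak sustained stimulation (32 uA) evokes far less
#'   activity than 52-72 uA stimulation.
#' @param indirect_onset_s,indirect_adapt_tau_s Onset lag and exponential
#'   adaptation time constant of the indirect effect (defaults 0 and Inf: the
#'   shift is a step at train onset).
#' @param seed Integer seed.
#' @return An object of class `icms_truth`: list of tibbles `m1`, `s1`,
#'   `pairs`, and `params`.
#' @export
ground_truth <- function(n_s1_arrays = 2,
                         digits = 1:4,
                         lambda0_shape = 9, lambda0_mean_hz = 15,
                         p_couple = 0.4,
                         g0_hz = 6, g_field_sd_hz = 4, g_noise_sd_hz = 2,
                         beta = 2,
                         p_direct_pair = 0.06,
                         p_direct_range = c(0.05, 0.4),
                         latency_range_ms = c(2.5, 5.5),
                         jitter_range_ms = c(0.1, 0.5),
                         tuning_gain_range = c(15, 50),
                         task_gain_grasp_range = c(0.4, 1.6),
                         task_gain_transport_range = c(0, 2),
                         phase_base_sd = 0.3,
                         amp_threshold_ua = 20, amp_ref_ua = 60,
                         amp_gamma = 3,
                         indirect_onset_s = 0, indirect_adapt_tau_s = Inf,
                         seed = NULL) {
  stopifnot(beta >= 1, p_couple >= 0, p_couple <= 1)
  with_seed_opt(seed, {
    ## --- M1 grid: 10 x 10, corners unwired -------------------------------
    grid <- tidyr::expand_grid(grid_row = 0:9, grid_col = 0:9)
    grid$electrode_id <- seq_len(nrow(grid))
    corner <- (grid$grid_row %in% c(0, 9)) & (grid$grid_col %in% c(0, 9))
    grid$wired <- !corner
    m1 <- grid[grid$wired, ]
    n_m1 <- nrow(m1)
    m1$channel_id <- m1$electrode_id
    m1$lambda0_hz <- stats::rgamma(n_m1, shape = lambda0_shape,
                                   scale = lambda0_mean_hz / lambda0_shape)
    ## digit preference gradient across columns, plus jitter
    nd <- length(digits)
    band <- findInterval(m1$grid_col + stats::runif(n_m1, -1.5, 1.5),
                         seq(0, 9, length.out = nd + 1),
                         rightmost.closed = TRUE, all.inside = TRUE)
    pref <- digits[band]
    depth <- stats::runif(n_m1, 0.5, 2)
    w <- matrix(0, n_m1, 5)
    for (d in 1:5) w[, d] <- depth * exp(-0.5 * ((d - pref) / 0.8)^2)
    w <- w[, digits, drop = FALSE]
    w <- w - rowMeans(w)
    W <- matrix(0, n_m1, 5)
    W[, digits] <- w
    colnames(W) <- paste0("w", 1:5)
    m1 <- dplyr::bind_cols(m1, tibble::as_tibble(W))
    m1$pref_digit <- digits[apply(w, 1, which.max)]
    ## 3D velocity tuning
    dirs <- matrix(stats::rnorm(n_m1 * 3), n_m1, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    gain <- stats::runif(n_m1, tuning_gain_range[1], tuning_gain_range[2])
    m1$tune_x <- dirs[, 1] * gain
    m1$tune_y <- dirs[, 2] * gain
    m1$tune_z <- dirs[, 3] * gain
    ## task gains on indirect input and per-phase baseline engagement
    m1$gain_squeeze <- 1
    m1$gain_grasp <- stats::runif(n_m1, task_gain_grasp_range[1],
                                  task_gain_grasp_range[2])
    m1$gain_transport <- stats::runif(n_m1, task_gain_transport_range[1],
                                      task_gain_transport_range[2])
    for (ph in c("base_squeeze", "base_grasp", "base_transport", "base_reach")) {
      m1[[ph]] <- stats::rnorm(n_m1, 0, phase_base_sd)
    }

    ## --- S1 arrays: 4 x 8 each, PF digit gradient along columns ----------
    s1 <- purrr::map_dfr(seq_len(n_s1_arrays), function(a) {
      g <- tidyr::expand_grid(grid_row = 0:3, grid_col = 0:7)
      g$array_id <- a + 1L  # M1 is array 1
      g$electrode_id <- 100L * a + seq_len(nrow(g))
      g$wired <- TRUE
      band <- findInterval(g$grid_col + stats::runif(nrow(g), -1, 1),
                           seq(0, 7, length.out = nd + 1),
                           rightmost.closed = TRUE, all.inside = TRUE)
      g$pf_digit <- digits[band]
      g
    })

    ## --- pairwise coupling ------------------------------------------------
    pairs <- tidyr::expand_grid(
      s1_channel = s1$electrode_id,
      m1_channel = m1$channel_id
    )
    pairs <- dplyr::left_join(
      pairs,
      dplyr::select(s1, s1_channel = "electrode_id", "array_id",
                    s1_row = "grid_row", s1_col = "grid_col", "pf_digit"),
      by = "s1_channel"
    )
    pairs <- dplyr::left_join(
      pairs,
      dplyr::select(m1, m1_channel = "channel_id", "pref_digit"),
      by = "m1_channel"
    )
    ## smooth per-(M1, array) linear field over the S1 grid
    fk <- tidyr::expand_grid(m1_channel = m1$channel_id,
                             array_id = unique(s1$array_id))
    sdc <- g_field_sd_hz / sqrt(3)
    fk$a0 <- stats::rnorm(nrow(fk), 0, sdc)
    fk$ar <- stats::rnorm(nrow(fk), 0, sdc)
    fk$ac <- stats::rnorm(nrow(fk), 0, sdc)
    pairs <- dplyr::left_join(pairs, fk, by = c("m1_channel", "array_id"))
    zr <- (pairs$s1_row - 1.5) / 1.118   # standardized grid coordinates
    zc <- (pairs$s1_col - 3.5) / 2.291
    field <- pairs$a0 + pairs$ar * zr + pairs$ac * zc
    coupled <- stats::runif(nrow(pairs)) < p_couple
    g_raw <- g0_hz + field + stats::rnorm(nrow(pairs), 0, g_noise_sd_hz)
    matched <- pairs$pf_digit == pairs$pref_digit
    pairs$coupled <- coupled
    pairs$g_base_hz <- ifelse(coupled, g_raw * ifelse(matched, beta, 1), 0)
    pairs$matched <- matched
    ## direct pairs
    direct <- stats::runif(nrow(pairs)) < p_direct_pair
    pairs$direct <- direct
    pairs$p_direct <- ifelse(
      direct,
      pmin(0.95, stats::runif(nrow(pairs), p_direct_range[1],
                              p_direct_range[2]) * ifelse(matched, beta, 1)),
      0
    )
    pairs$mu_lat_ms <- ifelse(direct,
                              stats::runif(nrow(pairs), latency_range_ms[1],
                                           latency_range_ms[2]), NA_real_)
    pairs$sigma_lat_ms <- ifelse(direct,
                                 stats::runif(nrow(pairs), jitter_range_ms[1],
                                              jitter_range_ms[2]), NA_real_)
    pairs <- dplyr::select(pairs, -"a0", -"ar", -"ac", -"s1_row", -"s1_col")

    structure(
      list(
        m1 = tibble::as_tibble(m1), s1 = tibble::as_tibble(s1), pairs = pairs,
        params = list(
          digits = digits, beta = beta, p_couple = p_couple, g0_hz = g0_hz,
          amp_threshold_ua = amp_threshold_ua, amp_ref_ua = amp_ref_ua,
          amp_gamma = amp_gamma,
          indirect_onset_s = indirect_onset_s,
          indirect_adapt_tau_s = indirect_adapt_tau_s,
          seed = seed
        )
      ),
      class = "icms_truth"
    )
  })
}

#' @export
print.icms_truth <- function(x, ...) {
  cat("<icms_truth>", nrow(x$m1), "M1 channels,", nrow(x$s1), "S1 channels,",
      sum(x$pairs$coupled), "indirect +", sum(x$pairs$direct),
      "direct pairs (beta =", x$params$beta, ")\n")
  invisible(x)
}

#' Rectified-linear amplitude response
#'
#' Scales both direct per-pulse spike probability and indirect rate shifts:
#' zero at the threshold amplitude, one at the reference amplitude, linear in
#' between and beyond.
#'
#' @param amplitude_ua Pulse amplitude(s), uA.
#' @param truth An `icms_truth` (supplies threshold and reference).
#' @return Dimensionless scale factor(s) >= 0.
#' @export
amp_response <- function(amplitude_ua, truth) {
  thr <- truth$params$amp_threshold_ua
  ref <- truth$params$amp_ref_ua
  gam <- truth$params$amp_gamma %||% 1
  pmax(0, (amplitude_ua - thr) / (ref - thr))^gam
}

#' Override coupling for selected channel pairs
#'
#' Convenience for constructing controlled recovery scenarios: sets the
#' indirect shift and/or direct-response parameters of the pairs formed by
#' `s1_channels` x `m1_channels`, leaving everything else untouched.
#'
#' @param truth An `icms_truth`.
#' @param s1_channels,m1_channels Channel ids selecting the pairs.
#' @param g_base_hz Indirect shift in Hz at reference amplitude (or NULL).
#' @param direct Logical direct flag (or NULL to leave).
#' @param p_direct,mu_lat_ms,sigma_lat_ms Direct-response parameters.
#' @return The modified truth.
#' @export
set_pair_coupling <- function(truth, s1_channels, m1_channels,
                              g_base_hz = NULL, direct = NULL,
                              p_direct = NULL, mu_lat_ms = NULL,
                              sigma_lat_ms = NULL) {
  sel <- truth$pairs$s1_channel %in% s1_channels &
    truth$pairs$m1_channel %in% m1_channels
  if (!is.null(g_base_hz)) {
    truth$pairs$g_base_hz[sel] <- g_base_hz
    truth$pairs$coupled[sel] <- g_base_hz != 0
  }
  if (!is.null(direct)) truth$pairs$direct[sel] <- direct
  if (!is.null(p_direct)) {
    if (any(p_direct < 0 | p_direct > 1)) stop("p_direct must lie in [0, 1]")
    truth$pairs$p_direct[sel] <- p_direct
  }
  if (!is.null(mu_lat_ms)) truth$pairs$mu_lat_ms[sel] <- mu_lat_ms
  if (!is.null(sigma_lat_ms)) truth$pairs$sigma_lat_ms[sel] <- sigma_lat_ms
  truth
}

#' Electrode-array map from a ground truth
#'
#' @param truth An `icms_truth`.
#' @return ArrayMap tibble: `electrode_id`, `array_id`, `region`, `grid_row`,
#'   `grid_col`, `wired`, `pf_digit` (NA on M1), `pitch_um`.
#' @export
array_map <- function(truth) {
  grid <- tidyr::expand_grid(grid_row = 0:9, grid_col = 0:9)
  grid$electrode_id <- seq_len(nrow(grid))
  corner <- (grid$grid_row %in% c(0, 9)) & (grid$grid_col %in% c(0, 9))
  m1 <- tibble::tibble(
    electrode_id = grid$electrode_id, array_id = 1L, region = "M1",
    grid_row = grid$grid_row, grid_col = grid$grid_col,
    wired = !corner, pf_digit = NA_integer_, pitch_um = 400
  )
  s1 <- tibble::tibble(
    electrode_id = truth$s1$electrode_id, array_id = truth$s1$array_id,
    region = "S1", grid_row = truth$s1$grid_row,
    grid_col = truth$s1$grid_col, wired = truth$s1$wired,
    pf_digit = as.integer(truth$s1$pf_digit), pitch_um = 400
  )
  dplyr::bind_rows(m1, s1)
}

#' Ground truth for the closed-loop feedback scenario
#'
#' A standard [ground_truth()] in which the two feedback electrodes (dominant
#' PFs on the thumb and index finger) are given strong indirect coupling to
#' the whole motor population: per-electrode rate shifts drawn from
#' N(`mean_shift_hz`, `sd_shift_hz`) at the reference amplitude, i.e. summed
#' evoked shifts of roughly 2-3x baseline on typical channels. This emulates a
#' preparation in which ICMS-evoked responses in M1 are strong and prevalent,
#' the regime in which stimulation feedback visibly contaminates decoding.
#'
#' @param seed Integer seed.
#' @param mean_shift_hz,sd_shift_hz Per-electrode indirect shift distribution
#'   (Hz at reference amplitude; defaults 20 and 8).
#' @param bias_ref_ms Magnitude (m/s) of the decoded velocity bias the
#'   contamination induces at the reference amplitude (default 0.45). The
#'   evoked pattern is given a component inside the population's velocity-
#'   tuning subspace of exactly this decoded size, reflecting the observation
#'   that ICMS-evoked activity overlaps the subspace used for motor control
#'   rather than lying orthogonal to it.
#' @param ... Passed to [ground_truth()].
#' @return List: `truth` (an `icms_truth`) and `stim_channels` (the two
#'   feedback electrode ids).
#' @export
feedback_scenario_truth <- function(seed, mean_shift_hz = 20,
                                    sd_shift_hz = 8, bias_ref_ms = 0.45,
                                    ...) {
  truth <- ground_truth(seed = seed, ...)
  stim_channels <- c(
    truth$s1$electrode_id[truth$s1$pf_digit == 1][1],
    truth$s1$electrode_id[truth$s1$pf_digit == 2][1]
  )
  stim_channels <- stim_channels[!is.na(stim_channels)]
  n_m1 <- nrow(truth$m1)
  B <- as.matrix(truth$m1[c("tune_x", "tune_y", "tune_z")])
  gain_tr <- truth$m1$gain_transport
  g <- withr::with_seed(child_seed(seed, 99), {
    list(
      rand = stats::rnorm(length(stim_channels) * n_m1, mean_shift_hz,
                          sd_shift_hz),
      u = stats::rnorm(3)
    )
  })
  ## tuning-subspace component sized so that the TOTAL decoded bias of the
  ## summed contamination is bias_ref_ms at the reference amplitude
  ## (ridge-inverted exactly as fit_ole decodes); the random part alone
  ## projects onto the 3-D tuning subspace with large seed-to-seed variance
  u <- g$u / sqrt(sum(g$u^2))
  c0 <- as.vector(B %*% u)
  G <- crossprod(B)
  P <- solve(G + 1e-3 * mean(diag(G)) * diag(3), t(B))
  rand_sum <- rowSums(matrix(g$rand, n_m1, length(stim_channels)))
  r <- as.vector(P %*% (rand_sum * gain_tr))
  v <- as.vector(P %*% (c0 * gain_tr))
  v_hat <- v / sqrt(sum(v^2))
  disc <- sum(r * v_hat)^2 + bias_ref_ms^2 - sum(r^2)
  s <- if (disc >= 0) {
    (-sum(r * v_hat) + sqrt(disc)) / sqrt(sum(v^2))
  } else {
    0  # random part already exceeds the target bias; leave it
  }
  align <- c0 * s
  for (i in seq_along(stim_channels)) {
    truth <- set_pair_coupling(
      truth, stim_channels[i], truth$m1$channel_id,
      g_base_hz = g$rand[(i - 1) * n_m1 + seq_len(n_m1)] +
        align / length(stim_channels)
    )
  }
  list(truth = truth, stim_channels = stim_channels)
}
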