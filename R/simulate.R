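#' Configure the synthetic pointing-study generator
#'
#' The generator emulates a factorial pointing experiment: straight-line
#' 30 cm fingertip paths sampled at 120 Hz, with a beta-shaped speed profile
#' whose mode position (the generative relative time to peak speed, in
#' percent of movement duration) is set per direction to mimic
#' gravity-dependent velocity-profile asymmetry. Defaults give upward
#' movements an earlier speed peak (45%) than downward ones (51%), with
#' symmetric lateral movements (48%), identically in both postures and
#' environments. Two corruption modes can be injected: duration outliers
#' (regenerated with a duration far above the population mean) and trials
#' with a contiguous span of missing samples.
#'
#' @param design A [study_design()].
#' @param rdpv_target Either a named numeric vector over directions
#'   (`up`, `down`, `left`, `right`, applied in every posture and
#'   environment) or a data.frame with columns `posture`, `environment`,
#'   `direction`, `rdpv` giving a full cell map. Percent, strictly inside
#'   (0, 100).
#' @param md_mean,md_sd Mean and SD (seconds) of the per-trial movement
#'   duration draw.
#' @param md_trunc_sd Truncation half-width of the duration draw, in SDs.
#'   Kept below 3 so that injected duration outliers are the only trials
#'   that can violate the 3-SD exclusion rule.
#' @param noise_sd SD (metres) of i.i.d. Gaussian positional noise added
#'   before filtering (marker jitter).
#' @param pad Seconds of quiescence before and after the movement; the
#'   threshold segmentation needs a quiet baseline, so at least 0.25 s.
#' @param rdpv_participant_sd SD (percentage points) of a per-participant
#'   random offset added to every generative rdpv target; 0 disables it.
#' @param n_outlier_trials,n_missing_trials Number of trials corrupted by
#'   each mode.
#' @param seed Integer seed driving all stochastic behaviour.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(design = study_design(),
                       rdpv_target = c(up = 45, down = 51, left = 48,
                                       right = 48),
                       md_mean = 0.5, md_sd = 0.05, md_trunc_sd = 2.5,
                       noise_sd = 5e-4, pad = 0.3,
                       rdpv_participant_sd = 0,
                       n_outlier_trials = 2, n_missing_trials = 1,
                       seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (md_mean <= 0) stop("md_mean must be positive")
  if (md_sd < 0 || noise_sd < 0 || rdpv_participant_sd < 0)
    stop("standard deviations must be non-negative")
  if (pad < 0.25) stop("pad must be at least 0.25 s (quiescent baseline)")
  if (md_trunc_sd <= 0 || md_trunc_sd >= 3)
    stop("md_trunc_sd must be in (0, 3)")
  if (is.list(rdpv_target) && !is.data.frame(rdpv_target))
    rdpv_target <- unlist(rdpv_target)  # e.g. a YAML map
  if (is.data.frame(rdpv_target)) {
    stopifnot(all(c("posture", "environment", "direction", "rdpv") %in%
                    names(rdpv_target)))
    vals <- rdpv_target$rdpv
  } else {
    if (!all(design$directions %in% names(rdpv_target)))
      stop("rdpv_target must name every direction")
    vals <- rdpv_target
  }
  if (any(vals <= 0 | vals >= 100))
    stop("rdpv_target values must lie strictly inside (0, 100)")
  structure(list(design = design, rdpv_target = rdpv_target,
                 md_mean = md_mean, md_sd = md_sd, md_trunc_sd = md_trunc_sd,
                 noise_sd = noise_sd, pad = pad,
                 rdpv_participant_sd = rdpv_participant_sd,
                 n_outlier_trials = as.integer(n_outlier_trials),
                 n_missing_trials = as.integer(n_missing_trials),
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdpv_for_cell <- function(config, posture, environment, direction) {
  rt <- config$rdpv_target
  if (is.data.frame(rt)) {
    hit <- rt$posture == posture & rt$environment == environment &
      rt$direction == direction
    if (sum(hit) != 1L) stop("rdpv_target map must cover every cell exactly once")
    rt$rdpv[hit]
  } else unname(rt[direction])
}

# Beta shape parameters (a, b) with fixed a + b = 6 so the mode sits at
# rdpv/100; rdpv = 50 gives a = b = 3, the minimum-jerk speed curve.
beta_shape_params <- function(rdpv_target) {
  if (rdpv_target <= 0 || rdpv_target >= 100)
    stop("rdpv_target must lie strictly inside (0, 100)")
  r <- rdpv_target / 100
  c(a = 1 + 4 * r, b = 5 - 4 * r)
}

#' Beta-shaped speed profile
#'
#' Closed-form unimodal speed curve `v(tau) = A/D * dbeta(tau, a, b)` with
#' the mode at `rdpv_target`% of the duration and time integral equal to the
#' amplitude. The shape family has `a + b = 6`, so `rdpv_target = 50` is the
#' minimum-jerk speed curve `30 tau^2 (1 - tau)^2`.
#'
#' @param rdpv_target Generative relative time of peak speed, percent in
#'   (0, 100).
#' @param duration Movement duration in seconds.
#' @param amplitude Path length in metres.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric speed series (m/s) at times `0, 1/rate, ...,
#'   round(duration * rate)/rate`, zero at both ends.
#' @examples
#' v <- shape_speed_profile(50, 0.5, 0.30, 120)
#' which.max(v)  # mid-duration
#' @export
shape_speed_profile <- function(rdpv_target, duration, amplitude,
                                sampling_rate) {
  stopifnot(duration > 0, amplitude > 0, sampling_rate > 0)
  ab <- beta_shape_params(rdpv_target)
  tau <- seq(0, round(duration * sampling_rate)) / (duration * sampling_rate)
  tau <- pmin(tau, 1)
  amplitude / duration * stats::dbeta(tau, ab["a"], ab["b"])
}

draw_truncated_duration <- function(md_mean, md_sd, trunc_sd) {
  if (md_sd == 0) return(md_mean)
  repeat {
    d <- stats::rnorm(1, md_mean, md_sd)
    if (abs(d - md_mean) <= trunc_sd * md_sd && d > 0) return(d)
  }
}

# Start position of the fingertip in room coordinates (m): roughly chest
# height at arm's length. Arbitrary but fixed; the analysis is
# translation-invariant.
SIM_START <- c(x = 0, y = 0.45, z = 1.10)

#' Synthesize one pointing trial
#'
#' A straight-line 3D path from the start position toward the labelled
#' target: displacement `amplitude * pbeta(t/D, a, b)` along the direction's
#' unit vector, quiescent padding at both ends, i.i.d. Gaussian positional
#' noise. Consumes the current RNG stream; seed externally for
#' reproducibility.
#'
#' @param config A [sim_config()].
#' @param participant,posture,environment,direction,block,trial Trial
#'   labels.
#' @param duration Movement duration in seconds; drawn from the truncated
#'   normal duration distribution when `NULL`.
#' @param rdpv Generative rdpv percent; looked up from the config map when
#'   `NULL`.
#' @return A [trial_trajectory()] with attributes `rdpv` and `duration`
#'   recording the generative values.
#' @export
synthesize_trial <- function(config, participant, posture, environment,
                             direction, block, trial,
                             duration = NULL, rdpv = NULL) {
  design <- config$design
  fs <- design$sampling_rate
  if (is.null(duration))
    duration <- draw_truncated_duration(config$md_mean, config$md_sd,
                                        config$md_trunc_sd)
  if (is.null(rdpv))
    rdpv <- rdpv_for_cell(config, posture, environment, direction)
  ab <- beta_shape_params(rdpv)
  n <- round((2 * config$pad + duration) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  tau <- pmin(pmax((t - config$pad) / duration, 0), 1)
  s <- design$amplitude * stats::pbeta(tau, ab["a"], ab["b"])
  u <- DIRECTION_VECTORS[[direction]]
  pos <- cbind(SIM_START["x"] + u[1] * s,
               SIM_START["y"] + u[2] * s,
               SIM_START["z"] + u[3] * s)
  if (config$noise_sd > 0)
    pos <- pos + matrix(stats::rnorm(3L * n, 0, config$noise_sd), n, 3L)
  out <- trial_trajectory(participant, posture, environment, direction,
                          block, trial,
                          samples = data.frame(t = t, x = pos[, 1],
                                               y = pos[, 2], z = pos[, 3]),
                          sampling_rate = fs)
  attr(out, "rdpv") <- rdpv
  attr(out, "duration") <- duration
  out
}

#' Simulate a full factorial pointing study
#'
#' Generates the complete trial set of the design in canonical order, then
#' injects the configured corruptions: `n_outlier_trials` randomly chosen
#' trials are regenerated with a movement duration 4-5 population SDs above
#' the mean, and `n_missing_trials` trials have a contiguous 0.1 s span of
#' samples blanked. A ground-truth ledger records each trial's generative
#' rdpv, duration and corruption status.
#'
#' @param config A [sim_config()].
#' @return List with `trials` (list of [trial_trajectory()]) and `ledger`
#'   (data.frame: labels, `rdpv_target`, `duration`, `corruption`).
#' @examples
#' sim <- simulate_study(sim_config(design = study_design(n_participants = 1),
#'                                  n_outlier_trials = 0,
#'                                  n_missing_trials = 0))
#' length(sim$trials)  # 192
#' @export
simulate_study <- function(config) {
  design <- config$design
  total <- n_design_trials(design)
  n_corrupt <- config$n_outlier_trials + config$n_missing_trials
  if (n_corrupt > total)
    stop("injection counts exceed the design trial count")
  set.seed(config$seed)
  participants <- sprintf("P%02d", seq_len(design$n_participants))
  p_offset <- stats::setNames(
    if (config$rdpv_participant_sd > 0)
      stats::rnorm(length(participants), 0, config$rdpv_participant_sd)
    else rep(0, length(participants)), participants)

  grid <- expand.grid(
    trial = seq_len(design$trials_per_direction_per_block),
    block = seq_len(design$blocks_per_condition),
    direction = design$directions,
    environment = design$environments,
    posture = design$postures,
    participant = participants,
    stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant,
                     match(grid$posture, POSTURE_LEVELS),
                     match(grid$environment, ENVIRONMENT_LEVELS),
                     match(grid$direction, DIRECTION_LEVELS),
                     grid$block, grid$trial), ]
  rownames(grid) <- NULL

  corrupt_idx <- if (n_corrupt > 0) sample(total, n_corrupt) else integer()
  outlier_idx <- corrupt_idx[seq_len(config$n_outlier_trials)]
  missing_idx <- setdiff(corrupt_idx, outlier_idx)

  trials <- vector("list", total)
  ledger <- cbind(grid,
                  rdpv_target = NA_real_, duration = NA_real_,
                  corruption = "none", stringsAsFactors = FALSE)
  for (i in seq_len(total)) {
    g <- grid[i, ]
    rdpv <- rdpv_for_cell(config, g$posture, g$environment, g$direction) +
      p_offset[[g$participant]]
    rdpv <- min(max(rdpv, 1), 99)
    dur <- if (i %in% outlier_idx) {
      config$md_mean + stats::runif(1, 4, 5) * config$md_sd
    } else {
      draw_truncated_duration(config$md_mean, config$md_sd,
                              config$md_trunc_sd)
    }
    tr <- synthesize_trial(config, g$participant, g$posture, g$environment,
                           g$direction, g$block, g$trial,
                           duration = dur, rdpv = rdpv)
    if (i %in% missing_idx) {
      ns <- nrow(tr$samples)
      span <- round(0.1 * design$sampling_rate)
      start <- floor(ns / 2) - floor(span / 2)
      tr$samples[start:(start + span - 1L), c("x", "y", "z")] <- NA_real_
      ledger$corruption[i] <- "missing_data"
    } else if (i %in% outlier_idx) {
      ledger$corruption[i] <- "duration_outlier"
    }
    ledger$rdpv_target[i] <- rdpv
    ledger$duration[i] <- dur
    trials[[i]] <- tr
  }
  list(trials = trials, ledger = ledger)
}
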