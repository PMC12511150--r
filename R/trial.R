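#' @keywords internal
POSTURE_LEVELS <- c("upright", "lying")
#' @keywords internal
ENVIRONMENT_LEVELS <- c("virtual", "physical")
#' @keywords internal
DIRECTION_LEVELS <- c("up", "down", "left", "right")

# Room-fixed (allocentric) unit vectors for the four target directions.
# x: lateral (rightward positive), y: anteroposterior, z: vertical.
DIRECTION_VECTORS <- list(
  up    = c(0, 0,  1),
  down  = c(0, 0, -1),
  left  = c(-1, 0, 0),
  right = c( 1, 0, 0)
)

#' Describe the factorial structure of a pointing study
#'
#' The default reproduces the reference design: 27 participants, two postures
#' (upright, lying), two visual environments (virtual, physical), four
#' allocentric movement directions, four blocks per posture-by-environment
#' condition with three trials per direction per block, a 30 cm movement
#' amplitude, and 120 Hz motion capture.
#'
#' @param n_participants Number of participants.
#' @param postures,environments,directions Factor level vectors.
#' @param blocks_per_condition Blocks within each posture-by-environment
#'   condition.
#' @param trials_per_direction_per_block Trials per direction within a block.
#' @param amplitude Start-to-target distance in metres.
#' @param sampling_rate Motion-capture sampling rate in Hz.
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design(n_participants = 27)
#' n_design_trials(d)  # 5184
#' @export
study_design <- function(n_participants = 27,
                         postures = POSTURE_LEVELS,
                         environments = ENVIRONMENT_LEVELS,
                         directions = DIRECTION_LEVELS,
                         blocks_per_condition = 4,
                         trials_per_direction_per_block = 3,
                         amplitude = 0.30,
                         sampling_rate = 120) {
  stopifnot(n_participants >= 1, blocks_per_condition >= 1,
            trials_per_direction_per_block >= 1)
  if (amplitude <= 0) stop("amplitude must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(list(
    n_participants = as.integer(n_participants),
    postures = postures,
    environments = environments,
    directions = directions,
    blocks_per_condition = as.integer(blocks_per_condition),
    trials_per_direction_per_block = as.integer(trials_per_direction_per_block),
    amplitude = amplitude,
    sampling_rate = sampling_rate
  ), class = "study_design")
}

#' Total number of trials implied by a design
#' @param design A `study_design`.
#' @return Integer trial count.
#' @export
n_design_trials <- function(design) {
  with(design, n_participants * length(postures) * length(environments) *
         length(directions) * blocks_per_condition *
         trials_per_direction_per_block)
}

#' Construct a single-trial trajectory
#'
#' Bundles one trial's 3D fingertip samples with its factorial labels.
#' Timestamps must be strictly increasing and uniformly spaced (tolerance
#' 1e-6 s); coordinates may be `NA` to mark missing motion data.
#'
#' @param participant Participant label.
#' @param posture One of `"upright"`, `"lying"`.
#' @param environment One of `"virtual"`, `"physical"`.
#' @param direction One of `"up"`, `"down"`, `"left"`, `"right"`
#'   (allocentric).
#' @param block Block number (1-based).
#' @param trial Trial index within direction and block (1-based).
#' @param samples `data.frame` with columns `t`, `x`, `y`, `z` (seconds and
#'   metres).
#' @param sampling_rate Sampling rate in Hz; inferred from `samples$t` when
#'   `NULL`.
#' @return An object of class `trial_trajectory`.
#' @export
trial_trajectory <- function(participant, posture, environment, direction,
                             block, trial, samples, sampling_rate = NULL) {
  posture <- match.arg(posture, POSTURE_LEVELS)
  environment <- match.arg(environment, ENVIRONMENT_LEVELS)
  direction <- match.arg(direction, DIRECTION_LEVELS)
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y", "z") %in% names(samples)))
  tt <- samples$t
  if (length(tt) < 24)
    stop("trial must contain at least 24 samples (0.2 s at 120 Hz)")
  dt <- diff(tt)
  if (any(dt <= 0))
    stop(sprintf("non-monotonic timestamps in trial %s/%s/%s/%s/b%s/t%s",
                 participant, posture, environment, direction, block, trial))
  if (max(dt) - min(dt) > 1e-6)
    stop("timestamps are not uniformly spaced (tolerance 1e-6 s)")
  if (is.null(sampling_rate)) sampling_rate <- 1 / mean(dt)
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(list(
    participant = as.character(participant),
    posture = posture, environment = environment, direction = direction,
    block = as.integer(block), trial = as.integer(trial),
    sampling_rate = sampling_rate,
    samples = samples[c("t", "x", "y", "z")]
  ), class = "trial_trajectory")
}

#' @export
print.trial_trajectory <- function(x, ...) {
  cat(sprintf("<trial_trajectory> %s %s/%s/%s block %d trial %d: %d samples @ %.5g Hz\n",
              x$participant, x$posture, x$environment, x$direction,
              x$block, x$trial, nrow(x$samples), x$sampling_rate))
  invisible(x)
}

#' Does a trial contain missing motion samples?
#' @param traj A `trial_trajectory`.
#' @return Logical.
#' @export
has_missing_samples <- function(traj) {
  anyNA(traj$samples[c("x", "y", "z")])
}

# Canonical key identifying one of the 16 posture x environment x direction
# cells.
cell_key <- function(posture, environment, direction) {
  paste(posture, environment, direction, sep = ".")
}

trial_uid <- function(traj) {
  with(traj, paste(participant, posture, environment, direction, block, trial,
                   sep = "."))
}

trial_labels <- function(traj) {
  data.frame(participant = traj$participant, posture = traj$posture,
             environment = traj$environment, direction = traj$direction,
             block = traj$block, trial = traj$trial,
             stringsAsFactors = FALSE)
}

# Order trials canonically: participant, then factor-level order of posture,
# environment and direction, then block and trial.
order_trials <- function(trials) {
  lab <- do.call(rbind, lapply(trials, trial_labels))
  ord <- order(lab$participant,
               match(lab$posture, POSTURE_LEVELS),
               match(lab$environment, ENVIRONMENT_LEVELS),
               match(lab$direction, DIRECTION_LEVELS),
               lab$block, lab$trial)
  trials[ord]
}
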