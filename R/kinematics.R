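# -- zero-phase Butterworth filtering ---------------------------------------
#
# Coefficients come from signal::butter; the zero-phase forward-backward pass
# is implemented here with odd-reflection padding and steady-state initial
# conditions, so that a constant series passes through exactly (DC gain 1
# with no edge transient).

# Steady-state initial state of the direct-form-II-transposed filter for a
# unit-step input: solving z = A'z + B at the fixed point.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  n <- nf - 1L
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  solve(diag(n) - t(comp), b[-1] - a[-1] * b[1])
}

# Direct-form-II-transposed IIR filter with initial state zi.
lfilter <- function(b, a, x, zi) {
  nf <- length(b)
  n <- length(x)
  y <- numeric(n)
  if (nf == 4L) {  # unrolled third-order path (the default filter)
    b0 <- b[1]; b1 <- b[2]; b2 <- b[3]; b3 <- b[4]
    a1 <- a[2]; a2 <- a[3]; a3 <- a[4]
    z1 <- zi[1]; z2 <- zi[2]; z3 <- zi[3]
    for (i in seq_len(n)) {
      xi <- x[i]
      yi <- b0 * xi + z1
      z1 <- b1 * xi + z2 - a1 * yi
      z2 <- b2 * xi + z3 - a2 * yi
      z3 <- b3 * xi - a3 * yi
      y[i] <- yi
    }
  } else {
    z <- zi
    m <- nf - 1L
    for (i in seq_len(n)) {
      xi <- x[i]
      yi <- b[1] * xi + z[1]
      if (m > 1L) z[1:(m - 1L)] <- b[2:m] * xi + z[2:m] - a[2:m] * yi
      z[m] <- b[nf] * xi - a[nf] * yi
      y[i] <- yi
    }
  }
  y
}

filtfilt_ss <- function(b, a, x) {
  nf <- max(length(a), length(b))
  npad <- 3L * nf
  n <- length(x)
  if (n <= npad)
    stop("series too short to filter: need more than ", npad, " samples")
  ext <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass forward and backward (zero phase lag,
#' squared magnitude response). Defaults match the kinematic preprocessing
#' protocol: third order, 5 Hz cutoff. Missing samples are rejected, never
#' interpolated; exclude such trials instead.
#'
#' @param series Numeric vector, or matrix with one column per coordinate.
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order (of the single pass).
#' @return Filtered series, same shape as the input.
#' @export
lowpass_filter <- function(series, sampling_rate, cutoff = 5, order = 3) {
  stopifnot(sampling_rate > 0, cutoff > 0, cutoff < sampling_rate / 2,
            order >= 1)
  if (anyNA(series))
    stop("series contains missing samples; exclude the trial rather than interpolate")
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  if (is.matrix(series)) {
    apply(series, 2, function(col) filtfilt_ss(bf$b, bf$a, col))
  } else {
    filtfilt_ss(bf$b, bf$a, as.numeric(series))
  }
}

#' Three-point numerical differentiation
#'
#' Central differences at interior samples, one-sided two-point differences
#' at the endpoints; exact for affine signals everywhere and for quadratics
#' in the interior.
#'
#' @param series Numeric vector.
#' @param sampling_rate Sampling rate in Hz.
#' @return Derivative series of the same length.
#' @export
differentiate <- function(series, sampling_rate) {
  n <- length(series)
  if (n < 3) stop("differentiation needs at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) * sampling_rate / 2
  d[1] <- (series[2] - series[1]) * sampling_rate
  d[n] <- (series[n] - series[n - 1]) * sampling_rate
  d
}

#' Tangential speed and scalar acceleration of a trajectory
#'
#' Speed is the Euclidean norm of the differentiated 3D position (tangential
#' speed, invariant to path shape); scalar acceleration is the derivative of
#' speed, so deceleration is negative. The trajectory is expected to be
#' filtered already and gap-free.
#'
#' @param positions n x 3 numeric matrix of (filtered) positions in metres.
#' @param sampling_rate Sampling rate in Hz.
#' @return List with numeric vectors `speed` (m/s) and `acceleration`
#'   (m/s^2).
#' @export
tangential_kinematics <- function(positions, sampling_rate) {
  if (anyNA(positions))
    stop("trajectory contains missing samples; trial must be excluded")
  v <- apply(positions, 2, differentiate, sampling_rate = sampling_rate)
  speed <- sqrt(rowSums(v^2))
  list(speed = speed, acceleration = differentiate(speed, sampling_rate))
}

#' Segment the movement by a percent-of-peak-speed threshold
#'
#' Onset is the first and offset the last sample at which speed strictly
#' exceeds `threshold` times its peak. A trial whose threshold crossing
#' touches the series boundary (no quiescent baseline) is flagged.
#'
#' @param speed Numeric speed series with a strictly positive maximum.
#' @param threshold Fraction of peak speed (default 0.10).
#' @return List with `onset`, `offset` (1-based sample indices) and
#'   `boundary` (logical flag).
#' @export
segment_movement <- function(speed, threshold = 0.10) {
  peak <- max(speed)
  if (!is.finite(peak) || peak <= 0)
    stop("cannot segment: speed has no strictly positive maximum")
  above <- which(speed > threshold * peak)
  onset <- above[1]
  offset <- above[length(above)]
  list(onset = onset, offset = offset,
       boundary = onset == 1L || offset == length(speed))
}

#' Extract the seven kinematic landmarks of a segmented trial
#'
#' On the window from onset to offset: movement duration
#' `MD = (offset - onset)/rate`; peak speed PV; peak acceleration PA (the
#' maximum of scalar acceleration before the speed peak); peak deceleration
#' PD (the magnitude of the minimum after the speed peak); and the relative
#' times rDPA, rDPV, rDPD of the three extrema, each expressed as
#' `100 * (index - onset)/(offset - onset)` percent of MD. Ties at an
#' extremum break to the earliest sample and are flagged.
#'
#' @param speed,acceleration Series from [tangential_kinematics()].
#' @param onset,offset Segmentation indices from [segment_movement()].
#' @param sampling_rate Sampling rate in Hz.
#' @return List of class `kinematic_landmarks`.
#' @export
extract_landmarks <- function(speed, acceleration, onset, offset,
                              sampling_rate) {
  stopifnot(onset < offset, offset <= length(speed))
  win <- onset:offset
  i_pv <- win[which.max(speed[win])]
  if (i_pv == onset || i_pv == offset)
    stop("peak speed must lie strictly inside the movement window")
  tie <- sum(speed[win] == speed[i_pv]) > 1L
  acc_win <- onset:i_pv
  dec_win <- i_pv:offset
  i_pa <- acc_win[which.max(acceleration[acc_win])]
  i_pd <- dec_win[which.min(acceleration[dec_win])]
  span <- offset - onset
  structure(list(
    onset = onset, offset = offset,
    i_pv = i_pv, i_pa = i_pa, i_pd = i_pd,
    MD = span / sampling_rate,
    PV = speed[i_pv],
    PA = acceleration[i_pa],
    PD = abs(acceleration[i_pd]),
    rDPV = 100 * (i_pv - onset) / span,
    rDPA = 100 * (i_pa - onset) / span,
    rDPD = 100 * (i_pd - onset) / span,
    tie_at_peak = tie
  ), class = "kinematic_landmarks")
}

# Full single-trial pipeline: filter positions, differentiate, segment,
# extract. Returns NULL for trials with missing samples.
trial_kinematics <- function(traj, config = analysis_config()) {
  if (has_missing_samples(traj)) return(NULL)
  pos <- as.matrix(traj$samples[c("x", "y", "z")])
  pos <- lowpass_filter(pos, traj$sampling_rate,
                        cutoff = config$cutoff_hz,
                        order = config$filter_order)
  kin <- tangential_kinematics(pos, traj$sampling_rate)
  seg <- segment_movement(kin$speed, threshold = config$onset_threshold)
  lm <- extract_landmarks(kin$speed, kin$acceleration, seg$onset, seg$offset,
                          traj$sampling_rate)
  list(speed = kin$speed, acceleration = kin$acceleration,
       landmarks = lm, boundary = seg$boundary)
}

#' Per-trial landmark table
#'
#' Runs the preprocessing/segmentation/landmark pipeline on every trial.
#' Trials with missing motion samples keep their row, with `NA` landmarks
#' and `missing_data = TRUE`, so the exclusion stage can log them.
#'
#' @param trials List of [trial_trajectory()] objects.
#' @param config An [analysis_config()].
#' @return data.frame with one row per trial: labels, onset/offset indices,
#'   the seven landmarks, and flags.
#' @export
landmark_table <- function(trials, config = analysis_config()) {
  rows <- lapply(trials, function(tr) {
    lab <- trial_labels(tr)
    kin <- trial_kinematics(tr, config)
    if (is.null(kin)) {
      cbind(lab, onset = NA_integer_, offset = NA_integer_,
            MD = NA_real_, PV = NA_real_, PA = NA_real_, PD = NA_real_,
            rDPV = NA_real_, rDPA = NA_real_, rDPD = NA_real_,
            missing_data = TRUE, boundary = FALSE, tie_at_peak = FALSE)
    } else {
      lm <- kin$landmarks
      cbind(lab, onset = lm$onset, offset = lm$offset,
            MD = lm$MD, PV = lm$PV, PA = lm$PA, PD = lm$PD,
            rDPV = lm$rDPV, rDPA = lm$rDPA, rDPD = lm$rDPD,
            missing_data = FALSE, boundary = kin$boundary,
            tie_at_peak = lm$tie_at_peak)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the trial-exclusion rules
#'
#' Removes (a) trials with missing motion samples and (b) trials whose
#' movement duration strictly exceeds the pool mean by more than three pool
#' standard deviations. The pool is the grand pool: all trials of all
#' participants with valid landmarks (missing-data trials removed first).
#' A trial exactly at mean + 3 SD is retained; the rule is strictly
#' "exceeded".
#'
#' @param landmarks Landmark table from [landmark_table()].
#' @param md_sd_limit SD multiple of the duration rule (default 3).
#' @return List with `retained` (landmark table subset) and `log`
#'   (data.frame: labels, rule, statistic).
#' @export
exclude_trials <- function(landmarks, md_sd_limit = 3) {
  lab_cols <- c("participant", "posture", "environment", "direction",
                "block", "trial")
  missing <- landmarks$missing_data
  pool <- landmarks[!missing, , drop = FALSE]
  log <- data.frame()
  if (any(missing)) {
    log <- cbind(landmarks[missing, lab_cols, drop = FALSE],
                 rule = "missing_data", statistic = NA_real_)
  }
  if (nrow(pool) > 1) {
    m <- mean(pool$MD)
    s <- stats::sd(pool$MD)
    z <- (pool$MD - m) / s
    out <- z > md_sd_limit
    if (any(out)) {
      log <- rbind(log, cbind(pool[out, lab_cols, drop = FALSE],
                              rule = "duration_outlier", statistic = z[out]))
      pool <- pool[!out, , drop = FALSE]
    }
  }
  if (nrow(pool) == 0L) warning("all trials excluded")
  rownames(pool) <- NULL
  rownames(log) <- NULL
  list(retained = pool, log = log)
}
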