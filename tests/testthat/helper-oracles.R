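# Shared oracles and fixture builders. All oracles are computed from first
# principles (dense closed-form evaluation, enumeration) independently of
# the package's own code paths.

# rDPV / rDPA / rDPD of the analytic beta speed curve after truncation at
# the 10%-of-peak threshold, by dense numerical evaluation.
oracle_beta_rdpv <- function(rdpv_target, threshold = 0.10,
                             n_grid = 200001) {
  a <- 1 + 4 * rdpv_target / 100
  b <- 5 - 4 * rdpv_target / 100
  tau <- seq(0, 1, length.out = n_grid)
  v <- dbeta(tau, a, b)
  above <- which(v > threshold * max(v))
  t_on <- tau[above[1]]
  t_off <- tau[above[length(above)]]
  100 * (tau[which.max(v)] - t_on) / (t_off - t_on)
}

# Continuous 10%-crossing times of the analytic beta curve (fractions of
# duration), by root finding.
oracle_beta_crossings <- function(rdpv_target, threshold = 0.10) {
  a <- 1 + 4 * rdpv_target / 100
  b <- 5 - 4 * rdpv_target / 100
  mode <- rdpv_target / 100
  peak <- dbeta(mode, a, b)
  f <- function(x) dbeta(x, a, b) - threshold * peak
  c(on = uniroot(f, c(1e-9, mode), tol = 1e-12)$root,
    off = uniroot(f, c(mode, 1 - 1e-9), tol = 1e-12)$root)
}

# Participant-by-cell mean table for one parameter, simulated directly at
# the aggregation level: value = subject effect + cell mean + noise.
make_cell_table <- function(n = 27, mu = function(posture, environment,
                                                  direction) 48,
                            subj_sd = 2, noise_sd = 3,
                            parameter = "rDPV") {
  grid <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                      posture = c("upright", "lying"),
                      environment = c("virtual", "physical"),
                      direction = c("up", "down", "left", "right"),
                      stringsAsFactors = FALSE)
  subj <- rnorm(n, 0, subj_sd)
  names(subj) <- sprintf("P%02d", seq_len(n))
  grid$parameter <- parameter
  grid$value <- subj[grid$participant] +
    mapply(mu, grid$posture, grid$environment, grid$direction) +
    rnorm(nrow(grid), 0, noise_sd)
  grid$n_trials <- 12L
  grid
}

# One noiseless synthetic trial with fixed generative parameters.
make_noiseless_trial <- function(rdpv, duration = 0.5, seed = 1) {
  cfg <- sim_config(noise_sd = 0, seed = seed)
  synthesize_trial(cfg, "P01", "upright", "virtual", "up", 1, 1,
                   duration = duration, rdpv = rdpv)
}

# Landmarks from a speed series without any filtering (pure
# segmentation + extraction), as used by the recovery oracle checks.
unfiltered_landmarks <- function(traj) {
  pos <- as.matrix(traj$samples[c("x", "y", "z")])
  kin <- tangential_kinematics(pos, traj$sampling_rate)
  seg <- segment_movement(kin$speed)
  extract_landmarks(kin$speed, kin$acceleration, seg$onset, seg$offset,
                    traj$sampling_rate)
}
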