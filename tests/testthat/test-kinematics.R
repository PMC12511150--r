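test_that("zero-phase filter: DC gain, phase, attenuation bound", {
  # a constant passes through exactly (steady-state initial conditions)
  expect_equal(lowpass_filter(rep(2, 100), 120), rep(2, 100),
               tolerance = 1e-12)
  # zero phase: a symmetric Gaussian bump keeps its peak sample
  t <- seq_len(301)
  bump <- exp(-(t - 151)^2 / (2 * 20^2))
  expect_identical(which.max(lowpass_filter(bump, 120)), 151L)
  # a 20 Hz sinusoid is attenuated at least as much as the squared
  # analog-prototype magnitude |H(f)|^2 = 1/(1 + (f/fc)^(2*order))
  x <- sin(2 * pi * 20 * (0:599) / 120)
  y <- lowpass_filter(x, 120)
  bound <- 1 / (1 + (20 / 5)^6)
  expect_lte(max(abs(y[200:400])), bound)
})

test_that("filter rejects short series and missing samples", {
  expect_error(lowpass_filter(rep(1, 10), 120), "too short")
  expect_error(lowpass_filter(c(rep(1, 50), NA, rep(1, 50)), 120), "missing")
})

test_that("three-point differentiation is exact for low-order polynomials", {
  fs <- 120
  t <- (0:99) / fs
  expect_equal(differentiate(3 + 2.5 * t, fs), rep(2.5, 100))  # affine
  d <- differentiate(t^2, fs)
  expect_equal(d[2:99], 2 * t[2:99])                           # quadratic
  expect_equal(differentiate(rep(7, 50), fs), rep(0, 50))
  expect_error(differentiate(c(1, 2), fs), "at least 3")
})

test_that("tangential speed is path-shape invariant", {
  fs <- 120
  t <- (0:199) / fs
  # pure linear motion: speed |k|, zero interior acceleration
  pos <- cbind(-0.4 * t, 0 * t, 0 * t)
  kin <- tangential_kinematics(pos, fs)
  expect_equal(kin$speed, rep(0.4, 200))
  expect_equal(kin$acceleration[3:198], rep(0, 196))
  # uniform circular motion: constant speed ~ r*omega, scalar acceleration
  # ~ 0 even though the vector acceleration is centripetal
  r <- 0.1; om <- 2 * pi
  pos <- cbind(r * cos(om * t), r * sin(om * t), 0 * t)
  kin <- tangential_kinematics(pos, fs)
  expect_equal(kin$speed[3:198], rep(r * om, 196), tolerance = 1e-3)
  expect_lt(max(abs(kin$acceleration[3:198])), 1e-9)
  expect_error(tangential_kinematics(cbind(c(1, NA, 1), 0, 0), fs),
               "excluded")
})

test_that("threshold segmentation finds the 10% crossings", {
  # symmetric triangle: onset/offset symmetric about the peak
  sp <- c(rep(0, 10), seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1],
          rep(0, 10))
  seg <- segment_movement(sp)
  peak <- which.max(sp)
  expect_identical(peak - seg$onset, seg$offset - peak)
  expect_false(seg$boundary)
  expect_error(segment_movement(rep(0, 100)), "strictly positive")
  # crossing at the series boundary flags the trial
  expect_true(segment_movement(seq(0, 1, length.out = 50))$boundary)
})

test_that("segmentation matches analytic 10% crossings of the beta curve", {
  n <- 2000
  tau <- (0:n) / n
  sp <- dbeta(tau, 1 + 4 * 0.45, 5 - 4 * 0.45)
  seg <- segment_movement(sp)
  cross <- oracle_beta_crossings(45)
  expect_lte(abs((seg$onset - 1) / n - cross["on"]), 1 / n)
  expect_lte(abs((seg$offset - 1) / n - cross["off"]), 1 / n)
})

test_that("landmark extraction: symmetric fixture, ordering, monotonicity", {
  # minimum-jerk (symmetric) profile measures rDPV = 50 +- 1 through the
  # full filtered pipeline
  lt <- landmark_table(list(make_noiseless_trial(50)))
  expect_lt(abs(lt$rDPV - 50), 1)
  # unimodal profiles order the landmarks rDPA < rDPV < rDPD
  for (r in c(40, 50, 60)) {
    lt <- landmark_table(list(make_noiseless_trial(r)))
    expect_true(lt$rDPA < lt$rDPV && lt$rDPV < lt$rDPD)
    expect_true(lt$PV > 0 && lt$PA > 0 && lt$PD > 0)
  }
  # measured rDPV is monotone in the generative target
  lt44 <- landmark_table(list(make_noiseless_trial(44)))
  lt52 <- landmark_table(list(make_noiseless_trial(52)))
  expect_lt(lt44$rDPV, lt52$rDPV)
})

test_that("ties at the speed maximum break to the earliest sample", {
  sp <- c(rep(0, 5), 1:10, 10, 10:1, rep(0, 5)) / 10
  acc <- differentiate(sp, 100)
  seg <- segment_movement(sp)
  lm <- extract_landmarks(sp, acc, seg$onset, seg$offset, 100)
  expect_true(lm$tie_at_peak)
  expect_identical(lm$i_pv, which(sp == max(sp))[1])
})

test_that("noiseless landmark extraction matches the dense analytic oracle", {
  for (r in seq(35, 65, 5)) {
    lm <- unfiltered_landmarks(make_noiseless_trial(r, duration = 0.5))
    one_sample_pct <- 100 / (lm$offset - lm$onset)
    expect_lte(abs(lm$rDPV - oracle_beta_rdpv(r)), one_sample_pct)
  }
})

test_that("the 5 Hz filter biases rDPV toward symmetry by at most 2 points", {
  # the zero-phase low-pass symmetrizes fast asymmetric profiles slightly;
  # the bias is bounded and vanishes at the symmetric target
  for (r in c(35, 40, 50, 60, 65)) {
    tr <- make_noiseless_trial(r, duration = 0.5)
    measured <- landmark_table(list(tr))$rDPV
    bias <- measured - oracle_beta_rdpv(r)
    expect_lte(abs(bias), 2)
    if (r < 50) expect_gte(bias, -0.1)   # pushed toward 50, not away
    if (r > 50) expect_lte(bias, 0.1)
  }
})

test_that("filtering an already-filtered series barely moves landmarks", {
  # rDPV is quantized in steps of one sample (~2 points for a 0.4 s
  # movement at 120 Hz), so idempotence holds to within that granularity
  lm_of <- function(p) {
    kin <- tangential_kinematics(p, 120)
    seg <- segment_movement(kin$speed)
    extract_landmarks(kin$speed, kin$acceleration, seg$onset, seg$offset,
                      120)
  }
  for (r in c(45, 48, 51)) {
    tr <- make_noiseless_trial(r)
    pos <- as.matrix(tr$samples[c("x", "y", "z")])
    once <- lm_of(lowpass_filter(pos, 120))
    twice <- lm_of(lowpass_filter(lowpass_filter(pos, 120), 120))
    one_sample_pct <- 100 / (once$offset - once$onset)
    expect_lte(abs(once$rDPV - twice$rDPV), one_sample_pct)
  }
})

test_that("landmarks are scale-equivariant and time-reversal covariant", {
  tr <- make_noiseless_trial(44)
  lm <- unfiltered_landmarks(tr)
  # scaling positions by s scales PV/PA/PD and leaves MD and rDPX
  # unchanged; a power-of-two factor keeps the check bit-exact
  s <- 2
  scaled <- tr
  scaled$samples[c("x", "y", "z")] <- tr$samples[c("x", "y", "z")] * s
  lm_s <- unfiltered_landmarks(scaled)
  expect_equal(lm_s$PV, s * lm$PV)
  expect_equal(lm_s$PA, s * lm$PA)
  expect_equal(lm_s$PD, s * lm$PD)
  expect_identical(lm_s$MD, lm$MD)
  expect_identical(c(lm_s$rDPV, lm_s$rDPA, lm_s$rDPD),
                   c(lm$rDPV, lm$rDPA, lm$rDPD))
  # reversing the samples swaps rDPV -> 100 - rDPV (one-sample quantization)
  rev_tr <- tr
  rev_tr$samples[c("x", "y", "z")] <-
    tr$samples[rev(seq_len(nrow(tr$samples))), c("x", "y", "z")]
  lm_r <- unfiltered_landmarks(rev_tr)
  one_sample_pct <- 100 / (lm$offset - lm$onset)
  expect_lte(abs(lm_r$rDPV - (100 - lm$rDPV)), one_sample_pct)
})

test_that("exclusion rules: boundary semantics and clean data", {
  # a landmark table with no corruption loses nothing
  sim <- simulate_study(sim_config(design = study_design(n_participants = 1),
                                   n_outlier_trials = 0,
                                   n_missing_trials = 0, seed = 2))
  ex <- exclude_trials(landmark_table(sim$trials))
  expect_identical(nrow(ex$log), 0L)
  expect_identical(nrow(ex$retained), length(sim$trials))

  # a trial exactly at mean + 3 SD is retained: the rule is strictly
  # "exceeded". Solve for the fixed point x = mean(c(base, x)) + 3 sd(...).
  base <- rep(c(0.45, 0.47, 0.48, 0.50, 0.52, 0.53, 0.55), 5)
  x_at <- uniroot(function(x) x - mean(c(base, x)) - 3 * sd(c(base, x)),
                  c(0.56, 5), tol = 1e-12)$root
  x_at <- x_at - 1e-9  # guard the fixed point against float round-off
  fake <- function(md) data.frame(
    participant = "P01", posture = "upright", environment = "virtual",
    direction = "up", block = 1L, trial = seq_along(md), onset = 1L,
    offset = 50L, MD = md, PV = 1, PA = 1, PD = 1, rDPV = 50, rDPA = 30,
    rDPD = 70, missing_data = FALSE, boundary = FALSE, tie_at_peak = FALSE)
  expect_identical(nrow(exclude_trials(fake(c(base, x_at)))$log), 0L)
  ex2 <- exclude_trials(fake(c(base, x_at + 1e-3)))
  expect_identical(nrow(ex2$log), 1L)
  expect_identical(ex2$log$rule, "duration_outlier")
})
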