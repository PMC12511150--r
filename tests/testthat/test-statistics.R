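test_that("cell aggregation: means, invariance, completeness", {
  sim <- simulate_study(sim_config(design = study_design(n_participants = 2),
                                   n_outlier_trials = 0,
                                   n_missing_trials = 0, seed = 6))
  lt <- exclude_trials(landmark_table(sim$trials))$retained
  cells <- aggregate_cells(lt)
  # every participant has 16 cells x 7 parameters
  expect_identical(nrow(cells), 2L * 16L * 7L)
  expect_true(all(cells$n_trials == 12))
  # a single-trial cell's mean equals that trial's value
  one <- lt[1, , drop = FALSE]
  c1 <- aggregate_cells(one)
  expect_identical(c1$value[c1$parameter == "rDPV"], one$rDPV)
  # permuting trial order leaves the means unchanged
  cells_perm <- aggregate_cells(lt[rev(seq_len(nrow(lt))), ])
  expect_equal(cells_perm, cells)
})

test_that("Shapiro-Wilk wrapper: calibration, power, degeneracy", {
  set.seed(31)
  # type-I calibration at alpha = 0.05
  rej <- mean(replicate(1000, shapiro_wilk(rnorm(500))$p < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # power against strong skew
  p_exp <- replicate(200, shapiro_wilk(rexp(500))$p)
  expect_gte(mean(p_exp < 0.001), 0.99)
  expect_error(shapiro_wilk(rep(1, 30)), "degenerate")
})

test_that("normality gate: family pass rate, skew sensitivity, determinism", {
  set.seed(17)
  n_rep <- 400
  gaussian_par <- 0
  skew_nonpar <- 0
  for (i in seq_len(n_rep)) {
    cells <- make_cell_table(n = 27, subj_sd = 0, noise_sd = 1)
    if (normality_gate(cells, "rDPV")$branch == "parametric")
      gaussian_par <- gaussian_par + 1
    # corrupt one cell with a heavily skewed distribution
    idx <- with(cells, posture == "lying" & environment == "physical" &
                  direction == "up")
    cells$value[idx] <- rlnorm(sum(idx), 0, 1.5)
    if (normality_gate(cells, "rDPV")$branch == "nonparametric")
      skew_nonpar <- skew_nonpar + 1
  }
  # 16 independent tests at 0.05: family pass rate ~ 0.95^16 ~ 0.44
  expect_gte(gaussian_par / n_rep, 0.35)
  expect_gte(skew_nonpar / n_rep, 0.99)
  # determinism
  set.seed(1); cells <- make_cell_table(n = 10)
  expect_identical(normality_gate(cells, "rDPV")$branch,
                   normality_gate(cells, "rDPV")$branch)
})

test_that("RM-ANOVA: null data, df bookkeeping, epsilon bounds", {
  # no between-condition variation: all F = 0, p = 1
  set.seed(23)
  cells <- make_cell_table(n = 8)
  m <- matrix(cells$value, nrow = 8)
  cells$value <- as.vector(m - rep(colMeans(matrix(cells$value, 8)),
                                   each = 8))
  res <- rm_anova_3way(cells, "rDPV")
  expect_equal(res$F, rep(0, 7))
  expect_equal(res$p, rep(1, 7))

  # df for the 4-level direction effect at n = 27 is (3, 78)
  set.seed(24)
  res27 <- rm_anova_3way(make_cell_table(n = 27), "rDPV")
  dir_row <- res27[res27$effect == "direction", ]
  expect_identical(c(dir_row$df1, dir_row$df2), c(3, 78))
  # epsilon = 1 exactly for 2-level factors; within [1/(k-1), 1] otherwise
  expect_equal(res27$gg_epsilon[res27$effect == "posture"], 1)
  expect_true(all(res27$gg_epsilon >= 1 / 3 - 1e-12 &
                    res27$gg_epsilon <= 1 + 1e-12))
  # partial eta squared identity
  expect_equal(res27$pes, res27$SS / (res27$SS + res27$SS_error))
})

test_that("RM-ANOVA decomposition conserves total sum of squares", {
  set.seed(25)
  for (i in 1:5) {
    cells <- make_cell_table(n = 5 + i)
    res <- rm_anova_3way(cells, "rDPV")
    total <- attr(res, "SS_total")
    parts <- sum(res$SS) + sum(res$SS_error) + attr(res, "SS_participants")
    expect_lt(abs(total - parts) / total, 1e-9)
  }
})

test_that("RM-ANOVA matches the aov error-strata oracle", {
  set.seed(26)
  cells <- make_cell_table(n = 5)
  res <- rm_anova_3way(cells, "rDPV")
  d <- cells
  d$P <- factor(d$posture); d$E <- factor(d$environment)
  d$D <- factor(d$direction); d$S <- factor(d$participant)
  fit <- summary(stats::aov(value ~ P * E * D + Error(S / (P * E * D)),
                            data = d))
  map <- c(posture = "P", environment = "E", direction = "D",
           "posture:environment" = "P:E", "posture:direction" = "P:D",
           "environment:direction" = "E:D",
           "posture:environment:direction" = "P:E:D")
  for (eff in names(map)) {
    stratum <- fit[[paste0("Error: S:", gsub(":", ":", map[eff]))]][[1]]
    mine <- res[res$effect == eff, ]
    expect_equal(mine$SS, stratum["Sum Sq"][[1]][1], tolerance = 1e-9)
    expect_equal(mine$SS_error, stratum["Sum Sq"][[1]][2], tolerance = 1e-9)
    expect_equal(mine$F, stratum["F value"][[1]][1], tolerance = 1e-9)
    expect_equal(unname(c(mine$df1, mine$df2)),
                 unname(stratum["Df"][[1]]), tolerance = 1e-12)
  }
})

test_that("sphericity machinery matches the car::Anova oracle", {
  skip_if_not_installed("car")
  set.seed(27)
  cells <- make_cell_table(n = 8)
  res <- rm_anova_3way(cells, "rDPV")
  m <- reachkin:::cell_matrix(cells, "rDPV")  # canonical cell order
  idata <- expand.grid(direction = factor(c("up", "down", "left", "right"),
                                          levels = c("up", "down", "left",
                                                     "right")),
                       environment = factor(c("virtual", "physical"),
                                            levels = c("virtual",
                                                       "physical")),
                       posture = factor(c("upright", "lying"),
                                        levels = c("upright", "lying")))
  fit <- car::Anova(stats::lm(m ~ 1), idata = idata,
                    idesign = ~ posture * environment * direction, type = 3)
  # car warns about clamping the Huynh-Feldt epsilon, which is not compared
  s <- suppressWarnings(summary(fit, multivariate = FALSE))
  sph <- s$sphericity.tests
  gg <- s$pval.adjustments
  for (eff in rownames(sph)) {
    mine <- res[res$effect == gsub(" ", "", tolower(eff)), ]
    expect_equal(mine$mauchly_W, unname(sph[eff, "Test statistic"]),
                 tolerance = 1e-8)
    expect_equal(mine$mauchly_p, unname(sph[eff, "p-value"]),
                 tolerance = 1e-8)
    expect_equal(mine$gg_epsilon, unname(gg[eff, "GG eps"]),
                 tolerance = 1e-8)
  }
})

test_that("Friedman: degenerate input, rank invariances", {
  cells <- make_cell_table(n = 4, subj_sd = 0, noise_sd = 0)
  cells$value <- cells$value + match(cells$participant,
                                     unique(cells$participant))
  # constant within participant: statistic 0, p 1
  fr <- friedman_cells(cells, "rDPV")
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p, 1)
  # invariant under strictly monotone transforms and per-participant shifts
  set.seed(33)
  cells <- make_cell_table(n = 6)
  f0 <- friedman_cells(cells, "rDPV")
  mono <- cells; mono$value <- exp(mono$value / 10)
  expect_equal(friedman_cells(mono, "rDPV")$statistic, f0$statistic)
  shift <- cells
  one <- shift$participant == shift$participant[1]
  shift$value[one] <- shift$value[one] + 100
  expect_equal(friedman_cells(shift, "rDPV")$statistic, f0$statistic)
})

test_that("Wilcoxon signed-rank: symmetry, oracle equality, degeneracy", {
  # antisymmetric difference multiset: centred statistic, p = 1
  w <- wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(w$p, 1)
  # exact path agrees with wilcox.test on tie-free data
  set.seed(41)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(wilcoxon_signed_rank(x, y)$p,
                 stats::wilcox.test(x, y, paired = TRUE,
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
})

test_that("Wilcoxon null calibration at the Bonferroni threshold", {
  set.seed(42)
  rej <- mean(replicate(10000,
    wilcoxon_signed_rank(rnorm(27), rnorm(27))$p < 0.003125))
  expect_lte(rej, 0.004)
})

test_that("planned comparisons: structure and Bonferroni bookkeeping", {
  pairs <- planned_pairs()
  expect_identical(nrow(pairs), 16L)
  expect_identical(sum(pairs$family == "environment"), 8L)
  expect_identical(sum(pairs$family == "direction"), 8L)
  # vertical vs lateral contrasts are never produced
  vert <- c("up", "down")
  expect_false(any(pairs$direction_a %in% vert != pairs$direction_b %in% vert))

  set.seed(51)
  cells <- make_cell_table(n = 10)
  comp <- planned_comparisons(cells, "rDPV", branch = "nonparametric")
  expect_identical(nrow(comp), 16L)
  expect_equal(unique(comp$p_threshold) * 16, 0.05)
  expect_identical(comp$significant, comp$p < comp$p_threshold)
  # parametric branch runs paired t contrasts
  comp_t <- planned_comparisons(cells, "rDPV", branch = "parametric")
  expect_true(all(comp_t$test == "paired_t"))
  # the signed-rank statistic ranks the pair differences, so it is
  # invariant under increasing affine transforms of the values
  aff <- cells; aff$value <- 2 * aff$value + 10
  expect_equal(planned_comparisons(aff, "rDPV", branch = "nonparametric")$statistic,
               comp$statistic)
})

test_that("simple main effects form a Bonferroni family of four", {
  set.seed(52)
  cells <- make_cell_table(n = 10)
  sme <- simple_main_effects(cells, "rDPV")
  expect_identical(nrow(sme), 4L)
  expect_equal(unique(sme$p_threshold), 0.05 / 4)
})
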