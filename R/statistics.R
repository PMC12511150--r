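KINEMATIC_PARAMETERS <- c("MD", "PV", "PA", "PD", "rDPV", "rDPA", "rDPD")

#' Aggregate retained trials to participant-by-cell means
#'
#' The analysis unit of the inferential stage: the arithmetic mean of each
#' kinematic parameter over a participant's retained trials within each
#' posture-by-environment-by-direction cell (16 cells per participant).
#'
#' @param landmarks Retained landmark table (see [exclude_trials()]).
#' @return Long data.frame: `participant`, `posture`, `environment`,
#'   `direction`, `parameter`, `value`, `n_trials`.
#' @export
aggregate_cells <- function(landmarks) {
  stopifnot(nrow(landmarks) > 0, !any(landmarks$missing_data))
  long <- do.call(rbind, lapply(KINEMATIC_PARAMETERS, function(p) {
    data.frame(participant = landmarks$participant,
               posture = landmarks$posture,
               environment = landmarks$environment,
               direction = landmarks$direction,
               parameter = p, value = landmarks[[p]],
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(value ~ participant + posture + environment +
                            direction + parameter, data = long, FUN = mean)
  cnt <- stats::aggregate(value ~ participant + posture + environment +
                            direction + parameter, data = long, FUN = length)
  agg$n_trials <- cnt$value[match(
    with(agg, paste(participant, posture, environment, direction, parameter)),
    with(cnt, paste(participant, posture, environment, direction, parameter)))]
  ord <- order(agg$parameter, agg$participant,
               match(agg$posture, POSTURE_LEVELS),
               match(agg$environment, ENVIRONMENT_LEVELS),
               match(agg$direction, DIRECTION_LEVELS))
  agg <- agg[ord, ]
  rownames(agg) <- NULL
  agg
}

# Extract the n x 16 participant-by-cell matrix for one parameter, columns
# in canonical cell order; errors on missing cells.
cell_matrix <- function(cells, parameter) {
  d <- cells[cells$parameter == parameter, , drop = FALSE]
  if (nrow(d) == 0) stop("no cell means for parameter ", parameter)
  grid <- expand.grid(direction = DIRECTION_LEVELS,
                      environment = ENVIRONMENT_LEVELS,
                      posture = POSTURE_LEVELS, stringsAsFactors = FALSE)
  keys <- cell_key(grid$posture, grid$environment, grid$direction)
  participants <- sort(unique(d$participant))
  m <- matrix(NA_real_, length(participants), length(keys),
              dimnames = list(participants, keys))
  m[cbind(match(d$participant, participants),
          match(cell_key(d$posture, d$environment, d$direction), keys))] <-
    d$value
  if (anyNA(m))
    stop("missing cells for parameter ", parameter,
         "; every participant needs all 16 condition cells")
  m
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] that rejects degenerate
#' (constant) samples explicitly.
#'
#' @param values Numeric vector, 3 to 5000 observations.
#' @return List: `statistic` (W), `p`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires between 3 and 5000 observations")
  if (stats::sd(values) == 0)
    stop("degenerate input: values are constant")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Decide the parametric vs non-parametric analysis branch
#'
#' One Shapiro-Wilk test per condition cell (16 tests across participants);
#' the branch is non-parametric as soon as any cell rejects normality at
#' `alpha`. The granularity is per parameter, matching how gate decisions
#' are reported in practice ("across all conditions").
#'
#' @param cells Cell-mean table from [aggregate_cells()].
#' @param parameter One of `r paste(KINEMATIC_PARAMETERS, collapse = ", ")`.
#' @param alpha Per-cell test level (default 0.05).
#' @return List: `branch` ("parametric"/"nonparametric"), `tests`
#'   (data.frame of per-cell W and p).
#' @export
normality_gate <- function(cells, parameter, alpha = 0.05) {
  m <- cell_matrix(cells, parameter)
  tests <- data.frame(cell = colnames(m), W = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(m))) {
    sw <- shapiro_wilk(m[, j])
    tests$W[j] <- sw$statistic
    tests$p[j] <- sw$p
  }
  branch <- if (any(tests$p < alpha)) "nonparametric" else "parametric"
  list(branch = branch, tests = tests)
}

# -- three-way repeated-measures ANOVA --------------------------------------

# Orthonormal within-factor contrast rows ((k-1) x k), orthogonal to the
# unit vector.
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  t(sweep(h, 2, sqrt(colSums(h^2)), "/"))
}

# Inclusion-exclusion effect array for the margin `dims` of `arr`.
margin_effect <- function(arr, dims) {
  d <- dim(arr)
  out <- array(0, d[dims])
  idx <- as.matrix(expand.grid(lapply(d[dims], seq_len)))
  subsets <- unlist(lapply(0:length(dims), function(k)
    utils::combn(seq_along(dims), k, simplify = FALSE)), recursive = FALSE)
  for (sub in subsets) {
    sgn <- (-1)^(length(dims) - length(sub))
    if (length(sub) == 0) {
      out <- out + sgn * mean(arr)
    } else {
      mt <- apply(arr, dims[sub], mean)
      vals <- if (length(sub) == 1) mt[idx[, sub]] else
        mt[idx[, sub, drop = FALSE]]
      out <- out + sgn * array(vals, d[dims])
    }
  }
  out
}

#' Three-way repeated-measures ANOVA (fully within-participant)
#'
#' Balanced 2 x 2 x 4 within-participant decomposition with the participant
#' as random factor: each of the seven effects (three mains, three two-way,
#' one three-way interaction) is tested against its own
#' effect-by-participant error term. Effect sizes are partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. For effects with more than 1
#' numerator df, Mauchly's sphericity test is run on the orthonormalized
#' contrast scores; when it rejects at `alpha_sphericity`, the
#' Greenhouse-Geisser epsilon multiplies both degrees of freedom and the
#' reported p-value uses the corrected reference distribution.
#'
#' @param cells Cell-mean table from [aggregate_cells()], or any data.frame
#'   with `participant`, `posture`, `environment`, `direction`, `value`.
#' @param parameter Parameter to analyse when `cells` carries several.
#' @param alpha_sphericity Level of Mauchly's test gating the correction.
#' @return data.frame with one row per effect: SS, df, F, p (corrected where
#'   applicable), partial eta squared, Mauchly W/p, epsilon. Attributes
#'   `SS_participants` and `SS_total` carry the remaining decomposition
#'   terms.
#' @export
rm_anova_3way <- function(cells, parameter = NULL, alpha_sphericity = 0.05) {
  if (!is.null(parameter)) {
    m <- cell_matrix(cells, parameter)
  } else {
    cells$parameter <- "value"
    m <- cell_matrix(cells, "value")
  }
  n <- nrow(m)
  if (n < 2) stop("repeated-measures ANOVA needs at least 2 participants")
  ks <- c(length(DIRECTION_LEVELS), length(ENVIRONMENT_LEVELS),
          length(POSTURE_LEVELS))
  # columns of m vary direction fastest, then environment, then posture
  arr <- array(m, c(n, ks))  # dims: subject, direction, environment, posture
  factor_dims <- c(direction = 2L, environment = 3L, posture = 4L)

  effect_names <- list("posture", "environment", "direction",
                       c("posture", "environment"),
                       c("posture", "direction"),
                       c("environment", "direction"),
                       c("posture", "environment", "direction"))
  rows <- lapply(effect_names, function(fs) {
    dims <- unname(factor_dims[fs])
    k_eff <- prod(dim(arr)[dims] - 1)
    ss_eff <- prod(dim(arr)[-dims]) * sum(margin_effect(arr, dims)^2)
    ss_err <- prod(dim(arr)[-c(1L, dims)]) *
      sum(margin_effect(arr, c(1L, dims))^2)
    df1 <- k_eff
    df2 <- k_eff * (n - 1)
    ms_eff <- ss_eff / df1
    ms_err <- ss_err / df2
    f <- ms_eff / ms_err
    p_unc <- stats::pf(f, df1, df2, lower.tail = FALSE)

    W <- NA_real_; p_mauchly <- NA_real_; eps <- 1
    corrected <- FALSE
    if (df1 > 1) {
      C <- 1
      for (fac in c("direction", "environment", "posture")) {
        k <- dim(arr)[factor_dims[fac]]
        Mi <- if (fac %in% fs) orthonormal_contrasts(k) else
          matrix(1 / sqrt(k), 1, k)
        C <- kronecker(Mi, C)  # direction index varies fastest in m
      }
      U <- m %*% t(C)
      S <- stats::cov(U)
      d <- df1
      eps <- if (sum(S * S) > 0) sum(diag(S))^2 / (d * sum(S * S)) else 1
      if (n - 1 >= d) {
        W <- det(S) / (sum(diag(S)) / d)^d
        if (W > 0) {
          # Mauchly's chi-squared approximation with the second-order Box
          # correction term
          nmp <- n - 1
          rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nmp)
          # the 3*p term counts the original repeated-measures columns (16
          # cells), following the reference implementations
          w2 <- (d + 2) * (d - 1) * (d - 2) *
            (2 * d^3 + 6 * d^2 + 3 * ncol(m) + 2) /
            (288 * d^2 * nmp^2 * rho^2)
          z <- -nmp * rho * log(W)
          fdf <- d * (d + 1) / 2 - 1
          pr1 <- stats::pchisq(z, fdf, lower.tail = FALSE)
          pr2 <- stats::pchisq(z, fdf + 4, lower.tail = FALSE)
          p_mauchly <- pr1 + w2 * (pr2 - pr1)
        }
      }
      corrected <- isTRUE(p_mauchly < alpha_sphericity)
    }
    df1_used <- if (corrected) eps * df1 else df1
    df2_used <- if (corrected) eps * df2 else df2
    p <- if (corrected)
      stats::pf(f, df1_used, df2_used, lower.tail = FALSE) else p_unc
    if (ss_eff == 0 && ss_err == 0) { f <- 0; p <- 1; p_unc <- 1 }
    data.frame(effect = paste(fs, collapse = ":"),
               SS = ss_eff, SS_error = ss_err,
               df1 = df1, df2 = df2, F = f,
               p_uncorrected = p_unc,
               pes = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
               mauchly_W = W, mauchly_p = p_mauchly,
               gg_epsilon = eps, sphericity_corrected = corrected,
               df1_used = df1_used, df2_used = df2_used, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  subj_dev <- margin_effect(arr, 1L)
  attr(out, "SS_participants") <- prod(dim(arr)[-1]) * sum(subj_dev^2)
  attr(out, "SS_total") <- sum((arr - mean(arr))^2)
  out
}

#' Friedman test over the 16 condition cells
#'
#' Non-parametric omnibus test of the participant-by-cell means: ranks
#' within each participant (average ranks for ties), chi-squared reference
#' with 15 df.
#'
#' @param cells Cell-mean table from [aggregate_cells()].
#' @param parameter Parameter to test.
#' @return List: `statistic` (chi-squared), `df`, `p`.
#' @export
friedman_cells <- function(cells, parameter) {
  m <- cell_matrix(cells, parameter)
  if (nrow(m) < 2) stop("Friedman test needs at least 2 participants")
  if (all(apply(m, 1, function(r) max(r) == min(r)))) {
    # every participant ranks all cells as tied: no information, no effect
    return(list(statistic = 0, df = ncol(m) - 1, p = 1))
  }
  ht <- stats::friedman.test(m)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# Exact null distribution of the signed-rank statistic (sum of positive
# ranks) by convolution over 2*rank integer units; handles average ranks.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  M <- sum(r2)
  f <- numeric(M + 1)
  f[1] <- 1
  for (r in r2) {
    g <- numeric(M + 1)
    g[(r + 1):(M + 1)] <- f[1:(M + 1 - r)]
    f <- f + g
  }
  f / 2^length(ranks)  # probabilities of W2 = 0..M (in 2*rank units)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of zero are dropped (Wilcoxon's original treatment). For 25
#' or fewer non-zero pairs the two-sided p-value is exact, computed from the
#' full enumeration of sign assignments (via the convolution of the
#' signed-rank generating function, which also accommodates average ranks
#' for tied magnitudes); for larger samples the normal approximation with
#' tie correction is used. The study-scale sample of 27 participants
#' therefore uses the approximation; the exact/asymptotic switch is
#' reported in the result.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List: `statistic` (V, sum of positive ranks), `n` (non-zero
#'   pairs), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate input: all paired differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  M <- n * (n + 1) / 2
  if (n <= exact_max) {
    probs <- signed_rank_null(r)
    v2 <- round(2 * V)
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[(v2 + 1):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - M / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    method <- "normal_approximation"
  }
  list(statistic = V, n = n, p = p, method = method)
}

#' The sixteen planned pairwise comparisons
#'
#' Enumerates the fixed comparison list: pairs 1-8 contrast virtual against
#' physical environments for each posture-by-direction combination; pairs
#' 9-16 contrast upward against downward and rightward against leftward
#' movements within each posture-by-environment combination. Vertical
#' versus lateral contrasts are never produced.
#'
#' @return data.frame with 16 rows: `comparison`, `family`, `posture`,
#'   `cell_a`/`cell_b` descriptors.
#' @export
planned_pairs <- function() {
  env_rows <- expand.grid(direction = c("up", "down", "right", "left"),
                          posture = POSTURE_LEVELS, stringsAsFactors = FALSE)
  a <- data.frame(comparison = 1:8, family = "environment",
                  posture_a = env_rows$posture, environment_a = "virtual",
                  direction_a = env_rows$direction,
                  posture_b = env_rows$posture, environment_b = "physical",
                  direction_b = env_rows$direction,
                  stringsAsFactors = FALSE)
  dir_rows <- expand.grid(pair = c("vertical", "lateral"),
                          environment = ENVIRONMENT_LEVELS,
                          posture = POSTURE_LEVELS, stringsAsFactors = FALSE)
  b <- data.frame(comparison = 9:16, family = "direction",
                  posture_a = dir_rows$posture,
                  environment_a = dir_rows$environment,
                  direction_a = ifelse(dir_rows$pair == "vertical", "up",
                                       "right"),
                  posture_b = dir_rows$posture,
                  environment_b = dir_rows$environment,
                  direction_b = ifelse(dir_rows$pair == "vertical", "down",
                                       "left"),
                  stringsAsFactors = FALSE)
  rbind(a, b)
}

#' Run the sixteen planned comparisons with Bonferroni correction
#'
#' On the non-parametric branch each pair is tested with the Wilcoxon
#' signed-rank test; on the parametric branch with a paired t contrast on
#' the cell means. The per-test significance threshold is `alpha / 16`
#' (0.003125 at the default family-wise alpha of 0.05).
#'
#' @param cells Cell-mean table from [aggregate_cells()].
#' @param parameter Parameter to test.
#' @param branch `"parametric"` or `"nonparametric"`; decided by
#'   [normality_gate()] when `NULL`.
#' @param alpha Family-wise significance level.
#' @return data.frame with 16 rows: comparison id, family, pair label, test
#'   used, statistic, p, `p_threshold`, `significant`.
#' @export
planned_comparisons <- function(cells, parameter, branch = NULL,
                                alpha = 0.05) {
  if (is.null(branch)) branch <- normality_gate(cells, parameter)$branch
  branch <- match.arg(branch, c("parametric", "nonparametric"))
  m <- cell_matrix(cells, parameter)
  pairs <- planned_pairs()
  thr <- alpha / nrow(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    a <- m[, cell_key(pr$posture_a, pr$environment_a, pr$direction_a)]
    b <- m[, cell_key(pr$posture_b, pr$environment_b, pr$direction_b)]
    if (branch == "nonparametric") {
      w <- wilcoxon_signed_rank(a, b)
      stat <- w$statistic; p <- w$p; test <- paste0("wilcoxon_", w$method)
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      stat <- unname(ht$statistic); p <- ht$p.value; test <- "paired_t"
    }
    data.frame(comparison = pr$comparison, family = pr$family,
               label = paste0(pr$posture_a, "-", pr$environment_a, "-",
                              pr$direction_a, " vs ", pr$posture_b, "-",
                              pr$environment_b, "-", pr$direction_b),
               test = test, statistic = stat, p = p, p_threshold = thr,
               significant = p < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simple main effects of direction within each posture
#'
#' Follow-up contrasts for a posture-by-direction interaction: within each
#' posture level (collapsing environments), the vertical and lateral
#' direction pairs are tested with paired contrasts, Bonferroni-corrected
#' within the family of four tests.
#'
#' @param cells Cell-mean table from [aggregate_cells()].
#' @param parameter Parameter to test.
#' @param branch `"parametric"` (paired t) or `"nonparametric"` (Wilcoxon).
#' @param alpha Family-wise level for the family of four.
#' @return data.frame with four rows.
#' @export
simple_main_effects <- function(cells, parameter, branch = "parametric",
                                alpha = 0.05) {
  branch <- match.arg(branch, c("parametric", "nonparametric"))
  m <- cell_matrix(cells, parameter)
  combos <- expand.grid(posture = POSTURE_LEVELS,
                        pair = c("vertical", "lateral"),
                        stringsAsFactors = FALSE)
  thr <- alpha / nrow(combos)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    po <- combos$posture[i]
    dirs <- if (combos$pair[i] == "vertical") c("up", "down") else
      c("right", "left")
    a <- rowMeans(m[, cell_key(po, ENVIRONMENT_LEVELS, dirs[1]), drop = FALSE])
    b <- rowMeans(m[, cell_key(po, ENVIRONMENT_LEVELS, dirs[2]), drop = FALSE])
    if (branch == "nonparametric") {
      w <- wilcoxon_signed_rank(a, b)
      stat <- w$statistic; p <- w$p
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(posture = po, contrast = paste(dirs, collapse = " vs "),
               statistic = stat, p = p, p_threshold = thr,
               significant = p < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
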