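# One-dimensional statistical parametric mapping for time-normalized
# kinematic profiles: node-wise paired t statistics, random-field-theory
# smoothness estimation and critical thresholds, suprathreshold clusters.

#' Time-normalize a movement segment
#'
#' Linearly interpolates a series onto `n_nodes` equally spaced time points
#' spanning the onset-offset window, so profiles of different durations can
#' be compared node by node (node 0 = movement onset, node
#' `n_nodes - 1` = offset). Only time is normalized; amplitudes are left
#' untouched.
#'
#' @param series Numeric series sampled at the trial's native rate.
#' @param onset,offset Sample indices bounding the movement.
#' @param n_nodes Number of nodes of the normalized grid (default 101,
#'   i.e. 0-100% in 1% steps).
#' @return Numeric vector of length `n_nodes`.
#' @export
time_normalize <- function(series, onset, offset, n_nodes = 101) {
  stopifnot(onset >= 1, offset <= length(series))
  if (offset - onset < 2)
    stop("degenerate segment: need at least 2 samples between onset and offset")
  stats::approx(x = onset:offset, y = series[onset:offset],
                xout = seq(onset, offset, length.out = n_nodes))$y
}

#' Node-wise paired t statistics
#'
#' Computes the paired t statistic `mean(d) / (sd(d)/sqrt(n))` at every
#' node of the difference curves `A - B`, where rows are participants
#' matched across the two matrices. Residuals (differences minus the
#' node-wise mean) are returned for smoothness estimation.
#'
#' @param a,b n x Q matrices of per-participant profiles, rows matched by
#'   participant.
#' @return List: `t` (length-Q t curve), `df` (n - 1), `residuals`
#'   (n x Q matrix).
#' @export
paired_spm_t <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  n <- nrow(a)
  if (n < 3) stop("paired SPM{t} needs at least 3 participants")
  d <- a - b
  mu <- colMeans(d)
  res <- sweep(d, 2, mu)
  sdv <- sqrt(colSums(res^2) / (n - 1))
  if (any(sdv == 0))
    stop("zero variance at node(s) ",
         paste(which(sdv == 0), collapse = ", "),
         ": t statistic undefined")
  list(t = mu / (sdv / sqrt(n)), df = n - 1, residuals = res)
}

#' Estimate field smoothness (FWHM) from residuals
#'
#' Normalized residual-gradient estimator: the residual curves are scaled
#' to unit variance node by node, the mean squared inter-node gradient is
#' pooled over curves and nodes, and `fwhm = sqrt(4 log 2) / RMS gradient`,
#' in node units. The estimate is clamped to `[1, Q]`.
#'
#' @param residuals n x Q residual matrix (see [paired_spm_t()]).
#' @return FWHM in node units.
#' @export
estimate_fwhm <- function(residuals) {
  stopifnot(is.matrix(residuals), nrow(residuals) >= 2,
            ncol(residuals) >= 3)
  q <- ncol(residuals)
  ssq <- colSums(residuals^2)
  if (any(ssq == 0)) stop("constant residuals: smoothness undefined")
  g <- residuals[, -1, drop = FALSE] - residuals[, -q, drop = FALSE]
  v <- colSums(g^2) / ((ssq[-1] + ssq[-q]) / 2)
  rms <- sqrt(mean(v))
  if (rms == 0) stop("constant residuals: smoothness undefined")
  min(max(sqrt(4 * log(2)) / rms, 1), q)
}

# 1D Euler-characteristic density of a t field at height t.
ec_density_t <- function(t, df) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + t^2 / df)^(-(df - 1) / 2)
}

#' Random-field-theory critical threshold for a 1D t field
#'
#' The smallest `t` at which the expected-Euler-characteristic bound for a
#' smooth 1D t field reaches the family-wise level:
#' `alpha_tail = P(T > t) + resels * EC1(t)` with
#' `resels = (n_nodes - 1)/fwhm`, solved per tail (`alpha/2` each side when
#' two-tailed) by monotone root finding to 1e-6. As `resels -> 0` the
#' threshold reduces to the pointwise t quantile.
#'
#' @param df Degrees of freedom.
#' @param fwhm Field smoothness in node units.
#' @param n_nodes Number of field nodes.
#' @param alpha Family-wise significance level.
#' @param two_tailed Split `alpha` over both tails (default `TRUE`).
#' @return Critical threshold `t_star`.
#' @export
rft_threshold <- function(df, fwhm, n_nodes, alpha = 0.05,
                          two_tailed = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(df >= 2, fwhm > 0, n_nodes >= 2)
  resels <- (n_nodes - 1) / fwhm
  target <- if (two_tailed) alpha / 2 else alpha
  f <- function(t)
    stats::pt(t, df, lower.tail = FALSE) + resels * ec_density_t(t, df) -
    target
  upper <- 10
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-6)$root
}

#' Suprathreshold clusters of a t curve
#'
#' Maximal runs of consecutive nodes with `|t| > t_star`. Cluster bounds are
#' reported in percent of normalized time (node index on a 0-100 scale for
#' the default 101-node grid).
#'
#' @param t_curve Numeric t curve.
#' @param t_star Critical threshold.
#' @return data.frame with columns `start_pct`, `end_pct`, `sign`
#'   (sign of t at the cluster's extreme node); zero rows when nothing
#'   exceeds the threshold.
#' @export
find_clusters <- function(t_curve, t_star) {
  stopifnot(all(is.finite(t_curve)), t_star > 0)
  q <- length(t_curve)
  above <- abs(t_curve) > t_star
  pct <- (seq_len(q) - 1) / (q - 1) * 100
  if (!any(above))
    return(data.frame(start_pct = numeric(), end_pct = numeric(),
                      sign = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    peak <- idx[which.max(abs(t_curve[idx]))]
    data.frame(start_pct = pct[starts[k]], end_pct = pct[ends[k]],
               sign = as.integer(sign(t_curve[peak])))
  })
  do.call(rbind, out)
}

# Assemble one SPM{t} result from matched profile matrices.
spm_t_test <- function(a, b, alpha = 0.05, two_tailed = TRUE) {
  tt <- paired_spm_t(a, b)
  fwhm <- estimate_fwhm(tt$residuals)
  q <- length(tt$t)
  t_star <- rft_threshold(tt$df, fwhm, q, alpha = alpha,
                          two_tailed = two_tailed)
  structure(list(t_curve = tt$t, df = tt$df, fwhm = fwhm,
                 resels = (q - 1) / fwhm, t_star = t_star, alpha = alpha,
                 two_tailed = two_tailed,
                 clusters = find_clusters(tt$t, t_star)),
            class = "spm_t")
}

#' @export
print.spm_t <- function(x, ...) {
  cat(sprintf("<spm_t> df=%d fwhm=%.2f resels=%.2f t*=%.3f (alpha=%g, %s)\n",
              x$df, x$fwhm, x$resels, x$t_star, x$alpha,
              if (x$two_tailed) "two-tailed" else "one-tailed"))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %.0f%%-%.0f%% (sign %+d)\n", i,
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$sign[i]))
  }
  invisible(x)
}

#' Participant-level time-normalized profile matrices
#'
#' For every retained trial, runs the preprocessing pipeline, time-normalizes
#' the speed and scalar-acceleration series over the onset-offset window,
#' and averages the normalized trials within each participant and condition
#' cell. These per-participant cell-mean profiles are the pairing unit of
#' the SPM comparisons.
#'
#' @param trials List of [trial_trajectory()] objects.
#' @param retained Retained landmark table (see [exclude_trials()]); used to
#'   select trials.
#' @param config An [analysis_config()].
#' @return List with elements `speed` and `acceleration`; each is a named
#'   list mapping a cell key (`posture.environment.direction`) to an
#'   n_participants x n_nodes matrix with participant rownames.
#' @export
participant_profiles <- function(trials, retained,
                                 config = analysis_config()) {
  keep <- with(retained, paste(participant, posture, environment, direction,
                               block, trial, sep = "."))
  trials <- trials[vapply(trials, trial_uid, character(1)) %in% keep]
  if (length(trials) == 0) stop("no retained trials to normalize")
  q <- config$spm_nodes
  n <- length(trials)
  sp <- matrix(NA_real_, n, q)
  ac <- matrix(NA_real_, n, q)
  part <- character(n)
  cell <- character(n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    kin <- trial_kinematics(tr, config)
    lm <- kin$landmarks
    sp[i, ] <- time_normalize(kin$speed, lm$onset, lm$offset, q)
    ac[i, ] <- time_normalize(kin$acceleration, lm$onset, lm$offset, q)
    part[i] <- tr$participant
    cell[i] <- cell_key(tr$posture, tr$environment, tr$direction)
  }
  build <- function(mat) {
    out <- list()
    for (ck in unique(cell)) {
      sub <- mat[cell == ck, , drop = FALSE]
      p <- part[cell == ck]
      means <- rowsum(sub, p) / as.vector(table(p)[sort(unique(p))])
      out[[ck]] <- means[order(rownames(means)), , drop = FALSE]
    }
    out
  }
  list(speed = build(sp), acceleration = build(ac))
}

#' Run the sixteen planned SPM comparisons on both profiles
#'
#' One paired SPM{t} per planned comparison and per quantity (speed and
#' acceleration): 32 results. Participants are paired across the two cells
#' of each comparison; all participants must be present in both cells.
#'
#' @param profiles Output of [participant_profiles()].
#' @param alpha Family-wise level per comparison.
#' @param two_tailed Tail convention (default two-tailed).
#' @return Named list of `spm_t` objects, keyed
#'   `"<comparison>.<quantity>"`; also see [spm_summary()].
#' @export
run_spm_comparisons <- function(profiles, alpha = 0.05, two_tailed = TRUE) {
  pairs <- planned_pairs()
  out <- list()
  for (qty in c("speed", "acceleration")) {
    prof <- profiles[[qty]]
    for (i in seq_len(nrow(pairs))) {
      pr <- pairs[i, ]
      ka <- cell_key(pr$posture_a, pr$environment_a, pr$direction_a)
      kb <- cell_key(pr$posture_b, pr$environment_b, pr$direction_b)
      if (is.null(prof[[ka]]) || is.null(prof[[kb]]))
        stop("missing profile cell: ", ka, " or ", kb)
      a <- prof[[ka]]
      b <- prof[[kb]]
      if (!identical(rownames(a), rownames(b)))
        stop("participants differ between cells ", ka, " and ", kb)
      res <- spm_t_test(a, b, alpha = alpha, two_tailed = two_tailed)
      res$comparison <- pr$comparison
      res$quantity <- qty
      res$label <- paste0(ka, " vs ", kb)
      out[[paste0(pr$comparison, ".", qty)]] <- res
    }
  }
  out
}

#' Tabular summary of SPM comparison results
#'
#' @param results List from [run_spm_comparisons()].
#' @return data.frame: comparison id, quantity, df, fwhm, t_star, number of
#'   clusters, and a compact cluster description.
#' @export
spm_summary <- function(results) {
  rows <- lapply(results, function(r) {
    cl <- r$clusters
    data.frame(comparison = r$comparison, quantity = r$quantity,
               label = r$label, df = r$df, fwhm = r$fwhm,
               t_star = r$t_star, n_clusters = nrow(cl),
               clusters = if (nrow(cl)) paste(sprintf(
                 "%+d:%.1f-%.1f%%", cl$sign, cl$start_pct, cl$end_pct),
                 collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$quantity, out$comparison), ]
}

#' Smooth Gaussian random curves
#'
#' White Gaussian noise convolved with a Gaussian kernel of the requested
#' FWHM (node units), generated on an extended grid and cropped so the
#' variance is stationary across nodes, then scaled to unit variance.
#' Used for null-calibration simulations of the SPM machinery.
#'
#' @param n_curves Number of curves (rows).
#' @param n_nodes Nodes per curve.
#' @param kernel_fwhm Smoothing-kernel FWHM in node units.
#' @return n_curves x n_nodes matrix.
#' @export
smooth_gaussian_curves <- function(n_curves, n_nodes, kernel_fwhm) {
  sigma <- kernel_fwhm / sqrt(8 * log(2))
  pad <- ceiling(4 * sigma)
  L <- n_nodes + 2 * pad
  k <- outer(seq_len(L), seq_len(n_nodes) + pad,
             function(i, j) stats::dnorm(i - j, sd = sigma))
  k <- sweep(k, 2, sqrt(colSums(k^2)), "/")  # unit marginal variance
  matrix(stats::rnorm(n_curves * L), n_curves, L) %*% k
}

#' Family-wise false-positive rate of the SPM procedure under a smooth null
#'
#' Monte-Carlo calibration: in each replicate, two independent sets of
#' smooth Gaussian curves (no true effect) are compared with the full
#' paired SPM{t} pipeline — node-wise t, residual-based FWHM estimate, RFT
#' threshold — and a false positive is recorded when any suprathreshold
#' cluster appears. The returned rate estimates the family-wise error of
#' the procedure and should not exceed `alpha` by more than Monte-Carlo
#' noise.
#'
#' @param n_participants Paired sample size per replicate.
#' @param n_nodes Nodes per curve.
#' @param kernel_fwhm Smoothing-kernel FWHM of the simulated curves.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param alpha Family-wise level of the tested procedure.
#' @param seed Integer seed.
#' @return List: `fwer`, `n_replicates`, `mc_se` (binomial Monte-Carlo
#'   standard error at the nominal level).
#' @export
spm_fwer_simulation <- function(n_participants = 27, n_nodes = 101,
                                kernel_fwhm = 20, n_replicates = 2000,
                                alpha = 0.05, seed = 1L) {
  set.seed(seed)
  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    a <- smooth_gaussian_curves(n_participants, n_nodes, kernel_fwhm)
    b <- smooth_gaussian_curves(n_participants, n_nodes, kernel_fwhm)
    res <- spm_t_test(a, b, alpha = alpha, two_tailed = TRUE)
    hits[r] <- nrow(res$clusters) > 0
  }
  list(fwer = mean(hits), n_replicates = n_replicates,
       mc_se = sqrt(alpha * (1 - alpha) / n_replicates))
}
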