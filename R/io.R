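TRAJ_COLUMNS <- c("participant", "posture", "environment", "direction",
                  "block", "trial", "t", "x", "y", "z")

#' Read a long-format trajectory table
#'
#' The file dialect is a long CSV with one row per motion-capture sample and
#' columns `participant, posture, environment, direction, block, trial, t,
#' x, y, z` (time in seconds, coordinates in metres). Missing samples are
#' encoded as empty coordinate cells (not omitted rows) so gaps stay
#' detectable. Grouping is label-driven: row order within the file is
#' irrelevant.
#'
#' @param path CSV file path.
#' @return A list of [trial_trajectory()] objects in canonical order.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), TRAJ_COLUMNS))
    stop("malformed header: expected columns ",
         paste(TRAJ_COLUMNS, collapse = ","))
  raw <- utils::read.csv(path, colClasses = c(
    participant = "character", posture = "character",
    environment = "character", direction = "character",
    block = "integer", trial = "integer",
    t = "numeric", x = "numeric", y = "numeric", z = "numeric"))
  if (nrow(raw) == 0L) return(list())
  key <- paste(raw$participant, raw$posture, raw$environment, raw$direction,
               raw$block, raw$trial, sep = ".")
  trials <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    g <- raw[idx, , drop = FALSE]
    g <- g[order(g$t), , drop = FALSE]
    if (any(diff(g$t) <= 0))
      stop("non-monotonic timestamps in trial ",
           paste(g$participant[1], g$posture[1], g$environment[1],
                 g$direction[1], g$block[1], g$trial[1], sep = "/"))
    trial_trajectory(g$participant[1], g$posture[1], g$environment[1],
                     g$direction[1], g$block[1], g$trial[1],
                     samples = data.frame(t = g$t, x = g$x, y = g$y, z = g$z))
  })
  order_trials(unname(trials))
}

#' Write trajectories as a canonical long-format CSV
#'
#' Output is canonically formatted (fixed column order, trials in canonical
#' order, `t` printed with 9 decimals and coordinates with 6, `NA`
#' coordinates as empty cells) so that read/write round-trips are
#' byte-identical.
#'
#' @param trials List of [trial_trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- order_trials(trials)
  fmt_num <- function(v, fmt) ifelse(is.na(v), "", sprintf(fmt, v))
  blocks <- vapply(trials, function(tr) {
    s <- tr$samples
    paste0(tr$participant, ",", tr$posture, ",", tr$environment, ",",
           tr$direction, ",", tr$block, ",", tr$trial, ",",
           sprintf("%.9f", s$t), ",",
           fmt_num(s$x, "%.6f"), ",", fmt_num(s$y, "%.6f"), ",",
           fmt_num(s$z, "%.6f"), collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(TRAJ_COLUMNS, collapse = ","), blocks), con, sep = "\n")
  invisible(path)
}

# Deterministic CSV serialization of a result table: fixed column order,
# numeric columns at 10 significant digits.
format_result_table <- function(df) {
  stopifnot(is.data.frame(df))
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "", sprintf("%.10g", out[[j]]))
  }
  out
}

write_result_csv <- function(df, path) {
  utils::write.csv(format_result_table(df), path, row.names = FALSE,
                   quote = FALSE)
  path
}

#' Write analysis result artifacts
#'
#' Serializes the landmark table, the planned-comparison table and optional
#' ANOVA/SPM tables as deterministic CSVs, together with a plain-text
#' analysis log (exclusions, branch decisions). Identical inputs yield
#' byte-identical outputs.
#'
#' @param landmarks Per-trial landmark table (see [landmark_table()]).
#' @param comparisons Planned-comparison table (see
#'   [planned_comparisons()]); must be non-empty.
#' @param out_dir Output directory, created if needed.
#' @param anova Optional ANOVA effect table.
#' @param spm Optional SPM summary table (see [spm_summary()]).
#' @param log Character vector of log lines.
#' @return Named character vector of the files written.
#' @export
write_results <- function(landmarks, comparisons, out_dir, anova = NULL,
                          spm = NULL, log = character()) {
  if (!is.data.frame(landmarks) || nrow(landmarks) == 0L)
    stop("landmark table is empty")
  if (!is.data.frame(comparisons) || nrow(comparisons) == 0L)
    stop("comparison table is empty")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(
    landmarks = write_result_csv(landmarks, file.path(out_dir, "landmarks.csv")),
    comparisons = write_result_csv(comparisons,
                                   file.path(out_dir, "comparisons.csv")))
  if (!is.null(anova))
    paths["anova"] <- write_result_csv(anova, file.path(out_dir, "anova.csv"))
  if (!is.null(spm))
    paths["spm"] <- write_result_csv(spm, file.path(out_dir, "spm.csv"))
  log_path <- file.path(out_dir, "analysis_log.txt")
  con <- file(log_path, open = "wb")
  writeLines(as.character(log), con, sep = "\n")
  close(con)
  paths["log"] <- log_path
  paths
}

#' Default analysis constants
#'
#' All constants default to the reference protocol: 5 Hz third-order
#' zero-phase Butterworth low-pass on positions, movement segmented at 10%
#' of peak tangential speed, alpha 0.05 with Bonferroni correction over the
#' 16 planned comparisons, and 101-node time normalization for SPM.
#'
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @param filter_order Butterworth order.
#' @param onset_threshold Fraction of peak speed defining onset/offset.
#' @param alpha Family-wise significance level.
#' @param spm_nodes Nodes of the time-normalized grid.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(cutoff_hz = 5, filter_order = 3,
                            onset_threshold = 0.10, alpha = 0.05,
                            spm_nodes = 101) {
  stopifnot(cutoff_hz > 0, filter_order >= 1,
            onset_threshold > 0, onset_threshold < 1,
            alpha > 0, alpha < 1, spm_nodes >= 3)
  structure(list(cutoff_hz = cutoff_hz, filter_order = filter_order,
                 onset_threshold = onset_threshold, alpha = alpha,
                 spm_nodes = as.integer(spm_nodes)),
            class = "analysis_config")
}

#' Read a YAML configuration file
#'
#' Recognised keys mirror [study_design()], [sim_config()] and
#' [analysis_config()] arguments; unknown keys raise an error, absent keys
#' fall back to the defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with elements `design`, `sim` and `analysis`.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c(names(formals(study_design)), names(formals(sim_config)),
             names(formals(analysis_config)))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  pick <- function(f) cfg[intersect(names(cfg), names(formals(f)))]
  design <- do.call(study_design, pick(study_design))
  sim_args <- pick(sim_config)
  sim_args$design <- design
  list(design = design,
       sim = do.call(sim_config, sim_args),
       analysis = do.call(analysis_config, pick(analysis_config)))
}
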