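#' Run the full condition-level analysis
#'
#' Orchestrates the inferential branch for every kinematic parameter:
#' landmark extraction, trial exclusion, aggregation to participant-by-cell
#' means, the Shapiro-Wilk normality gate, the omnibus test of the branch
#' taken (three-way repeated-measures ANOVA or Friedman), and the sixteen
#' Bonferroni-corrected planned comparisons. Every branch decision and
#' exclusion is recorded in the returned log.
#'
#' @param trials List of [trial_trajectory()] objects.
#' @param config An [analysis_config()].
#' @return List: `landmarks`, `exclusions`, `retained`, `cells`,
#'   `parameters` (per-parameter list with `branch`, `normality`, `omnibus`,
#'   `comparisons`), `comparisons` (all parameters combined), `log`.
#' @export
analyze_study <- function(trials, config = analysis_config()) {
  log <- character()
  landmarks <- landmark_table(trials, config)
  excl <- exclude_trials(landmarks)
  log <- c(log, sprintf("trials analysed: %d", nrow(landmarks)),
           sprintf("trials excluded: %d (%s)", nrow(excl$log),
                   if (nrow(excl$log)) paste(excl$log$rule, collapse = ", ")
                   else "none"),
           sprintf("trials retained: %d", nrow(excl$retained)))
  cells <- aggregate_cells(excl$retained)
  params <- list()
  comp_all <- list()
  for (p in KINEMATIC_PARAMETERS) {
    gate <- normality_gate(cells, p, alpha = config$alpha)
    omnibus <- if (gate$branch == "parametric") {
      rm_anova_3way(cells, p, alpha_sphericity = config$alpha)
    } else {
      friedman_cells(cells, p)
    }
    comp <- planned_comparisons(cells, p, branch = gate$branch,
                                alpha = config$alpha)
    log <- c(log, sprintf(
      "%s: branch=%s (min cell Shapiro-Wilk p=%.4g); %d/%d planned comparisons significant at %.6g",
      p, gate$branch, min(gate$tests$p), sum(comp$significant), nrow(comp),
      comp$p_threshold[1]))
    comp_all[[p]] <- cbind(parameter = p, comp)
    params[[p]] <- list(branch = gate$branch, normality = gate$tests,
                        omnibus = omnibus, comparisons = comp)
  }
  comparisons <- do.call(rbind, comp_all)
  rownames(comparisons) <- NULL
  list(landmarks = landmarks, exclusions = excl$log,
       retained = excl$retained, cells = cells, parameters = params,
       comparisons = comparisons, log = log)
}

#' Run the SPM stage on a trial set
#'
#' Builds participant cell-mean normalized profiles from the retained
#' trials and runs the sixteen planned SPM{t} comparisons on the requested
#' quantities.
#'
#' @param trials List of [trial_trajectory()] objects.
#' @param retained Retained landmark table; computed from `trials` when
#'   `NULL`.
#' @param config An [analysis_config()].
#' @return List: `results` (list of `spm_t`), `summary` (data.frame).
#' @export
spm_study <- function(trials, retained = NULL,
                      config = analysis_config()) {
  if (is.null(retained))
    retained <- exclude_trials(landmark_table(trials, config))$retained
  profiles <- participant_profiles(trials, retained, config)
  results <- run_spm_comparisons(profiles, alpha = config$alpha)
  list(results = results, summary = spm_summary(results))
}
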