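#' Score every session of a cohort
#'
#' Materializes each participant's gaze streams, segments them into trials,
#' and applies the age-appropriate scoring pipeline (40-ms frame
#' quantization and the 8-month validity rules at age 8; gap interpolation
#' and the automated-coding rules at age 24). Memory stays flat: streams
#' are generated and discarded one session at a time.
#'
#' @param cohort An [simulate_cohort()] object.
#' @param keep_trials Keep the per-trial score table (default TRUE).
#' @return List: `dwell` (long tibble: participant, group, age, condition,
#'   `n_scorable`, `dwell_index`, `included`), `trial_scores` (per-trial
#'   tibble or NULL), `status_counts` (tibble of trial statuses per age —
#'   the pipeline's quality dashboard).
#' @export
score_cohort <- function(cohort, keep_trials = TRUE) {
  stopifnot(inherits(cohort, "overlap_cohort"))
  spec <- cohort$protocol
  aois <- build_aois(spec)
  sess <- unique(cohort$trial_truth[, c("participant_id", "age")])
  grp <- stats::setNames(cohort$demographics$group,
                         cohort$demographics$participant_id)
  dwell <- vector("list", nrow(sess))
  trials <- if (keep_trials) vector("list", nrow(sess)) else NULL
  for (r in seq_len(nrow(sess))) {
    pid <- sess$participant_id[r]
    age <- sess$age[r]
    params <- scoring_params(if (age == 8) "infant8" else "toddler24")
    gz <- cohort_gaze(cohort, pid, age)
    recs <- segment_trials(gz$samples, gz$events, spec,
                           sampling_rate_hz = cohort$params$sampling_rate_hz)
    ps <- score_participant(recs, aois, params, participant_id = pid,
                            conditions = spec$conditions)
    dwell[[r]] <- dplyr::bind_cols(
      tibble::tibble(participant_id = pid, group = unname(grp[pid]), age = age),
      ps$condition_scores,
      tibble::tibble(included = ps$included))
    if (keep_trials) {
      trials[[r]] <- dplyr::bind_cols(
        tibble::tibble(participant_id = pid, age = age), ps$trial_scores)
    }
  }
  dwell <- dplyr::bind_rows(dwell)
  trial_scores <- if (keep_trials) dplyr::bind_rows(trials) else NULL
  status_counts <- if (keep_trials) {
    dplyr::count(trial_scores, .data$age, .data$status, name = "n_trials")
  } else NULL
  list(dwell = dwell, trial_scores = trial_scores,
       status_counts = status_counts)
}

#' Group-level analysis of a scored cohort
#'
#' Runs the full statistical layer: the linear mixed model of the
#' longitudinal dwell indices with Bonferroni post hocs, independent-samples
#' t-tests of the BITSEA domains (including the sleep-items-removed
#' dysregulation variant, with the Welch variant auto-selected when the
#' variance-homogeneity pretest rejects), the dwell x domain Pearson
#' correlation table, and the demographic chi-square comparisons.
#'
#' @param dwell Long dwell tibble from [score_cohort()].
#' @param domain_scores BITSEA domain scores from [score_domains()].
#' @param demographics Demographics tibble with `participant_id`, `group`
#'   and the covariate columns.
#' @param covariates Optional covariate columns of `dwell` to screen in the
#'   mixed model.
#' @return List of class `overlap_analysis`: `lmm`, `bitsea_tests`,
#'   `correlations`, `demographics_chi2`.
#' @export
analyze_cohort <- function(dwell, domain_scores, demographics,
                           covariates = NULL) {
  inc <- dwell[dwell$included & !is.na(dwell$dwell_index), ]
  lmm <- fit_dwell_lmm(inc, covariates = covariates)

  grp <- demographics[, c("participant_id", "group")]
  ds <- merge(domain_scores, grp, by = "participant_id")
  test_domain <- function(col) {
    x <- ds[[col]][ds$group == "waking"]
    y <- ds[[col]][ds$group == "nonwaking"]
    out <- ttest_independent(x, y, variant = "auto")
    dplyr::bind_cols(tibble::tibble(domain = col), out)
  }
  bitsea_tests <- dplyr::bind_rows(lapply(
    c("dysregulation", "competence", "externalizing", "internalizing",
      "dysregulation_no_sleep"), test_domain))

  correlations <- pearson_correlations(inc, domain_scores)

  chi2 <- dplyr::bind_rows(lapply(
    c("co_sleeping", "falling_asleep_alone", "healthcare_center",
      "breastfeeding"),
    function(cv) {
      x <- demographics[[cv]]
      # breastfeeding has three categories; dichotomize exclusively
      # breastfed vs any formula
      if (cv == "breastfeeding") {
        x <- ifelse(x == "breastfed_only", "breastfed_only", "any_formula")
      }
      counts <- table(factor(demographics$group,
                             levels = c("waking", "nonwaking")), x)
      res <- chi_square_2x2(counts)
      dplyr::bind_cols(tibble::tibble(covariate = cv), res)
    }))

  structure(list(lmm = lmm, bitsea_tests = bitsea_tests,
                 correlations = correlations, demographics_chi2 = chi2),
            class = "overlap_analysis")
}

#' Write analysis tables and a plain-text report
#'
#' @param analysis An [analyze_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(analysis$lmm$fixed_effects, file.path(dir, "lmm_fixed_effects.tsv"))
  write_tsv_file(analysis$lmm$emm_group_condition,
                 file.path(dir, "lmm_marginal_means.tsv"))
  if (!is.null(analysis$lmm$pairwise)) {
    write_tsv_file(analysis$lmm$pairwise, file.path(dir, "lmm_pairwise.tsv"))
  }
  write_tsv_file(analysis$bitsea_tests, file.path(dir, "bitsea_tests.tsv"))
  write_tsv_file(analysis$correlations, file.path(dir, "correlations.tsv"))
  write_tsv_file(analysis$demographics_chi2,
                 file.path(dir, "demographics_chi2.tsv"))
  rep_path <- file.path(dir, "report.txt")
  con <- file(rep_path, open = "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("Overlap-task group analysis")
  wl("===========================")
  wl("")
  wl("Covariance structure selected by AIC: ", analysis$lmm$covariance$selected)
  wl("")
  wl("Fixed effects (Satterthwaite F tests):")
  utils::capture.output(print(as.data.frame(analysis$lmm$fixed_effects),
                              row.names = FALSE, digits = 4), file = con)
  wl("")
  wl("BITSEA domain comparisons (waking vs nonwaking):")
  utils::capture.output(print(as.data.frame(
    analysis$bitsea_tests[, c("domain", "t", "df", "p_value", "d", "variant")]),
    row.names = FALSE, digits = 4), file = con)
  invisible(dir)
}
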