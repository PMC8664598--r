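#' Pearson 2x2 chi-square test
#'
#' Plain Pearson statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1
#' degree of freedom and no continuity correction — the convention that
#' reproduces published group-comparison values exactly from the printed
#' contingency counts.
#'
#' @param counts 2x2 matrix (or object coercible to one) of nonnegative
#'   counts; rows = groups, columns = categories.
#' @return Tibble: `statistic`, `df`, `p_value`, `n`.
#' @examples
#' chi_square_2x2(matrix(c(29, 4, 36, 50), nrow = 2))
#' @export
chi_square_2x2 <- function(counts) {
  m <- as.matrix(counts)
  check_that(all(dim(m) == c(2, 2)), "`counts` must be 2x2")
  check_that(all(m >= 0), "counts must be nonnegative")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  margins <- c(a + b, c_ + d, a + c_, b + d)
  check_that(all(margins > 0), "all margins must be positive")
  n <- sum(m)
  x2 <- n * (a * d - b * c_)^2 / prod(margins)
  tibble::tibble(statistic = x2, df = 1L,
                 p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE),
                 n = n)
}

#' Demographic contingency counts for the night-awakening groups
#'
#' The published questionnaire counts (waking vs nonwaking group) for the
#' two sleep-related rearing covariates that the chi-square convention is
#' validated against: co-sleeping (more than once a week vs less than twice
#' a month) and falling asleep alone (once a week vs once a day). Rows are
#' groups (waking, nonwaking), columns the two categories.
#'
#' @return Named list of 2x2 matrices.
#' @export
demographic_counts <- function() {
  list(
    co_sleeping = matrix(c(29, 4, 36, 50), nrow = 2, byrow = FALSE,
                         dimnames = list(c("waking", "nonwaking"),
                                         c("gt_once_week", "lt_twice_month"))),
    falling_asleep_alone = matrix(c(49, 20, 23, 41), nrow = 2, byrow = FALSE,
                                  dimnames = list(c("waking", "nonwaking"),
                                                  c("once_week", "once_day")))
  )
}

#' Published BITSEA domain summaries for the two groups
#'
#' Means, SDs and group sizes of the four socio-emotional domains (plus the
#' sleep-items-removed dysregulation variant) for the waking and nonwaking
#' groups, as printed; usable as direct input to
#' [ttest_independent_summary()].
#'
#' @return Tibble with one row per domain.
#' @export
bitsea_domain_summaries <- function() {
  tibble::tribble(
    ~domain,                  ~m_waking, ~sd_waking, ~n_waking, ~m_nonwaking, ~sd_nonwaking, ~n_nonwaking,
    "dysregulation",          4.23,      2.74,       53,        2.47,         2.14,          47,
    "competence",             18.11,     2.42,       53,        19.13,        2.60,          47,
    "externalizing",          3.41,      2.27,       53,        3.00,         2.10,          47,
    "internalizing",          1.59,      1.75,       53,        1.05,         0.99,          47,
    "dysregulation_no_sleep", 2.42,      1.81,       53,        1.79,         1.53,          47
  )
}

#' Independent-samples t-test from group summaries
#'
#' Pooled-variance test (with `d = (M1 - M2)/s_p` sharing the pooled SD) or
#' Welch test with Satterthwaite degrees of freedom. Works from summary
#' statistics so published tables can be re-analyzed directly.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return Tibble: `t`, `df`, `p_value`, `d`, `variant`, plus the group
#'   summaries.
#' @examples
#' ttest_independent_summary(4.23, 2.74, 53, 2.47, 2.14, 47)
#' @export
ttest_independent_summary <- function(m1, s1, n1, m2, s2, n2,
                                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  check_that(n1 >= 2 && n2 >= 2, "each group needs n >= 2")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  check_that(sp2 > 0, "zero pooled variance")
  d <- (m1 - m2) / sqrt(sp2)
  if (variant == "pooled") {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  tibble::tibble(t = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 d = d, variant = variant,
                 m1 = m1, sd1 = s1, n1 = n1, m2 = m2, sd2 = s2, n2 = n2)
}

#' Independent-samples t-test from raw vectors
#'
#' By default the pooled test is used, switching to Welch when Levene's
#' variance-homogeneity pretest (Brown-Forsythe, median-centered) rejects
#' at .05.
#'
#' @param x,y Numeric vectors (NA dropped).
#' @param variant `"auto"`, `"pooled"` or `"welch"`.
#' @return As [ttest_independent_summary()].
#' @export
ttest_independent <- function(x, y, variant = c("auto", "pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (variant == "auto") {
    zx <- abs(x - stats::median(x))
    zy <- abs(y - stats::median(y))
    lev <- stats::anova(stats::lm(c(zx, zy) ~ factor(rep(1:2, c(length(zx), length(zy))))))
    variant <- if (lev$`Pr(>F)`[1] < 0.05) "welch" else "pooled"
  }
  ttest_independent_summary(mean(x), stats::sd(x), length(x),
                            mean(y), stats::sd(y), length(y),
                            variant = variant)
}

#' Bonferroni adjustment for a family of pairwise comparisons
#'
#' `p_adj = min(1, m * p)` with `m` the family size (all level pairs by
#' default, e.g. the 6 condition pairs within each group).
#'
#' @param comparisons Tibble with a `p_value` column (one row per pairwise
#'   comparison in the family).
#' @param m Family size; defaults to `nrow(comparisons)`.
#' @return The tibble with an added `p_adjusted` column.
#' @export
bonferroni_pairwise <- function(comparisons, m = nrow(comparisons)) {
  check_that(nrow(comparisons) > 0, "empty comparison family")
  check_that("p_value" %in% names(comparisons),
             "`comparisons` must have a p_value column")
  comparisons$p_adjusted <- pmin(1, m * comparisons$p_value)
  comparisons
}

#' Linear mixed model for the longitudinal dwell indices
#'
#' Fits the screening model `dwell_index ~ group * age * emotion` with a
#' child-level random intercept to the long participant x age x condition
#' table, using Satterthwaite F tests (which is why the denominator degrees
#' of freedom are fractional). Covariance structures for the repeated
#' measures are compared by AIC over a candidate set — compound symmetry
#' (the random intercept), an AR(1) over age within child x condition, and
#' heterogeneous residual variance by emotion — and the winner is reported;
#' the Satterthwaite fixed-effect tests are taken from the random-intercept
#' fit. Estimated marginal means, Bonferroni-corrected pairwise condition
#' contrasts within each group, and Cohen's d (contrast estimate over the
#' square root of the summed random-intercept and residual variances) are
#' emitted.
#'
#' Supplied covariates are screened by adding each to the fixed part and
#' reporting its Satterthwaite F test.
#'
#' @param table Long tibble with columns `participant_id`, `group`, `age`,
#'   `condition`, `dwell_index` (included participants only; incomplete
#'   longitudinal data are fine).
#' @param covariates Optional character vector of additional column names
#'   in `table` to screen.
#' @param posthoc Compute marginal means and Bonferroni pairwise contrasts
#'   (default TRUE; turn off in simulation loops that only need the F tests).
#' @param select_covariance Run the AIC covariance-structure comparison
#'   (default TRUE).
#' @return Object of class `dwell_lmm`: list with `fixed_effects`,
#'   `emm_condition`, `emm_group_condition`, `pairwise`, `covariance`
#'   (candidate AIC table + selected name), `covariate_screen`,
#'   `variance_components`, and the underlying `fit`.
#' @export
fit_dwell_lmm <- function(table, covariates = NULL, posthoc = TRUE,
                          select_covariance = TRUE) {
  needed <- c("participant_id", "group", "age", "condition", "dwell_index")
  check_that(all(needed %in% names(table)),
             paste("table must have columns:", paste(needed, collapse = ", ")))
  check_that(length(unique(table$group)) >= 2, "need at least two groups")
  if (stats::var(table$dwell_index) == 0) {
    stop("degenerate fit: all responses identical", call. = FALSE)
  }
  d <- data.frame(
    participant_id = factor(table$participant_id),
    group = factor(table$group),
    age = factor(table$age),
    condition = factor(table$condition),
    dwell_index = table$dwell_index
  )
  cells <- interaction(d$group, d$age, d$condition, drop = TRUE)
  cell_vars <- tapply(d$dwell_index, cells, stats::var)
  if (!all(is.na(cell_vars)) && max(cell_vars, na.rm = TRUE) < 1e-12) {
    return(fit_dwell_degenerate(d))
  }

  fit <- lmerTest::lmer(
    dwell_index ~ group * age * condition + (1 | participant_id),
    data = d, REML = TRUE)
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  fixed_effects <- tibble::tibble(
    effect = rownames(an),
    F = an$`F value`, df_num = an$NumDF, df_den = an$DenDF,
    p_value = an$`Pr(>F)`)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_id <- vc$vcov[vc$grp == "participant_id"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  d_denom <- sqrt(var_id + var_res)

  # covariance-structure comparison by AIC (REML, same fixed effects)
  aic_tab <- NULL
  sel <- "compound_symmetry (not compared)"
  if (select_covariance) {
  cand <- list()
  cand$compound_symmetry <- tryCatch(
    nlme::lme(dwell_index ~ group * age * condition,
              random = ~ 1 | participant_id, data = d, method = "REML"),
    error = function(e) NULL)
  cand$ar1_age <- tryCatch(
    nlme::lme(dwell_index ~ group * age * condition,
              random = ~ 1 | participant_id, data = d, method = "REML",
              correlation = nlme::corAR1(form = ~ as.numeric(age) |
                                           participant_id / condition)),
    error = function(e) NULL)
  cand$heterogeneous_emotion <- tryCatch(
    nlme::lme(dwell_index ~ group * age * condition,
              random = ~ 1 | participant_id, data = d, method = "REML",
              weights = nlme::varIdent(form = ~ 1 | condition)),
    error = function(e) NULL)
  aic_tab <- tibble::tibble(
    structure = names(cand),
    AIC = vapply(cand, function(f) if (is.null(f)) NA_real_ else stats::AIC(f),
                 numeric(1)))
  sel <- aic_tab$structure[which.min(aic_tab$AIC)]
  }

  emm_cond <- NULL; emm_gc <- NULL; pairwise <- NULL
  if (posthoc) {
    # emmeans warns that margins average over interaction cells: that
    # averaging is exactly the intended estimate here
    emm_cond <- suppressMessages(
      emmeans::emmeans(fit, ~ condition, lmer.df = "satterthwaite"))
    emm_gc <- suppressMessages(
      emmeans::emmeans(fit, ~ condition | group, lmer.df = "satterthwaite"))
    pw <- summary(emmeans::contrast(emm_gc, method = "pairwise",
                                    adjust = "bonferroni"))
    pairwise <- tibble::tibble(
      group = pw$group, contrast = as.character(pw$contrast),
      estimate = pw$estimate, se = pw$SE, df = pw$df,
      t = pw$t.ratio, p_adjusted = pw$p.value,
      cohens_d = pw$estimate / d_denom)
    emm_cond <- tibble::as_tibble(as.data.frame(emm_cond))
    emm_gc <- tibble::as_tibble(as.data.frame(emm_gc))
  }

  screen <- NULL
  if (!is.null(covariates)) {
    screen <- dplyr::bind_rows(lapply(covariates, function(cv) {
      d2 <- d
      d2[[cv]] <- table[[cv]]
      ok <- !is.na(d2[[cv]])
      f2 <- lmerTest::lmer(
        stats::as.formula(paste0(
          "dwell_index ~ group * age * condition + ", cv,
          " + (1 | participant_id)")),
        data = d2[ok, ], REML = TRUE)
      a2 <- stats::anova(f2, type = 3, ddf = "Satterthwaite")
      row <- a2[rownames(a2) == cv, , drop = FALSE]
      tibble::tibble(covariate = cv, F = row$`F value`,
                     df_num = row$NumDF, df_den = row$DenDF,
                     p_value = row$`Pr(>F)`)
    }))
  }

  structure(list(
    fixed_effects = fixed_effects,
    emm_condition = emm_cond,
    emm_group_condition = emm_gc,
    pairwise = pairwise,
    covariance = list(candidates = aic_tab, selected = sel),
    covariate_screen = screen,
    variance_components = c(participant = var_id, residual = var_res),
    degenerate = FALSE,
    fit = fit
  ), class = "dwell_lmm")
}

# Fixed-effects least-squares decomposition for noiseless cell-constant
# tables, where a mixed model cannot estimate its variance components.
# Effects with (numerically) zero sum of squares report F = 0.
fit_dwell_degenerate <- function(d) {
  fit <- stats::lm(dwell_index ~ group * age * condition, data = d)
  an <- suppressWarnings(stats::anova(fit))
  an <- an[rownames(an) != "Residuals", , drop = FALSE]
  ss <- an$`Sum Sq`
  fixed_effects <- tibble::tibble(
    effect = gsub(":", " x ", rownames(an)),
    F = ifelse(ss < 1e-10, 0, Inf),
    df_num = an$Df, df_den = NA_real_, p_value = NA_real_)
  fixed_effects$effect <- rownames(an)
  emm_cond <- suppressWarnings(suppressMessages(
    emmeans::emmeans(fit, ~ condition)))
  emm_gc <- suppressWarnings(suppressMessages(
    emmeans::emmeans(fit, ~ condition | group)))
  structure(list(
    fixed_effects = fixed_effects,
    emm_condition = tibble::as_tibble(as.data.frame(emm_cond)),
    emm_group_condition = tibble::as_tibble(as.data.frame(emm_gc)),
    pairwise = NULL,
    covariance = list(candidates = NULL, selected = "none (degenerate)"),
    covariate_screen = NULL,
    variance_components = c(participant = 0, residual = 0),
    degenerate = TRUE,
    fit = fit
  ), class = "dwell_lmm")
}

#' @export
print.dwell_lmm <- function(x, ...) {
  cat("Linear mixed model of dwell indices",
      if (x$degenerate) "(degenerate least-squares fallback)", "\n")
  cat("Covariance structure selected by AIC:", x$covariance$selected, "\n\n")
  print(as.data.frame(x$fixed_effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pearson correlations between dwell indices and BITSEA domains
#'
#' Pairwise-complete Pearson r with unadjusted two-sided p for every
#' (condition x age) dwell column against every BITSEA domain, mirroring
#' the exploratory correlation table layout.
#'
#' @param dwell_wide Tibble with columns `participant_id`, `age`,
#'   `condition`, `dwell_index` (included participants).
#' @param domain_scores Tibble from [score_domains()].
#' @param domains Domain columns to correlate.
#' @return Tibble: `age`, `condition`, `domain`, `r`, `n`, `p_value`.
#' @export
pearson_correlations <- function(dwell_wide, domain_scores,
                                 domains = c("internalizing", "externalizing",
                                             "dysregulation_no_sleep",
                                             "competence")) {
  combos <- expand.grid(age = unique(dwell_wide$age),
                        condition = unique(dwell_wide$condition),
                        domain = domains, stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    dw <- dwell_wide[dwell_wide$age == cm$age &
                       dwell_wide$condition == cm$condition,
                     c("participant_id", "dwell_index")]
    merged <- merge(dw, domain_scores[, c("participant_id", cm$domain)],
                    by = "participant_id")
    x <- merged$dwell_index
    y <- merged[[cm$domain]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3) {
      return(tibble::tibble(age = cm$age, condition = cm$condition,
                            domain = cm$domain, r = NA_real_, n = n,
                            p_value = NA_real_))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(age = cm$age, condition = cm$condition,
                            domain = cm$domain, r = NA_real_, n = n,
                            p_value = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(age = cm$age, condition = cm$condition, domain = cm$domain,
                   r = unname(ct$estimate), n = n, p_value = ct$p.value)
  }))
}
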