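test_that("the 2x2 chi-square reproduces the published demographic statistics", {
  counts <- demographic_counts()
  expect_equal(round(chi_square_2x2(counts$co_sleeping)$statistic, 3), 20.376)
  expect_equal(round(chi_square_2x2(counts$falling_asleep_alone)$statistic, 3),
               16.454)
  # equal proportions give exactly zero
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("the chi-square formula agrees with the uncorrected base-R test", {
  withr::with_seed(17, {
    for (i in 1:25) {
      m <- matrix(stats::rpois(4, 30) + 1, 2, 2)
      ours <- chi_square_2x2(m)
      ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("the pooled t-test reproduces the published dysregulation comparison", {
  s <- bitsea_domain_summaries()
  dys <- s[s$domain == "dysregulation", ]
  res <- ttest_independent_summary(dys$m_waking, dys$sd_waking, dys$n_waking,
                                   dys$m_nonwaking, dys$sd_nonwaking,
                                   dys$n_nonwaking)
  # tolerance implied by the 2-decimal rounding of the published summaries
  expect_lt(abs(res$t - 3.542), 0.03)
  expect_lt(abs(res$d - 0.72), 0.03)
  expect_equal(res$df, 98)
})

test_that("t-test degenerate and identity cases", {
  expect_equal(ttest_independent_summary(5, 2, 20, 5, 2, 20)$t, 0)
  expect_equal(ttest_independent_summary(5, 2, 20, 5, 2, 20)$d, 0)
  expect_error(ttest_independent_summary(5, 0, 20, 5, 0, 20), "pooled variance")
  # welch and pooled coincide when variances and sizes are equal
  w <- ttest_independent_summary(6, 1.5, 30, 5, 1.5, 30, variant = "welch")
  p <- ttest_independent_summary(6, 1.5, 30, 5, 1.5, 30, variant = "pooled")
  expect_equal(w$t, p$t)
  expect_equal(w$df, p$df)
})

test_that("raw-vector t-tests agree with base R", {
  withr::with_seed(23, {
    x <- stats::rnorm(40, 1, 1)
    y <- stats::rnorm(35, 0.2, 1.4)
    ours_p <- ttest_independent(x, y, variant = "pooled")
    ref_p <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours_p$t, unname(ref_p$statistic), tolerance = 1e-12)
    expect_equal(ours_p$p_value, ref_p$p.value, tolerance = 1e-12)
    ours_w <- ttest_independent(x, y, variant = "welch")
    ref_w <- stats::t.test(x, y)
    expect_equal(ours_w$t, unname(ref_w$statistic), tolerance = 1e-12)
    expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-9)
  })
})

test_that("Bonferroni adjustment caps at 1 and uses the pair-family size", {
  fam <- tibble::tibble(p_value = c(0.01, 0.5))
  adj <- bonferroni_pairwise(fam, m = 6)
  expect_equal(adj$p_adjusted, c(0.06, 1))
  # four conditions produce six pairs
  expect_equal(choose(4, 2), 6)
  expect_error(bonferroni_pairwise(fam[0, ]), "empty")
})

test_that("correlation table: exact linear pairs and constant columns", {
  dw <- tibble::tibble(participant_id = sprintf("P%02d", 1:10), age = 8,
                       condition = "happy", dwell_index = (1:10) / 10)
  ds <- tibble::tibble(participant_id = sprintf("P%02d", 1:10),
                       competence = 2 * (1:10), internalizing = 5,
                       externalizing = 10:1, dysregulation_no_sleep = 1:10)
  ct <- pearson_correlations(dw, ds)
  expect_equal(ct$r[ct$domain == "competence"], 1)
  expect_equal(ct$r[ct$domain == "externalizing"], -1)
  expect_true(is.na(ct$r[ct$domain == "internalizing"]))  # constant column
  expect_equal(ct$n, rep(10, 4))
})

test_that("correlation p-values are calibrated under independence", {
  withr::with_seed(29, {
    reps <- 1000
    hits <- 0
    for (i in 1:reps) {
      x <- stats::rnorm(50); y <- stats::rnorm(50)
      if (stats::cor.test(x, y)$p.value < 0.05) hits <- hits + 1
    }
    rate <- hits / reps
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  })
})

test_that("the generative happy-competence correlation is recovered at large n", {
  co <- simulate_cohort(sim_params(n_waking = 600, n_nonwaking = 0,
                                   retention_24m = 1), seed = 19)
  cl <- co$child_latents
  r <- stats::cor(cl$happy_latent_8m, cl$competence_latent)
  n <- nrow(cl)
  se <- (1 - 0.337^2) / sqrt(n - 3)
  expect_lt(abs(r - 0.337), 3 * se)
})

test_that("an all-identical response table is a degenerate-fit error", {
  tab <- expand.grid(participant_id = sprintf("P%02d", 1:8),
                     group = c("waking", "nonwaking"), age = c(8, 24),
                     condition = c("a", "b", "c", "d"))
  tab$dwell_index <- 0.5
  expect_error(fit_dwell_lmm(tibble::as_tibble(tab)), "degenerate")
})

test_that("noiseless cell constants give those constants as marginal means and F = 0 for absent effects", {
  tab <- expand.grid(participant_id = sprintf("P%02d", 1:10),
                     group = c("waking", "nonwaking"), age = c(8, 24),
                     condition = c("fearful", "happy", "neutral_open",
                                   "neutral_closed"),
                     stringsAsFactors = FALSE)
  cellmeans <- c(fearful = 0.6, happy = 0.55, neutral_open = 0.5,
                 neutral_closed = 0.5)
  tab$dwell_index <- cellmeans[tab$condition]
  res <- fit_dwell_lmm(tibble::as_tibble(tab))
  expect_true(res$degenerate)
  emm <- res$emm_condition
  expect_equal(emm$emmean[match(names(cellmeans), emm$condition)],
               unname(cellmeans), tolerance = 1e-12)
  fe <- res$fixed_effects
  absent <- fe$effect[!grepl("^condition$", fe$effect)]
  expect_true(all(fe$F[fe$effect %in% absent] == 0))
  expect_true(fe$F[fe$effect == "condition"] > 0)
})

test_that("with no between-child variance the fixed effects match an OLS oracle", {
  withr::with_seed(37, {
    tab <- expand.grid(participant_id = sprintf("P%02d", 1:30),
                       age = c(8, 24),
                       condition = c("fearful", "happy", "neutral_open",
                                     "neutral_closed"),
                       stringsAsFactors = FALSE)
    tab$group <- ifelse(as.integer(sub("P", "", tab$participant_id)) <= 15,
                        "waking", "nonwaking")
    tab$dwell_index <- 0.5 +
      0.05 * (tab$condition == "fearful") +
      0.02 * (tab$group == "waking") * (tab$condition == "happy") +
      stats::rnorm(nrow(tab), 0, 0.1)
    res <- fit_dwell_lmm(tibble::as_tibble(tab), posthoc = FALSE,
                         select_covariance = FALSE)
    ols <- stats::lm(dwell_index ~ group * age * condition,
                     data = transform(tab, group = factor(group),
                                      age = factor(age),
                                      condition = factor(condition)))
    expect_equal(unname(lme4::fixef(res$fit)), unname(stats::coef(ols)),
                 tolerance = 1e-6)
  })
})

test_that("the mixed model recovers the simulated group-by-emotion structure", {
  co <- simulate_cohort(sim_params(), seed = 55)
  sc <- score_cohort(co, keep_trials = FALSE)
  res <- fit_dwell_lmm(sc$dwell[sc$dwell$included, ])
  fe <- res$fixed_effects
  # the emotion effect built into the generator is large and detected
  expect_lt(fe$p_value[fe$effect == "condition"], 0.001)
  expect_true(all(fe$df_num[fe$effect == "condition"] == 3))
  # fractional Satterthwaite denominator df
  expect_false(all(fe$df_den == round(fe$df_den)))
  # model marginal means agree with the raw age-balanced cell means
  emm <- res$emm_group_condition
  inc <- sc$dwell[sc$dwell$included, ]
  raw_cells <- aggregate(dwell_index ~ group + condition + age, inc, mean)
  raw <- aggregate(dwell_index ~ group + condition, raw_cells, mean)
  m0 <- merge(as.data.frame(emm), raw, by = c("group", "condition"))
  expect_lt(max(abs(m0$emmean - m0$dwell_index)), 0.01)
  # and sit near the generator's targets, within the Monte-Carlo spread of
  # a single 146-child cohort (group intercept wobble ~0.012 SD per group,
  # max over 8 cells)
  mu <- dwell_mean_defaults()
  m <- merge(as.data.frame(emm), mu, by = c("group", "condition"))
  expect_lt(max(abs(m$emmean - m$mu)), 0.08)
  # Bonferroni adjustment never lowers a p-value below its raw value
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(res$fit, ~ condition | group), method = "pairwise",
    adjust = "none"))
  expect_true(all(res$pairwise$p_adjusted >= raw$p.value - 1e-12))
  expect_true(res$covariance$selected %in%
                c("compound_symmetry", "ar1_age", "heterogeneous_emotion"))
})

test_that("covariate screening reports one F test per supplied covariate", {
  co <- simulate_cohort(sim_params(n_waking = 30, n_nonwaking = 30), seed = 71)
  sc <- score_cohort(co, keep_trials = FALSE)
  dw <- sc$dwell[sc$dwell$included, ]
  dem <- co$demographics
  dw$ces_d <- dem$ces_d[match(dw$participant_id, dem$participant_id)]
  res <- fit_dwell_lmm(dw, covariates = "ces_d", posthoc = FALSE,
                       select_covariance = FALSE)
  expect_equal(nrow(res$covariate_screen), 1)
  expect_equal(res$covariate_screen$covariate, "ces_d")
  expect_true(is.finite(res$covariate_screen$p_value))
})
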