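#' Default condition-mean matrix for the dwell-index generator
#'
#' Post-censoring mean dwell indices per group x condition, constant over
#' age (the study design this generator emulates found no interactions
#' involving age). Waking = three or more signaled night awakenings,
#' nonwaking = at most one.
#'
#' @return Tibble with columns `group`, `condition`, `mu`.
#' @export
dwell_mean_defaults <- function() {
  tibble::tribble(
    ~group,      ~condition,       ~mu,
    "waking",    "fearful",        0.611,
    "waking",    "happy",          0.550,
    "waking",    "neutral_open",   0.541,
    "waking",    "neutral_closed", 0.505,
    "nonwaking", "fearful",        0.646,
    "nonwaking", "happy",          0.602,
    "nonwaking", "neutral_open",   0.510,
    "nonwaking", "neutral_closed", 0.551
  )
}

#' Default per-group covariate frequencies
#'
#' Category probabilities for the rearing covariates, taken from the
#' published group-wise questionnaire counts (proportions of non-missing).
#'
#' @return Nested list: `covariate_freq_defaults()$waking$co_sleeping` etc.
#' @export
covariate_freq_defaults <- function() {
  list(
    waking = list(
      breastfeeding = c(breastfed_only = 43, mixed = 16, formula_only = 14) / 73,
      co_sleeping = c(gt_once_week = 29, lt_twice_month = 36) / 65,
      falling_asleep_alone = c(once_week = 49, once_day = 23) / 72,
      healthcare_center = c(prevention = 43, control = 34) / 77
    ),
    nonwaking = list(
      breastfeeding = c(breastfed_only = 20, mixed = 11, formula_only = 29) / 60,
      co_sleeping = c(gt_once_week = 4, lt_twice_month = 50) / 54,
      falling_asleep_alone = c(once_week = 20, once_day = 41) / 61,
      healthcare_center = c(prevention = 28, control = 41) / 69
    )
  )
}

#' Default BITSEA item-model calibration targets
#'
#' Per analysis domain: the nonwaking-group mean and SD, the internal
#' consistency the item model should reproduce, the standardized waking -
#' nonwaking shift, and the number of "common" (frequently endorsed) items
#' in the two-class item model. The two item classes let sparse problem
#' scales carry their shared variance on a few common items, which is the
#' only way a thresholded item model can approximate published mean, SD and
#' alpha simultaneously.
#'
#' @return Tibble with one row per domain.
#' @export
bitsea_target_defaults <- function() {
  tibble::tribble(
    ~domain,         ~mean_nonwaking, ~sd_nonwaking, ~alpha, ~effect_d, ~n_common,
    "internalizing", 1.05,            0.99,          0.515,  0.38,      2L,
    "externalizing", 3.00,            2.10,          0.650,  0.19,      2L,
    "dysregulation", 2.47,            2.14,          0.660,  0.72,      3L,
    "competence",    19.13,           2.60,          0.657,  -0.48,     8L
  )
}

#' Generator parameters for a synthetic cohort
#'
#' Defaults reproduce the statistical structure of the study the package
#' emulates: 77 waking / 69 nonwaking children, 83% retention at 24 months,
#' group-specific awakening counts (truncated Poisson with means 3.8 and
#' 0.9, respecting the group definitions of at least 3 vs at most 1),
#' condition-mean dwell indices per [dwell_mean_defaults()], a 0.10
#' between-child SD and 0.25 within-condition trial SD on the latent index
#' scale, a 10% unscorable-trial rate (which yields about 5.4 scorable
#' trials of 6 per condition), a 3% extra long-gap rate at 24 months, BITSEA
#' domain shifts of d = 0.72 (dysregulation), -0.48 (competence), 0.38
#' (internalizing) and 0.19 (externalizing), and a 0.337 child-level
#' correlation between the 8-month happy-condition dwell latent and the
#' competence latent.
#'
#' @param n_waking,n_nonwaking Group sizes.
#' @param retention_24m Probability a child returns at 24 months.
#' @param awakening_mean_waking,awakening_mean_nonwaking Mean awakening
#'   counts per group (conditional on the group definition).
#' @param mu Condition-mean tibble (`group`, `condition`, `mu`).
#' @param sigma_subject Between-child SD of the latent index intercept.
#' @param sigma_trial Within-condition trial SD of the latent index.
#' @param p_invalid Per-trial probability of an unscorable trial.
#' @param p_gap Additional per-trial probability of a >200 ms gap at 24
#'   months.
#' @param bitsea_targets Item-model calibration targets
#'   ([bitsea_target_defaults()]).
#' @param bitsea_effects Named standardized group shifts per domain.
#' @param child_factor_loading Loading of the shared child factor across
#'   BITSEA domains (a stated convention; within-child domain correlations
#'   are not published).
#' @param rho_happy_competence Child-level correlation between the gaze
#'   intercept (hence the 8-month happy dwell latent) and the competence
#'   latent.
#' @param covariate_freqs Per-group covariate category probabilities.
#' @param sampling_rate_hz Eye-tracker sampling rate of the emitted logs.
#' @param age_trend Additive change of all condition means at 24 months
#'   (default 0; exposed for sensitivity work).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_waking = 77, n_nonwaking = 69,
                       retention_24m = 0.83,
                       awakening_mean_waking = 3.8,
                       awakening_mean_nonwaking = 0.9,
                       mu = dwell_mean_defaults(),
                       sigma_subject = 0.10,
                       sigma_trial = 0.25,
                       p_invalid = 0.10,
                       p_gap = 0.03,
                       bitsea_targets = bitsea_target_defaults(),
                       bitsea_effects = c(internalizing = 0.38,
                                          externalizing = 0.19,
                                          dysregulation = 0.72,
                                          competence = -0.48),
                       child_factor_loading = 0.3,
                       rho_happy_competence = 0.337,
                       covariate_freqs = covariate_freq_defaults(),
                       sampling_rate_hz = 300,
                       age_trend = 0) {
  check_that(is_count(n_waking) && is_count(n_nonwaking) &&
               n_waking + n_nonwaking > 0, "group sizes must be counts")
  check_that(is_prob(retention_24m) && is_prob(p_invalid) && is_prob(p_gap),
             "probabilities must lie in [0, 1]")
  check_that(all(mu$mu > 0 & mu$mu < 1), "all mu entries must lie in (0, 1)")
  check_that(sigma_subject >= 0 && sigma_trial >= 0, "SDs must be nonnegative")
  bt <- bitsea_targets
  bt$effect_d <- bitsea_effects[bt$domain]
  structure(list(
    n_waking = n_waking, n_nonwaking = n_nonwaking,
    retention_24m = retention_24m,
    awakening_mean_waking = awakening_mean_waking,
    awakening_mean_nonwaking = awakening_mean_nonwaking,
    mu = mu, sigma_subject = sigma_subject, sigma_trial = sigma_trial,
    p_invalid = p_invalid, p_gap = p_gap,
    bitsea_targets = bt,
    child_factor_loading = child_factor_loading,
    rho_happy_competence = rho_happy_competence,
    covariate_freqs = covariate_freqs,
    sampling_rate_hz = sampling_rate_hz,
    age_trend = age_trend
  ), class = "sim_params")
}

# Expected value of clamp(X, 0, 1) for X ~ Normal(m, sigma^2): mass below 0
# scores 0 (anticipatory floor), mass above 1 scores 1 (timeout).
censored_clamp_mean <- function(m, sigma) {
  if (sigma == 0) return(pmin(pmax(m, 0), 1))
  a0 <- (0 - m) / sigma
  a1 <- (1 - m) / sigma
  (1 - stats::pnorm(a1)) +
    m * (stats::pnorm(a1) - stats::pnorm(a0)) +
    sigma * (stats::dnorm(a0) - stats::dnorm(a1))
}

#' Calibrate the latent location for a censored target mean
#'
#' Returns the location m such that `E[clamp(Normal(m, sigma^2), 0, 1)]`
#' equals `target_mean` to within 1e-9, by monotone root finding. This is
#' what lets the generator's post-censoring condition means equal the
#' documented mu matrix even though latent indices beyond [0, 1] are
#' emitted as anticipatory-floor and timeout trials.
#'
#' @param target_mean Desired post-censoring mean, in (0, 1).
#' @param sigma Total latent SD.
#' @param cell Optional label used in error messages.
#' @return Location parameter m.
#' @examples
#' calibrate_censored_mean(0.5, 0.25)   # 0.5 by symmetry
#' @export
calibrate_censored_mean <- function(target_mean, sigma, cell = NULL) {
  lab <- if (is.null(cell)) "" else paste0(" for cell ", cell)
  if (!is_prob(target_mean) || target_mean <= 0 || target_mean >= 1) {
    stop("target mean", lab, " must lie strictly in (0, 1)", call. = FALSE)
  }
  if (sigma == 0) return(target_mean)
  f <- function(m) censored_clamp_mean(m, sigma) - target_mean
  out <- tryCatch(
    stats::uniroot(f, lower = -10, upper = 11, tol = 1e-10),
    error = function(e) stop("censored-mean calibration failed", lab, ": ",
                             conditionMessage(e), call. = FALSE))
  out$root
}

# ---- BITSEA item-model calibration -----------------------------------------

# Conditional endorsement probability P(item >= level) given domain latent z,
# for threshold tau and loading lambda.
.q_cond <- function(z, tau, lambda) {
  stats::pnorm((lambda * z - tau) / sqrt(1 - lambda^2))
}

# Moments of the domain sum for the two-class graded item model, with the
# domain latent ~ Normal(mu, 1). Quadrature over the latent.
bitsea_sum_moments <- function(mu, lambda, tau_c, tau_r, n_common, n_rare) {
  z <- seq(-8, 8, by = 0.04) + mu
  w <- stats::dnorm(z, mean = mu) * 0.04
  w <- w / sum(w)
  e_c <- .q_cond(z, tau_c[1], lambda) + .q_cond(z, tau_c[2], lambda)
  e_r <- .q_cond(z, tau_r[1], lambda) + .q_cond(z, tau_r[2], lambda)
  s2_c <- .q_cond(z, tau_c[1], lambda) + 3 * .q_cond(z, tau_c[2], lambda)
  s2_r <- .q_cond(z, tau_r[1], lambda) + 3 * .q_cond(z, tau_r[2], lambda)
  m_c <- sum(w * e_c); m_r <- sum(w * e_r)
  v_c <- sum(w * s2_c) - m_c^2
  v_r <- sum(w * s2_r) - m_r^2
  cov_cc <- sum(w * e_c * e_c) - m_c^2
  cov_rr <- sum(w * e_r * e_r) - m_r^2
  cov_cr <- sum(w * e_c * e_r) - m_c * m_r
  mean_sum <- n_common * m_c + n_rare * m_r
  var_sum <- n_common * v_c + n_rare * v_r +
    n_common * (n_common - 1) * cov_cc + n_rare * (n_rare - 1) * cov_rr +
    2 * n_common * n_rare * cov_cr
  sum_item_var <- n_common * v_c + n_rare * v_r
  k <- n_common + n_rare
  alpha <- (k / (k - 1)) * (1 - sum_item_var / var_sum)
  list(mean = mean_sum, sd = sqrt(var_sum), alpha = alpha)
}

# Solve (lambda, tau_common, tau_rare) so the nonwaking-group sum matches the
# target mean/SD/alpha, then the latent group shift delta for the target
# standardized effect. Deterministic; cached per parameter set.
calibrate_bitsea_domain <- function(k, n_common, mean0, sd0, alpha0, effect_d) {
  n_rare <- k - n_common
  key <- paste(k, n_common, mean0, sd0, alpha0, effect_d, sep = "|")
  if (!is.null(.bitsea_cal_cache[[key]])) return(.bitsea_cal_cache[[key]])
  # parameters: logit-ish lambda, tau1_c, dtau_c, tau1_r, dtau_r
  unpack <- function(p) {
    lambda <- 0.95 / (1 + exp(-p[1]))
    list(lambda = lambda,
         tau_c = c(p[2], p[2] + exp(p[3])),
         tau_r = c(p[4], p[4] + exp(p[5])))
  }
  obj <- function(p) {
    u <- unpack(p)
    mo <- bitsea_sum_moments(0, u$lambda, u$tau_c, u$tau_r, n_common, n_rare)
    ((mo$mean - mean0) / max(mean0, 1))^2 +
      ((mo$sd - sd0) / sd0)^2 +
      ((mo$alpha - alpha0) / alpha0)^2
  }
  init <- c(0.5, stats::qnorm(1 - min(mean0 / k, 0.95)), 0.2,
            stats::qnorm(1 - min(mean0 / (3 * k), 0.3)) + 0.5, 0.2)
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  u <- unpack(fit$par)
  base <- bitsea_sum_moments(0, u$lambda, u$tau_c, u$tau_r, n_common, n_rare)
  # group shift: standardized difference of the sum under latent shift delta
  g <- function(delta) {
    mo <- bitsea_sum_moments(delta, u$lambda, u$tau_c, u$tau_r, n_common, n_rare)
    sd_pool <- sqrt((mo$sd^2 + base$sd^2) / 2)
    (mo$mean - base$mean) / sd_pool - effect_d
  }
  delta <- stats::uniroot(g, lower = -3, upper = 3, tol = 1e-8)$root
  out <- list(lambda = u$lambda, tau_c = u$tau_c, tau_r = u$tau_r,
              delta = delta, achieved = base, objective = fit$value)
  .bitsea_cal_cache[[key]] <- out
  out
}

.bitsea_cal_cache <- new.env(parent = emptyenv())

# ---- cohort simulation ------------------------------------------------------

# truncated-Poisson awakening counts: waking conditioned on >= 3 with a
# conditional mean matching the published group mean; nonwaking conditioned
# on <= 1 (equivalent to Bernoulli(lambda/(1+lambda)))
sample_awakenings <- function(n, group, target_mean) {
  if (group == "nonwaking") {
    p1 <- target_mean            # = lambda/(1+lambda), directly the P(count=1)
    return(stats::rbinom(n, 1, p1))
  }
  cond_mean <- function(lam) {
    k <- 0:100
    pk <- stats::dpois(k, lam)
    sum(k[k >= 3] * pk[k >= 3]) / sum(pk[k >= 3])
  }
  lam <- stats::uniroot(function(l) cond_mean(l) - target_mean,
                        lower = 0.05, upper = 20, tol = 1e-8)$root
  out <- integer(0)
  while (length(out) < n) {
    draw <- stats::rpois(2 * n, lam)
    out <- c(out, draw[draw >= 3])
  }
  out[seq_len(n)]
}

sample_categorical <- function(n, probs) {
  names(probs)[1 + findInterval(stats::runif(n), cumsum(probs),
                                left.open = TRUE)]
}

# session time layout: trial t occupies [3000 t, 3000 t + 2000]; central
# onset at 3000 t, distractor onset 1000 ms later
trial_start_ms <- function(trial_index) 3000 * trial_index

sample_time <- function(trial_start, k, dt) trial_start + round(k * dt, 3)

# latency as the scorer will compute it: time of the last central sample
# minus the distractor onset, in identical floating-point arithmetic
latency_from_k <- function(trial_start, k_trans, dt, solo_ms = 1000) {
  sample_time(trial_start, k_trans, dt) - (trial_start + solo_ms)
}

#' Simulate a complete synthetic cohort
#'
#' Generates demographics (night-awakening groups with their covariate
#' profiles), per-child latent gaze intercepts, per-trial latent dwell
#' indices at both ages (with the condition means calibrated so the
#' post-censoring means equal `params$mu`), BITSEA item responses at 24
#' months from a calibrated graded-threshold item model, attrition, and the
#' full ground-truth record. Gaze streams are a deterministic function of
#' the ground truth and are materialized lazily by [cohort_gaze()] /
#' [write_cohort()], so large cohorts stay cheap until their logs are
#' needed.
#'
#' Latent trial indices s >= 1 are emitted as timeout (no-saccade) trials;
#' s < 0 clamps to the anticipatory floor (latency 160 ms, index 0);
#' otherwise the emitted latency is 160 + 840 s, snapped to the observation
#' grid of the age (40-ms video frame at 8 months, the sample period at 24
#' months) with the snapped value recorded as ground truth. Unscorable
#' trials are injected at rate `p_invalid` by violating one validity rule
#' chosen uniformly (late initial fixation, wrong-direction saccade,
#' anticipatory latency, and at 24 months a >200-ms gap); additional gap
#' trials occur at rate `p_gap` at 24 months.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed; the same seed yields a bit-identical cohort.
#' @return Object of class `overlap_cohort`: list with `demographics`,
#'   `trial_truth`, `child_latents`, `bitsea_responses`, `instrument`,
#'   `params`, `seed`, `protocol`, `cell_locations`.
#' @export
simulate_cohort <- function(params = sim_params(), seed) {
  stopifnot(inherits(params, "sim_params"))
  spec <- protocol_spec()
  instrument <- load_instrument()
  n <- params$n_waking + params$n_nonwaking
  ids <- sprintf("P%04d", seq_len(n))
  group <- rep(c("waking", "nonwaking"), c(params$n_waking, params$n_nonwaking))

  sigma_tot <- sqrt(params$sigma_subject^2 + params$sigma_trial^2)
  mu_tab <- params$mu
  mu_tab$cell <- paste(mu_tab$group, mu_tab$condition, sep = ":")
  mu_tab$m <- vapply(seq_len(nrow(mu_tab)), function(i) {
    calibrate_censored_mean(mu_tab$mu[i], sigma_tot, cell = mu_tab$cell[i])
  }, numeric(1))

  bt <- params$bitsea_targets
  cal <- lapply(seq_len(nrow(bt)), function(i) {
    k <- sum(instrument$domain == bt$domain[i])
    calibrate_bitsea_domain(k, bt$n_common[i], bt$mean_nonwaking[i],
                            bt$sd_nonwaking[i], bt$alpha[i], bt$effect_d[i])
  })
  names(cal) <- bt$domain

  with_seed(seed, {
    # demographics ------------------------------------------------------
    awak_w <- sample_awakenings(params$n_waking, "waking",
                                params$awakening_mean_waking)
    awak_nw <- sample_awakenings(params$n_nonwaking, "nonwaking",
                                 params$awakening_mean_nonwaking)
    cf <- params$covariate_freqs
    draw_cov <- function(name) {
      out <- character(n)
      for (g in c("waking", "nonwaking")) {
        sel <- group == g
        out[sel] <- sample_categorical(sum(sel), cf[[g]][[name]])
      }
      out
    }
    demographics <- tibble::tibble(
      participant_id = ids,
      group = group,
      awakenings = c(awak_w, awak_nw),
      breastfeeding = draw_cov("breastfeeding"),
      co_sleeping = draw_cov("co_sleeping"),
      falling_asleep_alone = draw_cov("falling_asleep_alone"),
      healthcare_center = draw_cov("healthcare_center"),
      ces_d = round(pmax(stats::rnorm(n, 10, 6), 0)),
      stai = round(pmax(stats::rnorm(n, 34, 8), 20)),
      retained_24m = stats::runif(n) < params$retention_24m
    )

    # child latents -----------------------------------------------------
    zg <- stats::rnorm(n)                       # gaze intercept (standardized)
    f <- stats::rnorm(n)                        # shared socio-emotional factor
    lf <- params$child_factor_loading
    rho <- params$rho_happy_competence
    z_dom <- sapply(bt$domain, function(d) {
      if (d == "competence") {
        resid_sd <- sqrt(1 - lf^2 - rho^2)
        lf * f + rho * zg + resid_sd * stats::rnorm(n)
      } else {
        lf * f + sqrt(1 - lf^2) * stats::rnorm(n)
      }
    })
    colnames(z_dom) <- bt$domain
    shifted <- z_dom
    for (d in bt$domain) {
      shifted[group == "waking", d] <- shifted[group == "waking", d] +
        cal[[d]]$delta
    }
    mu_happy <- stats::setNames(mu_tab$m[mu_tab$condition == "happy"],
                                mu_tab$group[mu_tab$condition == "happy"])
    child_latents <- tibble::tibble(
      participant_id = ids, group = group,
      gaze_intercept_z = zg, shared_factor = f,
      happy_latent_8m = mu_happy[group] + params$sigma_subject * zg,
      internalizing_latent = shifted[, "internalizing"],
      externalizing_latent = shifted[, "externalizing"],
      dysregulation_latent = shifted[, "dysregulation"],
      competence_latent = shifted[, "competence"]
    )

    # trial-level ground truth -------------------------------------------
    dt <- 1000 / params$sampling_rate_hz
    sessions <- expand.grid(idx = seq_len(n), age = c(8, 24))
    sessions <- sessions[sessions$age == 8 |
                           demographics$retained_24m[sessions$idx], ]
    truth <- dplyr::bind_rows(lapply(seq_len(nrow(sessions)), function(r) {
      i <- sessions$idx[r]
      age <- sessions$age[r]
      sched <- generate_schedule(spec, seed = derive_seed(seed, i * 97 + age))
      nt <- nrow(sched)
      cell_m <- mu_tab$m[match(paste(group[i], sched$condition, sep = ":"),
                               mu_tab$cell)] +
        if (age == 24) params$age_trend else 0
      s_lat <- cell_m + params$sigma_subject * zg[i] +
        stats::rnorm(nt, 0, params$sigma_trial)
      u <- stats::runif(nt)
      inv_rules <- if (age == 8) {
        c("invalid_initial", "invalid_wrong", "invalid_anticipatory")
      } else {
        c("invalid_initial", "invalid_wrong", "invalid_anticipatory",
          "invalid_gap")
      }
      type <- ifelse(u < params$p_invalid,
                     inv_rules[1 + floor(stats::runif(nt) * length(inv_rules))],
                     "saccade")
      if (age == 24 && params$p_gap > 0) {
        extra <- type == "saccade" & stats::runif(nt) < params$p_gap
        type[extra] <- "invalid_gap"
      }
      # snap valid latencies to the observation grid of the age
      x_raw <- 160 + 840 * pmax(s_lat, 0)
      grid <- if (age == 8) spec$frame_ms else dt
      k_grid <- round(x_raw / grid)
      x_grid <- k_grid * grid
      timeout <- s_lat >= 1 | x_grid >= 1000
      starts <- trial_start_ms(sched$trial_index)
      k_trans <- 1000 / dt + round(x_grid / dt)
      lat <- latency_from_k(starts, k_trans, dt)
      latency <- ifelse(type == "saccade" & !timeout, lat, NA_real_)
      type[type == "saccade" & timeout] <- "timeout"
      true_index <- ifelse(type == "timeout", 1,
                           ifelse(type == "saccade",
                                  pmin(pmax((latency - 160) / 840, 0), 1),
                                  NA_real_))
      tibble::tibble(
        participant_id = ids[i], group = group[i], age = age,
        trial_index = sched$trial_index, condition = sched$condition,
        distractor_side = sched$distractor_side,
        type = type, latent_s = s_lat,
        latency_ms = latency, true_index = true_index
      )
    }))

    # BITSEA item responses at 24 months ---------------------------------
    retained <- which(demographics$retained_24m)
    resp <- matrix(NA_real_, nrow = length(retained), ncol = nrow(instrument),
                   dimnames = list(NULL, instrument$item_id))
    for (d in bt$domain) {
      item_ids <- instrument$item_id[instrument$domain == d]
      k <- length(item_ids)
      cc <- cal[[d]]
      n_common <- bt$n_common[bt$domain == d]
      z <- shifted[retained, d]
      eps <- matrix(stats::rnorm(length(retained) * k), ncol = k)
      t_lat <- cc$lambda * z + sqrt(1 - cc$lambda^2) * eps
      tau1 <- c(rep(cc$tau_c[1], n_common), rep(cc$tau_r[1], k - n_common))
      tau2 <- c(rep(cc$tau_c[2], n_common), rep(cc$tau_r[2], k - n_common))
      sc <- sweep(t_lat, 2, tau1, ">=") + sweep(t_lat, 2, tau2, ">=")
      resp[, item_ids] <- sc
    }
    other_ids <- instrument$item_id[instrument$domain == "other_problem"]
    if (length(other_ids) > 0) {
      eps <- matrix(stats::rnorm(length(retained) * length(other_ids)),
                    ncol = length(other_ids))
      resp[, other_ids] <- (eps >= 1.3) + (eps >= 2.3)
    }
    bitsea_responses <- dplyr::bind_cols(
      tibble::tibble(participant_id = ids[retained]),
      tibble::as_tibble(resp))

    structure(list(
      demographics = demographics,
      trial_truth = truth,
      child_latents = child_latents,
      bitsea_responses = bitsea_responses,
      instrument = instrument,
      params = params, seed = seed, protocol = spec,
      cell_locations = mu_tab
    ), class = "overlap_cohort")
  })
}

#' @export
print.overlap_cohort <- function(x, ...) {
  cat("Synthetic Overlap-task cohort:",
      x$params$n_waking, "waking /", x$params$n_nonwaking, "nonwaking children;",
      sum(x$demographics$retained_24m), "retained at 24 months (seed",
      paste0(x$seed, ")\n"))
  invisible(x)
}

# ---- deterministic gaze materialization -------------------------------------

# fixed gaze targets used by the emitter
.gaze_points <- function(aois) {
  mid <- function(r) c(mean(r[c("xmin", "xmax")]), mean(r[c("ymin", "ymax")]))
  list(central = c(0, 0),
       left = mid(aois$distractor_left),
       right = mid(aois$distractor_right),
       away = c(0, -20))
}

# emit the sample block for one trial's ground-truth row
emit_trial_samples <- function(row, dt, aois, anticipatory_demo = 80,
                               wrong_demo = 480, gap_demo = 520) {
  start <- trial_start_ms(row$trial_index)
  n_samp <- round(2000 / dt)
  k <- 0:n_samp
  t_ms <- sample_time(start, k, dt)
  pts <- .gaze_points(aois)
  target <- if (row$distractor_side == "left") pts$left else pts$right
  opposite <- if (row$distractor_side == "left") pts$right else pts$left
  k_onset <- round(1000 / dt)
  place <- function(k_trans, landing) {
    xy <- matrix(rep(pts$central, length(k)), ncol = 2, byrow = TRUE)
    after <- k > k_trans
    xy[after, 1] <- landing[1]
    xy[after, 2] <- landing[2]
    xy
  }
  valid <- rep(TRUE, length(k))
  if (row$type == "saccade") {
    k_trans <- k_onset + round((row$latency_ms) / dt)
    xy <- place(k_trans, target)
  } else if (row$type == "timeout") {
    xy <- place(length(k) + 1, target)
  } else if (row$type == "invalid_initial") {
    xy <- matrix(rep(pts$away, length(k)), ncol = 2, byrow = TRUE)
  } else if (row$type == "invalid_wrong") {
    xy <- place(k_onset + round(wrong_demo / dt), opposite)
  } else if (row$type == "invalid_anticipatory") {
    xy <- place(k_onset + round(anticipatory_demo / dt), target)
  } else if (row$type == "invalid_gap") {
    k_trans <- k_onset + round(gap_demo / dt)
    xy <- place(k_trans, target)
    rel <- t_ms - (start + 1000)
    valid <- !(rel >= gap_demo - 120 & rel <= gap_demo + 160)
  } else {
    stop("unknown trial type: ", row$type)
  }
  tibble::tibble(t_ms = t_ms, x_deg = xy[, 1], y_deg = xy[, 2], valid = valid)
}

#' Materialize the gaze and event logs for one session
#'
#' Deterministic function of the cohort's ground truth: calling it twice
#' gives identical streams.
#'
#' @param cohort An [simulate_cohort()] object.
#' @param participant_id Participant identifier.
#' @param age 8 or 24.
#' @return List with `samples` (gaze tibble) and `events` (event tibble).
#' @export
cohort_gaze <- function(cohort, participant_id, age) {
  rows <- cohort$trial_truth[cohort$trial_truth$participant_id == participant_id &
                               cohort$trial_truth$age == age, ]
  check_that(nrow(rows) > 0, paste("no session for", participant_id, "at age", age))
  dt <- 1000 / cohort$params$sampling_rate_hz
  aois <- build_aois(cohort$protocol)
  samples <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    emit_trial_samples(rows[i, ], dt, aois)
  }))
  events <- tibble::tibble(
    trial_index = rows$trial_index,
    condition = rows$condition,
    central_onset_ms = trial_start_ms(rows$trial_index),
    distractor_onset_ms = trial_start_ms(rows$trial_index) + 1000,
    distractor_side = rows$distractor_side
  )
  list(samples = samples, events = events)
}

#' Write a cohort's files
#'
#' Emits per-session gaze and event logs
#' (`gaze_<id>_<age>m.tsv` / `events_<id>_<age>m.tsv`), the BITSEA response
#' table, the demographics table and the ground-truth trial table under
#' `dir`.
#'
#' @param cohort An [simulate_cohort()] object.
#' @param dir Output directory (created if missing).
#' @param participants Optional subset of participant ids to write gaze
#'   logs for (all by default; event/summary tables always cover everyone).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, participants = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(cohort$demographics, file.path(dir, "demographics.tsv"))
  write_tsv_file(cohort$trial_truth, file.path(dir, "trial_truth.tsv"))
  write_tsv_file(cohort$bitsea_responses, file.path(dir, "bitsea_responses.tsv"))
  if (is.null(participants)) participants <- cohort$demographics$participant_id
  sess <- unique(cohort$trial_truth[, c("participant_id", "age")])
  sess <- sess[sess$participant_id %in% participants, ]
  for (r in seq_len(nrow(sess))) {
    gz <- cohort_gaze(cohort, sess$participant_id[r], sess$age[r])
    stem <- paste0(sess$participant_id[r], "_", sess$age[r], "m")
    write_gaze_log(gz$samples, file.path(dir, paste0("gaze_", stem, ".tsv")))
    write_event_log(gz$events, file.path(dir, paste0("events_", stem, ".tsv")))
  }
  invisible(dir)
}
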