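p8 <- scoring_params("infant8")
p24 <- scoring_params("toddler24")

test_that("short gaps are interpolated and long gaps reported unfilled", {
  tr <- make_trial(list(
    list(from = 1200, to = 1296, x = 0, y = 0, valid = FALSE)))
  out <- interpolate_gaps(tr, 200)
  rep <- attr(out, "gap_report")
  expect_true(all(out$samples$valid))
  expect_equal(nrow(rep), 1)
  expect_true(rep$filled)
  expect_lt(rep$extent_ms, 200)

  tr2 <- make_trial(list(
    list(from = 1200, to = 1448, x = 0, y = 0, valid = FALSE)))
  out2 <- interpolate_gaps(tr2, 200)
  rep2 <- attr(out2, "gap_report")
  expect_false(rep2$filled)
  expect_gte(rep2$extent_ms, 200)
  expect_true(any(!out2$samples$valid))

  # no invalid samples: identity
  tr3 <- make_timeout_trial()
  out3 <- interpolate_gaps(tr3, 200)
  expect_identical(out3$samples, tr3$samples)

  # all-invalid trial is reported but untouched
  tr4 <- make_trial(list(list(from = 0, to = 2000, x = 0, y = 0, valid = FALSE)))
  out4 <- interpolate_gaps(tr4, 200)
  expect_false(any(out4$samples$valid))
  expect_false(attr(out4, "gap_report")$filled)
})

test_that("interpolation fills coordinates linearly between the flanks", {
  tr <- make_trial(list(
    list(from = 0, to = 1000, x = 0, y = 0),
    list(from = 1003, to = 1097, x = 0, y = 0, valid = FALSE),
    list(from = 1100, to = 2000, x = 10, y = 10)))
  out <- interpolate_gaps(tr, 200)
  s <- out$samples
  mid <- s$t_ms > 1000 & s$t_ms < 1100
  expect_true(all(s$valid))
  w <- (s$t_ms[mid] - 1000) / 100
  expect_equal(s$x_deg[mid], 10 * w, tolerance = 1e-10)
})

test_that("frame quantization floors to the 40-ms grid and is idempotent", {
  tr <- make_timeout_trial(dt = 5)
  q1 <- frame_quantize(tr, 40)
  rel <- q1$samples$t_ms - 1000
  expect_true(all(rel %% 40 == 0))
  # a sample at +515 ms lands on frame +480
  expect_equal(unique(rel[tr$samples$t_ms - 1000 >= 480 &
                            tr$samples$t_ms - 1000 < 520]), 480)
  q2 <- frame_quantize(q1, 40)
  expect_identical(q2$samples, q1$samples)
})

test_that("frame-quantized and raw scoring differ by less than one frame", {
  withr::with_seed(99, {
    for (i in 1:50) {
      lat <- round(runif(1, 200, 960), 1)
      tr <- make_saccade_trial(lat)
      raw <- find_disengagement(tr, default_aois, p8)
      qs <- score_trial(tr, default_aois, p8)  # quantizes first
      expect_equal(raw$status, "scorable_saccade")
      expect_equal(qs$status, "scorable_saccade")
      expect_lt(abs(raw$latency_ms - qs$latency_ms), 40)
    }
  })
})

test_that("the dwell index endpoints and midpoint match the printed formula", {
  expect_identical(trial_index(160, p8), 0)
  expect_identical(trial_index(NA, p8, timeout = TRUE), 1)
  expect_equal(trial_index(580, p8), 0.5)
  # 24-month latencies in [150, 160) clamp to zero
  expect_identical(trial_index(155, p24), 0)
  expect_error(trial_index(NA_real_, p8), "undefined")
})

test_that("the index is monotone, bounded, and affinely identical to 1-(1000-x)/840", {
  x <- seq(160, 1000, by = 0.5)
  idx <- trial_index(x, p8)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(idx >= 0 & idx <= 1))
  expect_equal(idx, 1 - (1000 - x) / 840, tolerance = 1e-15)
  expect_equal(mean(idx), mean(1 - (1000 - x) / 840), tolerance = 1e-15)
})

test_that("a clean saccade is scored with its exact latency", {
  tr <- make_saccade_trial(500)
  sc <- find_disengagement(tr, default_aois, p24)
  expect_equal(sc$status, "scorable_saccade")
  expect_equal(sc$latency_ms, 500)
  expect_equal(sc$index, (500 - 160) / 840)
})

test_that("a full-window fixation scores as a timeout with index 1", {
  sc <- find_disengagement(make_timeout_trial(), default_aois, p24)
  expect_equal(sc$status, "scorable_timeout")
  expect_equal(sc$index, 1)
})

test_that("anticipatory saccades are rejected per age-specific thresholds", {
  sc8 <- find_disengagement(make_saccade_trial(120), default_aois, p8)
  expect_equal(sc8$status, "rejected_anticipatory")
  # 155 ms: anticipatory at 8 months (<160) but acceptable at 24 (>150);
  # construct on a grid that holds a sample at +155
  tr <- make_saccade_trial(155, dt = 5)
  expect_equal(find_disengagement(tr, default_aois, p8)$status,
               "rejected_anticipatory")
  sc24 <- find_disengagement(tr, default_aois, p24)
  expect_equal(sc24$status, "scorable_saccade")
  expect_equal(sc24$index, 0)  # clamped below the 160-ms normalization floor
})

test_that("saccades away from the distractor are rejected as wrong direction", {
  opp <- aoi_center(default_aois$distractor_left)
  tr <- make_trial(list(
    list(from = 1500.001, to = 2000, x = opp[1], y = opp[2])), side = "right")
  expect_equal(find_disengagement(tr, default_aois, p24)$status,
               "rejected_wrong_direction")
  # leaving the face without registering anywhere is also not a valid saccade
  tr2 <- make_trial(list(
    list(from = 1500.001, to = 2000, x = 0, y = -20)), side = "right")
  expect_equal(find_disengagement(tr2, default_aois, p24)$status,
               "rejected_wrong_direction")
})

test_that("insufficient central fixation is rejected at 24 months only", {
  tgt <- aoi_center(default_aois$distractor_right)
  # repeated brief excursions keep the pre-saccade central fraction ~32%
  segs <- list(
    list(from = 1060, to = 1230, x = 0, y = -20),
    list(from = 1290, to = 1460, x = 0, y = -20),
    list(from = 1520, to = 1690, x = 0, y = -20),
    list(from = 1750.001, to = 2000, x = tgt[1], y = tgt[2]))
  tr <- make_trial(segs, side = "right")
  sc24 <- find_disengagement(tr, default_aois, p24)
  expect_equal(sc24$status, "rejected_insufficient_fixation")
  sc8 <- find_disengagement(tr, default_aois, scoring_params("infant8"))
  expect_equal(sc8$status, "scorable_saccade")
  expect_equal(sc8$latency_ms, 750)
})

test_that("gaze absent at trial start or distractor onset rejects the trial", {
  tr <- make_trial(list(list(from = 0, to = 2000, x = 0, y = -20)))
  expect_equal(find_disengagement(tr, default_aois, p24)$status,
               "rejected_no_initial_fixation")
  empty <- make_timeout_trial()
  empty$samples <- empty$samples[0, ]
  expect_equal(find_disengagement(empty, default_aois, p24)$status,
               "rejected_no_initial_fixation")
})

test_that("a saccade landing across missing data is rejected at 24 months", {
  tgt <- aoi_center(default_aois$distractor_right)
  tr <- make_trial(list(
    list(from = 1500.001, to = 1560, x = 0, y = 0, valid = FALSE),
    list(from = 1560.001, to = 2000, x = tgt[1], y = tgt[2])), side = "right")
  # scored directly (no interpolation): the transition crosses invalid samples
  expect_equal(find_disengagement(tr, default_aois, p24)$status,
               "rejected_missing_at_saccade")
  # the composed pipeline interpolates the short gap away instead
  expect_equal(score_trial(tr, default_aois, p24)$status, "scorable_saccade")
})

test_that("long gaps inside the analysis window reject the trial", {
  tgt <- aoi_center(default_aois$distractor_right)
  tr <- make_trial(list(
    list(from = 1400, to = 1660, x = 0, y = 0, valid = FALSE),
    list(from = 1660.001, to = 2000, x = tgt[1], y = tgt[2])), side = "right")
  expect_equal(score_trial(tr, default_aois, p24)$status, "rejected_gap")
})

test_that("excess pre-onset movement is rejected at 8 months only", {
  segs <- list(
    list(from = 100, to = 180, x = 0, y = -20),
    list(from = 300, to = 380, x = 0, y = -20),
    list(from = 500, to = 580, x = 0, y = -20))
  tr <- make_trial(segs)
  expect_equal(find_disengagement(tr, default_aois, p8)$status,
               "rejected_excess_movement")
  expect_equal(find_disengagement(tr, default_aois, p24)$status,
               "scorable_timeout")
})

test_that("the scorer agrees with the brute-force AOI-walk oracle", {
  withr::with_seed(2024, {
    n_mismatch <- 0
    for (i in 1:1000) {
      tr <- random_trial()
      params <- if (i %% 2 == 0) p24 else p8
      got <- find_disengagement(tr, default_aois, params)
      want <- oracle_score(tr, default_aois, params)
      same <- identical(got$status, want$status) &&
        (is.na(want$latency_ms) || isTRUE(all.equal(got$latency_ms,
                                                    want$latency_ms)))
      if (!same) n_mismatch <- n_mismatch + 1
    }
    expect_equal(n_mismatch, 0)
  })
})

test_that("condition dwell averages scorable trials only", {
  ts <- tibble::tibble(
    condition = "fearful",
    status = c("scorable_saccade", "scorable_timeout", "rejected_gap",
               "rejected_anticipatory", "rejected_wrong_direction"),
    index = c(0, 1, NA, NA, NA))
  cd <- condition_dwell(ts, "fearful")
  expect_equal(cd$n_scorable, 2)
  expect_equal(cd$dwell_index, 0.5)

  ts2 <- tibble::tibble(condition = "happy",
                        status = rep("scorable_timeout", 6), index = 1)
  expect_equal(condition_dwell(ts2, "happy")$dwell_index, 1)
  expect_true(is.na(condition_dwell(ts2, "fearful")$dwell_index))
})

test_that("participant inclusion requires two scorable trials per condition", {
  sched <- generate_schedule(default_spec, 3)
  trials <- lapply(seq_len(nrow(sched)), function(i) {
    make_saccade_trial(520, side = sched$distractor_side[i],
                       trial_index = sched$trial_index[i],
                       condition = sched$condition[i],
                       t0 = 3000 * sched$trial_index[i])
  })
  ps <- score_participant(trials, default_aois, p24,
                          participant_id = "X",
                          conditions = default_spec$conditions)
  expect_true(ps$included)
  expect_true(all(ps$condition_scores$n_scorable == 6))

  # knock one condition down to a single scorable trial
  bad <- which(sched$condition == "happy")[1:5]
  for (i in bad) {
    trials[[i]] <- make_trial(list(list(from = 0, to = 2000, x = 0, y = -20)),
                              trial_index = sched$trial_index[i],
                              condition = "happy",
                              t0 = 3000 * sched$trial_index[i])
  }
  ps2 <- score_participant(trials, default_aois, p24,
                           conditions = default_spec$conditions)
  expect_false(ps2$included)
  expect_equal(ps2$condition_scores$n_scorable[
    ps2$condition_scores$condition == "happy"], 1)
})

test_that("scoring is deterministic and order-independent across trials", {
  sched <- generate_schedule(default_spec, 8)
  trials <- lapply(seq_len(nrow(sched)), function(i) {
    make_saccade_trial(200 + 40 * (i %% 10), side = sched$distractor_side[i],
                       trial_index = sched$trial_index[i],
                       condition = sched$condition[i],
                       t0 = 3000 * sched$trial_index[i])
  })
  a <- score_participant(trials, default_aois, p8,
                         conditions = default_spec$conditions)
  b <- score_participant(rev(trials), default_aois, p8,
                         conditions = default_spec$conditions)
  expect_equal(a$condition_scores, b$condition_scores)
  expect_equal(a$included, b$included)
})
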