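#' Scoring parameters for the Overlap task
#'
#' Two age modes mirror the two measurement instruments: `infant8` (manual
#' video coding at 25 fps, i.e. 40-ms frames, anticipatory threshold
#' 160 ms) and `toddler24` (automated 300-Hz eye tracking, anticipatory
#' threshold 150 ms, with a 70% central-fixation requirement and a 200-ms
#' maximal tolerated gap in the gaze data).
#'
#' The normalized dwell-time index maps a disengagement latency x in
#' milliseconds to `clamp((x - norm_min_ms) / norm_span_ms, 0, 1)`, which
#' for the default constants (160, 840) is algebraically identical to
#' `1 - (1000 - x)/840`: the shortest acceptable latency scores 0 and a
#' trial without a saccade by the 1000-ms window end scores 1.
#'
#' @param age_mode `"infant8"` or `"toddler24"`.
#' @param anticipatory_ms Anticipatory-saccade floor in ms (defaults 160 at
#'   8 months, 150 at 24 months).
#' @param window_end_ms Analysis-window end relative to distractor onset.
#' @param norm_min_ms,norm_span_ms Constants of the dwell-index normalization.
#' @param min_fixation_fraction Minimal fraction of pre-disengagement time
#'   on the central face (toddler24 only).
#' @param max_gap_ms Longest tolerated missing-data run (toddler24 only);
#'   shorter runs are linearly interpolated.
#' @param frame_ms Video frame duration for manual-coding quantization
#'   (infant8 only).
#' @param min_scorable_per_condition Inclusion rule: minimum scorable trials
#'   in every condition.
#' @param max_central_exits Ceiling on central-AOI exits before distractor
#'   onset used to flag excessive movement (infant8 only); this rejection
#'   rule has no published quantitative definition and the ceiling is a
#'   package convention.
#' @param landing_window_ms A saccade counts as directed to the distractor
#'   only if gaze registers inside the distractor AOI within this long after
#'   leaving the central AOI.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(age_mode = c("infant8", "toddler24"),
                           anticipatory_ms = NULL,
                           window_end_ms = 1000,
                           norm_min_ms = 160,
                           norm_span_ms = 840,
                           min_fixation_fraction = 0.70,
                           max_gap_ms = 200,
                           frame_ms = 40,
                           min_scorable_per_condition = 2,
                           max_central_exits = 2,
                           landing_window_ms = 200) {
  age_mode <- match.arg(age_mode)
  if (is.null(anticipatory_ms)) {
    anticipatory_ms <- if (age_mode == "infant8") 160 else 150
  }
  check_that(norm_min_ms + norm_span_ms == window_end_ms,
             "norm_min_ms + norm_span_ms must equal window_end_ms")
  check_that(min_fixation_fraction > 0 && min_fixation_fraction <= 1,
             "`min_fixation_fraction` must lie in (0, 1]")
  check_that(anticipatory_ms > 0 && anticipatory_ms < window_end_ms,
             "`anticipatory_ms` must lie in (0, window_end_ms)")
  structure(list(age_mode = age_mode,
                 anticipatory_ms = anticipatory_ms,
                 window_end_ms = window_end_ms,
                 norm_min_ms = norm_min_ms,
                 norm_span_ms = norm_span_ms,
                 min_fixation_fraction = min_fixation_fraction,
                 max_gap_ms = max_gap_ms,
                 frame_ms = frame_ms,
                 min_scorable_per_condition = min_scorable_per_condition,
                 max_central_exits = max_central_exits,
                 landing_window_ms = landing_window_ms),
            class = "scoring_params")
}

trial_statuses <- c("scorable_saccade", "scorable_timeout",
                    "rejected_no_initial_fixation", "rejected_anticipatory",
                    "rejected_wrong_direction", "rejected_gap",
                    "rejected_insufficient_fixation",
                    "rejected_excess_movement", "rejected_missing_at_saccade")

scorable_statuses <- c("scorable_saccade", "scorable_timeout")

#' Interpolate short gaps in a trial's gaze data
#'
#' Runs of invalid samples whose extent (time between the flanking valid
#' samples) does not exceed `max_gap_ms` are filled by linear interpolation
#' of the flanking coordinates; longer runs, and runs touching the record
#' boundary, are left invalid. Used on the automated (24-month) path before
#' disengagement scoring.
#'
#' @param trial A `trial_record` (see [segment_trials()]).
#' @param max_gap_ms Longest gap that may be filled.
#' @return The trial with interpolated samples; attribute `"gap_report"`
#'   holds a tibble of all invalid runs (`t_start`, `t_end`, `extent_ms`,
#'   `filled`).
#' @export
interpolate_gaps <- function(trial, max_gap_ms = 200) {
  s <- trial$samples
  report <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                           extent_ms = numeric(), filled = logical())
  if (nrow(s) == 0L || all(s$valid) ) {
    attr(trial, "gap_report") <- report
    return(trial)
  }
  if (!any(s$valid)) {
    # nothing to anchor interpolation on; leave untouched but report
    report <- tibble::tibble(t_start = s$t_ms[1], t_end = s$t_ms[nrow(s)],
                             extent_ms = s$t_ms[nrow(s)] - s$t_ms[1],
                             filled = FALSE)
    attr(trial, "gap_report") <- report
    return(trial)
  }
  r <- rle(s$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    prev_i <- i0 - 1L
    next_i <- i1 + 1L
    boundary <- prev_i < 1L || next_i > nrow(s)
    extent <- if (boundary) {
      s$t_ms[i1] - s$t_ms[i0]
    } else {
      s$t_ms[next_i] - s$t_ms[prev_i]
    }
    fill <- !boundary && extent <= max_gap_ms
    if (fill) {
      w <- (s$t_ms[i0:i1] - s$t_ms[prev_i]) / (s$t_ms[next_i] - s$t_ms[prev_i])
      s$x_deg[i0:i1] <- s$x_deg[prev_i] + w * (s$x_deg[next_i] - s$x_deg[prev_i])
      s$y_deg[i0:i1] <- s$y_deg[prev_i] + w * (s$y_deg[next_i] - s$y_deg[prev_i])
      s$valid[i0:i1] <- TRUE
    }
    report <- dplyr::bind_rows(report, tibble::tibble(
      t_start = s$t_ms[i0], t_end = s$t_ms[i1],
      extent_ms = extent, filled = fill))
  }
  trial$samples <- s
  attr(trial, "gap_report") <- report
  trial
}

#' Quantize sample times to the video frame grid
#'
#' Emulates the temporal resolution of manual frame-by-frame video coding:
#' sample times are floored to the `frame_ms` grid anchored at distractor
#' onset. Idempotent.
#'
#' @param trial A `trial_record`.
#' @param frame_ms Frame duration (default 40 ms).
#' @return The trial with quantized sample times.
#' @export
frame_quantize <- function(trial, frame_ms = 40) {
  if (nrow(trial$samples) == 0L) return(trial)
  onset <- trial$event$distractor_onset_ms
  rel <- trial$samples$t_ms - onset
  trial$samples$t_ms <- onset + floor(rel / frame_ms) * frame_ms
  trial
}

#' Per-trial normalized dwell-time index
#'
#' `clamp((x - norm_min_ms)/norm_span_ms, 0, 1)` for a saccade at latency
#' `x`; 1 for a timeout (no saccade by the window end). With the default
#' constants this equals the affine form `1 - (1000 - x)/840`. Latencies
#' below `norm_min_ms` (possible at 24 months, where the anticipatory floor
#' is 150 ms but the normalization keeps the printed 160/840 constants)
#' clamp to 0.
#'
#' @param latency_ms Saccade latency in ms, or `NA` for a timeout when
#'   `timeout = TRUE`.
#' @param params A [scoring_params()].
#' @param timeout Logical; `TRUE` scores the trial as a timeout.
#' @return Index value in `[0, 1]`.
#' @examples
#' p <- scoring_params("infant8")
#' trial_index(160, p)            # 0
#' trial_index(580, p)            # 0.5
#' trial_index(NA, p, timeout = TRUE)  # 1
#' @export
trial_index <- function(latency_ms, params, timeout = FALSE) {
  stopifnot(inherits(params, "scoring_params"))
  if (isTRUE(timeout)) return(1)
  if (any(is.na(latency_ms))) {
    stop("trial_index is undefined for rejected trials (NA latency)",
         call. = FALSE)
  }
  pmin(pmax((latency_ms - params$norm_min_ms) / params$norm_span_ms, 0), 1)
}

# label valid samples: "central", "target", "other", "away"
label_samples <- function(x, y, aois, side) {
  target_rect <- if (side == "left") aois$distractor_left else aois$distractor_right
  other_rect <- if (side == "left") aois$distractor_right else aois$distractor_left
  lab <- rep("away", length(x))
  lab[in_rect(x, y, other_rect)] <- "other"
  lab[in_rect(x, y, target_rect)] <- "target"
  lab[in_rect(x, y, aois$central)] <- "central"  # ties resolve to central
  lab
}

#' Score a single trial's disengagement
#'
#' Applies the validity rules of the trial's age mode and, for valid trials,
#' extracts the disengagement latency: the last time point at which gaze is
#' inside the central face AOI before the first gaze shift that lands in the
#' distractor AOI, measured from distractor onset. Trials where gaze stays
#' on the face through the whole analysis window are scorable timeouts with
#' index 1.
#'
#' Rejection rules: gaze not on the face at trial start or distractor onset
#' (`rejected_no_initial_fixation`); saccade landing in a stretch of missing
#' gaze data (`rejected_missing_at_saccade`, 24 months); an uninterpolated
#' gap longer than `max_gap_ms` inside the analysis window (`rejected_gap`,
#' 24 months); gaze leaving the face without registering in the distractor
#' AOI (`rejected_wrong_direction`); latency under the anticipatory floor
#' (`rejected_anticipatory`); under 70% of pre-disengagement time on the
#' face (`rejected_insufficient_fixation`, 24 months); more than
#' `max_central_exits` excursions off the face before distractor onset
#' (`rejected_excess_movement`, 8 months).
#'
#' @param trial A `trial_record`, already gap-interpolated / frame-quantized
#'   as appropriate for the age mode (see [score_trial()] for the composed
#'   pipeline).
#' @param aois An [build_aois()] AOI set.
#' @param params A [scoring_params()].
#' @return One-row tibble: `status`, `latency_ms`, `index`.
#' @export
find_disengagement <- function(trial, aois, params) {
  stopifnot(inherits(params, "scoring_params"))
  result <- function(status, latency = NA_real_) {
    idx <- if (status == "scorable_saccade") {
      trial_index(latency, params)
    } else if (status == "scorable_timeout") 1 else NA_real_
    tibble::tibble(status = status, latency_ms = latency, index = idx)
  }
  s <- trial$samples
  onset <- trial$event$distractor_onset_ms
  side <- trial$event$distractor_side
  wend <- onset + params$window_end_ms
  if (nrow(s) == 0L || !any(s$valid)) {
    return(result("rejected_no_initial_fixation"))
  }
  lab <- rep(NA_character_, nrow(s))
  lab[s$valid] <- label_samples(s$x_deg[s$valid], s$y_deg[s$valid], aois, side)

  # initial fixation: first valid sample of the trial, and the last valid
  # sample at or before distractor onset, must both be on the face
  vidx <- which(s$valid)
  first_valid <- vidx[1]
  pre <- vidx[s$t_ms[vidx] <= onset]
  if (lab[first_valid] != "central" || length(pre) == 0L ||
      lab[pre[length(pre)]] != "central") {
    return(result("rejected_no_initial_fixation"))
  }

  toddler <- params$age_mode == "toddler24"

  # unfilled long gaps inside the analysis window (24-month rule)
  long_gap <- FALSE
  if (toddler && any(!s$valid)) {
    r <- rle(s$valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(!r$values)) {
      prev_i <- starts[k] - 1L
      next_i <- ends[k] + 1L
      g0 <- if (prev_i >= 1L) s$t_ms[prev_i] else s$t_ms[starts[k]]
      g1 <- if (next_i <= nrow(s)) s$t_ms[next_i] else s$t_ms[ends[k]]
      if (g1 - g0 > params$max_gap_ms && g1 >= onset && g0 <= wend) {
        long_gap <- TRUE
      }
    }
  }

  # excessive movement before distractor onset (8-month rule): count
  # central-AOI exits in the valid pre-onset stream
  if (params$age_mode == "infant8") {
    pre_lab <- lab[vidx[s$t_ms[vidx] <= onset]]
    exits <- sum(pre_lab[-length(pre_lab)] == "central" &
                   pre_lab[-1] != "central")
    if (exits > params$max_central_exits) {
      return(result("rejected_excess_movement"))
    }
  }

  # walk valid samples in the analysis window
  win <- vidx[s$t_ms[vidx] >= onset & s$t_ms[vidx] <= wend]
  last_central_t <- s$t_ms[pre[length(pre)]]
  transition <- NULL   # list(latency, landing_i)
  wrong <- FALSE
  i <- 1L
  while (i <= length(win)) {
    j <- win[i]
    if (lab[j] == "central") {
      last_central_t <- s$t_ms[j]
      i <- i + 1L
      next
    }
    # departure from the face: scan ahead for the landing AOI
    horizon <- last_central_t + params$landing_window_ms
    k <- i
    landed <- NULL
    while (k <= length(win) && s$t_ms[win[k]] <= horizon) {
      lk <- lab[win[k]]
      if (lk == "target") { landed <- "target"; break }
      if (lk == "other") { landed <- "other"; break }
      if (lk == "central") { landed <- "central"; break }
      k <- k + 1L
    }
    if (is.null(landed)) {       # left the face, never registered anywhere
      wrong <- TRUE
      break
    } else if (landed == "target") {
      transition <- list(latency = last_central_t - onset, landing_i = win[k])
      break
    } else if (landed == "other") {
      wrong <- TRUE
      break
    } else {                     # brief excursion, gaze returned to the face
      last_central_t <- s$t_ms[win[k]]
      i <- k + 1L
    }
  }

  if (!is.null(transition) && toddler) {
    # landing must not happen across missing gaze data
    between <- s$t_ms > last_central_t & s$t_ms < s$t_ms[transition$landing_i]
    if (any(!s$valid[between])) {
      return(result("rejected_missing_at_saccade"))
    }
  }
  if (long_gap) return(result("rejected_gap"))
  if (wrong) return(result("rejected_wrong_direction"))

  # pre-disengagement central-fixation fraction (24-month rule)
  diseng_t <- if (!is.null(transition)) last_central_t else wend
  span <- win[s$t_ms[win] <= diseng_t]
  frac <- if (length(span) > 0L) mean(lab[span] == "central") else 1
  if (is.null(transition)) {
    # no saccade: the gaze must have remained on the face through the window
    if (length(win) == 0L || lab[win[length(win)]] != "central") {
      return(result("rejected_wrong_direction"))
    }
    if (toddler && frac < params$min_fixation_fraction) {
      return(result("rejected_insufficient_fixation"))
    }
    return(result("scorable_timeout"))
  }
  if (transition$latency < params$anticipatory_ms) {
    return(result("rejected_anticipatory"))
  }
  if (toddler && frac < params$min_fixation_fraction) {
    return(result("rejected_insufficient_fixation"))
  }
  result("scorable_saccade", transition$latency)
}

#' Score one trial end to end for its age mode
#'
#' Composes the mode-specific preprocessing (gap interpolation at 24
#' months, frame quantization at 8 months) with [find_disengagement()].
#'
#' @inheritParams find_disengagement
#' @return One-row tibble: `status`, `latency_ms`, `index`.
#' @export
score_trial <- function(trial, aois, params) {
  if (params$age_mode == "toddler24") {
    trial <- interpolate_gaps(trial, params$max_gap_ms)
  } else {
    trial <- frame_quantize(trial, params$frame_ms)
  }
  find_disengagement(trial, aois, params)
}

#' Condition-level dwell index
#'
#' Mean per-trial index over the scorable trials (saccades and timeouts) of
#' one condition; `n_scorable` is the formula's n. Undefined (NA) when no
#' trial is scorable.
#'
#' @param trial_scores Tibble of per-trial scores with columns `condition`,
#'   `status`, `index`.
#' @param condition Condition label to aggregate.
#' @return One-row tibble: `condition`, `n_scorable`, `dwell_index`.
#' @export
condition_dwell <- function(trial_scores, condition) {
  rows <- trial_scores[trial_scores$condition == condition &
                         trial_scores$status %in% scorable_statuses, ]
  tibble::tibble(
    condition = condition,
    n_scorable = nrow(rows),
    dwell_index = if (nrow(rows) > 0L) mean(rows$index) else NA_real_
  )
}

#' Score a participant's full session
#'
#' Scores every trial, aggregates the four condition dwell indices, and
#' applies the inclusion rule: a participant enters the analysis only with
#' at least `min_scorable_per_condition` scorable trials in every condition.
#'
#' @param trials List of `trial_record`s (one session).
#' @param aois AOI set.
#' @param params [scoring_params()].
#' @param participant_id Identifier copied into the output.
#' @param conditions Condition labels defining the session (defaults to the
#'   distinct conditions present in the events).
#' @return List of class `participant_scores`: `participant_id`, `age_mode`,
#'   `trial_scores` (per-trial tibble), `condition_scores` (4 rows),
#'   `included`.
#' @export
score_participant <- function(trials, aois, params, participant_id = NA,
                              conditions = NULL) {
  per_trial <- dplyr::bind_rows(lapply(trials, function(tr) {
    sc <- score_trial(tr, aois, params)
    dplyr::bind_cols(
      tibble::tibble(trial_index = tr$event$trial_index,
                     condition = tr$event$condition),
      sc)
  }))
  if (is.null(conditions)) conditions <- unique(per_trial$condition)
  cond <- dplyr::bind_rows(lapply(conditions, condition_dwell,
                                  trial_scores = per_trial))
  structure(list(
    participant_id = participant_id,
    age_mode = params$age_mode,
    trial_scores = per_trial,
    condition_scores = cond,
    included = all(cond$n_scorable >= params$min_scorable_per_condition)
  ), class = "participant_scores")
}

#' @export
print.participant_scores <- function(x, ...) {
  cat("Participant", x$participant_id, "(", x$age_mode, ")",
      if (x$included) "included" else "excluded", "\n")
  print(x$condition_scores)
  invisible(x)
}
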