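# Fixture builders and the independent brute-force scoring oracle.
# Everything here is constructed in code at test time; no stored data.

default_spec <- protocol_spec()
default_aois <- build_aois(default_spec)

# Build a trial_record from an explicit piecewise gaze trajectory.
# segments: list of list(from, to, x, y, valid) in ms relative to the
# central onset (trial spans 0..2000, distractor onset at 1000).
make_trial <- function(segments, dt = 10 / 3, trial_index = 0L,
                       condition = "fearful", side = "right",
                       t0 = 0) {
  n_samp <- round(2000 / dt)
  k <- 0:n_samp
  t_rel <- round(k * dt, 3)
  x <- rep(0, length(k)); y <- rep(0, length(k)); valid <- rep(TRUE, length(k))
  for (seg in segments) {
    sel <- t_rel >= seg$from & t_rel <= seg$to
    x[sel] <- seg$x
    y[sel] <- seg$y
    if (!is.null(seg$valid)) valid[sel] <- seg$valid
  }
  ev <- tibble::tibble(trial_index = trial_index, condition = condition,
                       central_onset_ms = t0, distractor_onset_ms = t0 + 1000,
                       distractor_side = side)
  structure(list(event = ev,
                 samples = tibble::tibble(t_ms = t0 + t_rel, x_deg = x,
                                          y_deg = y, valid = valid),
                 empty = FALSE, sampling_rate_hz = 1000 / dt),
            class = "trial_record")
}

aoi_center <- function(rect) c(mean(rect[c("xmin", "xmax")]),
                               mean(rect[c("ymin", "ymax")]))

# convenience: a clean saccade trial with the given latency (ms after
# distractor onset); gaze sits on the face through 1000 + latency, then on
# the distractor
make_saccade_trial <- function(latency, side = "right", dt = 10 / 3, ...) {
  target <- aoi_center(if (side == "left") default_aois$distractor_left
                       else default_aois$distractor_right)
  make_trial(list(
    list(from = 1000 + latency + 1e-9, to = 2000, x = target[1], y = target[2])
  ), side = side, dt = dt, ...)
}

make_timeout_trial <- function(side = "right", dt = 10 / 3, ...) {
  make_trial(list(), side = side, dt = dt, ...)
}

# ---- independent brute-force oracle ----------------------------------------
# A literal per-sample AOI walk, written as a plain state machine over
# individual samples. Deliberately unvectorized and structured around the
# rule statements rather than the package implementation.
oracle_score <- function(trial, aois, params) {
  s <- trial$samples
  onset <- trial$event$distractor_onset_ms
  side <- trial$event$distractor_side
  wend <- onset + params$window_end_ms
  rej <- function(st) list(status = st, latency_ms = NA_real_)
  if (nrow(s) == 0 || sum(s$valid) == 0) return(rej("rejected_no_initial_fixation"))

  lab_of <- function(i) {
    if (!s$valid[i]) return("invalid")
    x <- s$x_deg[i]; y <- s$y_deg[i]
    if (in_rect(x, y, aois$central)) return("central")
    tgt <- if (side == "left") aois$distractor_left else aois$distractor_right
    oth <- if (side == "left") aois$distractor_right else aois$distractor_left
    if (in_rect(x, y, tgt)) return("target")
    if (in_rect(x, y, oth)) return("other")
    "away"
  }
  labs <- vapply(seq_len(nrow(s)), lab_of, character(1))

  first_valid <- which(labs != "invalid")[1]
  pre_idx <- which(labs != "invalid" & s$t_ms <= onset)
  if (labs[first_valid] != "central" || length(pre_idx) == 0 ||
      labs[pre_idx[length(pre_idx)]] != "central") {
    return(rej("rejected_no_initial_fixation"))
  }

  toddler <- params$age_mode == "toddler24"

  long_gap <- FALSE
  if (toddler) {
    i <- 1
    while (i <= nrow(s)) {
      if (labs[i] == "invalid") {
        j <- i
        while (j <= nrow(s) && labs[j] == "invalid") j <- j + 1
        g0 <- if (i > 1) s$t_ms[i - 1] else s$t_ms[i]
        g1 <- if (j <= nrow(s)) s$t_ms[j] else s$t_ms[j - 1]
        if (g1 - g0 > params$max_gap_ms && g1 >= onset && g0 <= wend) {
          long_gap <- TRUE
        }
        i <- j
      } else i <- i + 1
    }
  }

  if (params$age_mode == "infant8") {
    exits <- 0
    prev <- NULL
    for (i in pre_idx) {
      if (!is.null(prev) && prev == "central" && labs[i] != "central") {
        exits <- exits + 1
      }
      prev <- labs[i]
    }
    if (exits > params$max_central_exits) return(rej("rejected_excess_movement"))
  }

  win <- which(labs != "invalid" & s$t_ms >= onset & s$t_ms <= wend)
  last_central <- s$t_ms[pre_idx[length(pre_idx)]]
  latency <- NA_real_
  landing_i <- NA_integer_
  outcome <- "none"
  i <- 1
  while (i <= length(win)) {
    idx <- win[i]
    if (labs[idx] == "central") {
      last_central <- s$t_ms[idx]
      i <- i + 1
      next
    }
    # departed the face: what does gaze reach within the landing window?
    hit <- "nothing"
    j <- i
    while (j <= length(win) &&
           s$t_ms[win[j]] <= last_central + params$landing_window_ms) {
      l <- labs[win[j]]
      if (l %in% c("target", "other", "central")) { hit <- l; break }
      j <- j + 1
    }
    if (hit == "target") {
      latency <- last_central - onset
      landing_i <- win[j]
      outcome <- "saccade"
      break
    } else if (hit == "central") {
      last_central <- s$t_ms[win[j]]
      i <- j + 1
    } else {
      outcome <- "wrong"
      break
    }
  }

  if (outcome == "saccade" && toddler) {
    mid <- which(s$t_ms > last_central & s$t_ms < s$t_ms[landing_i])
    if (any(labs[mid] == "invalid")) return(rej("rejected_missing_at_saccade"))
  }
  if (long_gap) return(rej("rejected_gap"))
  if (outcome == "wrong") return(rej("rejected_wrong_direction"))

  diseng <- if (outcome == "saccade") last_central else wend
  span <- win[s$t_ms[win] <= diseng]
  frac <- if (length(span) > 0) mean(labs[span] == "central") else 1

  if (outcome == "none") {
    if (length(win) == 0 || labs[win[length(win)]] != "central") {
      return(rej("rejected_wrong_direction"))
    }
    if (toddler && frac < params$min_fixation_fraction) {
      return(rej("rejected_insufficient_fixation"))
    }
    return(list(status = "scorable_timeout", latency_ms = NA_real_))
  }
  if (latency < params$anticipatory_ms) return(rej("rejected_anticipatory"))
  if (toddler && frac < params$min_fixation_fraction) {
    return(rej("rejected_insufficient_fixation"))
  }
  list(status = "scorable_saccade", latency_ms = latency)
}

# random synthetic trial for property tests: a mix of clean saccades,
# timeouts, wrong-direction shifts, anticipatory shifts, away starts and
# brief excursions, with coordinate jitter inside the AOIs
random_trial <- function(dt = 10 / 3) {
  side <- sample(c("left", "right"), 1)
  tgt <- aoi_center(if (side == "left") default_aois$distractor_left
                    else default_aois$distractor_right)
  oth <- aoi_center(if (side == "left") default_aois$distractor_right
                    else default_aois$distractor_left)
  kind <- sample(c("saccade", "timeout", "wrong", "anticipatory", "away",
                   "excursion"), 1)
  segs <- list()
  jx <- stats::runif(1, -2, 2); jy <- stats::runif(1, -2, 2)
  if (kind == "saccade" || kind == "anticipatory") {
    lat <- if (kind == "saccade") sample(seq(200, 960, by = 40), 1) else 80
    segs <- list(list(from = 1000 + lat + 0.001, to = 2000,
                      x = tgt[1] + jx / 2, y = tgt[2] + jy / 4))
  } else if (kind == "wrong") {
    lat <- sample(seq(200, 800, by = 40), 1)
    segs <- list(list(from = 1000 + lat + 0.001, to = 2000,
                      x = oth[1] + jx / 2, y = oth[2] + jy / 4))
  } else if (kind == "away") {
    segs <- list(list(from = 0, to = 2000, x = 0, y = -20))
  } else if (kind == "excursion") {
    # brief off-face excursion that returns, then a late saccade
    e0 <- sample(seq(1100, 1400, by = 40), 1)
    lat <- sample(seq(600, 960, by = 40), 1)
    segs <- list(
      list(from = e0, to = e0 + 120, x = 0, y = -20),
      list(from = 1000 + lat + 0.001, to = 2000, x = tgt[1], y = tgt[2]))
  }
  make_trial(segs, dt = dt, side = side)
}
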