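#' Overlap-task protocol specification
#'
#' Describes one session of the Overlap attention-disengagement task: a
#' central face (happy, fearful, neutral with eyes open, neutral with eyes
#' closed) is shown alone for 1000 ms and then flanked by a lateral
#' distractor for 3000 ms; the presentation order is randomized under
#' run-length restrictions (no emotion more than four times in a row, no
#' side more than three times in a row).
#'
#' Geometry is expressed in degrees of visual angle in screen-centered
#' coordinates (x rightward, y upward). `anticipatory_ms` is the per-age
#' floor on plausible disengagement latencies: saccades faster than this are
#' rejected as anticipatory (160 ms for the 8-month manual coding, 150 ms
#' for the 24-month eye tracking).
#'
#' @param conditions Character vector of face-condition labels.
#' @param trials_per_condition Trials per condition (default 6; 24 total).
#' @param central_solo_ms Duration the face is shown alone (ms).
#' @param overlap_ms Duration face and distractor are shown together (ms).
#' @param face_size_deg Width/height of the face stimulus in degrees.
#' @param distractor_size_deg Width/height of the distractor in degrees.
#' @param face_distractor_separation_deg Distance between face and
#'   distractor in degrees (nearest-edge by default; see [build_aois()]).
#' @param max_emotion_run Maximum allowed run of identical conditions.
#' @param max_side_run Maximum allowed run of identical distractor sides.
#' @param anticipatory_ms Named numeric, per-age anticipatory threshold (ms).
#' @param window_end_ms End of the disengagement analysis window, measured
#'   from distractor onset (ms).
#' @param frame_ms Video frame duration used by the 8-month manual coding.
#' @return An object of class `protocol_spec`.
#' @examples
#' spec <- protocol_spec()
#' spec$trials_per_condition * length(spec$conditions)  # 24 trials
#' @export
protocol_spec <- function(conditions = c("happy", "fearful",
                                         "neutral_open", "neutral_closed"),
                          trials_per_condition = 6,
                          central_solo_ms = 1000,
                          overlap_ms = 3000,
                          face_size_deg = c(width = 15.8, height = 11.4),
                          distractor_size_deg = c(width = 15.8, height = 4.0),
                          face_distractor_separation_deg = 13.6,
                          max_emotion_run = 4,
                          max_side_run = 3,
                          anticipatory_ms = c(infant8 = 160, toddler24 = 150),
                          window_end_ms = 1000,
                          frame_ms = 40) {
  check_that(is.character(conditions) && length(conditions) >= 1 &&
               !anyDuplicated(conditions),
             "`conditions` must be distinct labels")
  check_that(is_count(trials_per_condition) && trials_per_condition >= 1,
             "`trials_per_condition` must be a positive count")
  check_that(all(anticipatory_ms > 0) && all(anticipatory_ms < window_end_ms),
             "anticipatory thresholds must lie in (0, window_end_ms)")
  check_that(window_end_ms <= overlap_ms,
             "`window_end_ms` cannot exceed `overlap_ms`")
  check_that(all(c(face_size_deg, distractor_size_deg) > 0) &&
               face_distractor_separation_deg >= 0,
             "geometric extents must be strictly positive")
  spec <- list(
    conditions = conditions,
    trials_per_condition = as.integer(trials_per_condition),
    central_solo_ms = central_solo_ms,
    overlap_ms = overlap_ms,
    face_size_deg = face_size_deg,
    distractor_size_deg = distractor_size_deg,
    face_distractor_separation_deg = face_distractor_separation_deg,
    max_emotion_run = as.integer(max_emotion_run),
    max_side_run = as.integer(max_side_run),
    anticipatory_ms = anticipatory_ms,
    window_end_ms = window_end_ms,
    frame_ms = frame_ms
  )
  structure(spec, class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Overlap-task protocol:",
      length(x$conditions), "conditions x", x$trials_per_condition,
      "trials =", length(x$conditions) * x$trials_per_condition, "trials\n")
  cat("  central solo", x$central_solo_ms, "ms; overlap", x$overlap_ms,
      "ms; analysis window", x$window_end_ms, "ms\n")
  invisible(x)
}

n_trials <- function(spec) length(spec$conditions) * spec$trials_per_condition

# linear scan: does a schedule satisfy both run-length constraints?
schedule_satisfies <- function(condition, side, spec) {
  max_run_length(condition) <= spec$max_emotion_run &&
    max_run_length(side) <= spec$max_side_run
}

#' Generate a constrained random trial order
#'
#' Random permutation of the balanced condition multiset (6 of each face)
#' and of a balanced left/right side assignment, resampled until no
#' condition repeats more than `max_emotion_run` times in a row and no side
#' more than `max_side_run` times in a row. The two sequences are sampled
#' independently since the constraints do not interact. After a bounded
#' number of rejections a deterministic interleaved order is used as repair;
#' if even that violates the constraints the spec is infeasible.
#'
#' @param spec A [protocol_spec()].
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @param max_retries Rejection-sampling cap before deterministic repair.
#' @return A tibble with columns `trial_index` (0-based), `condition`,
#'   `distractor_side`.
#' @examples
#' sched <- generate_schedule(protocol_spec(), seed = 1)
#' table(sched$condition)
#' @export
generate_schedule <- function(spec, seed, max_retries = 10000) {
  stopifnot(inherits(spec, "protocol_spec"))
  n <- n_trials(spec)
  base_cond <- rep(spec$conditions, each = spec$trials_per_condition)
  n_left <- n %/% 2L
  base_side <- c(rep("left", n_left), rep("right", n - n_left))

  sample_until <- function(base, max_run) {
    for (i in seq_len(max_retries)) {
      cand <- sample(base)
      if (max_run_length(cand) <= max_run) return(cand)
    }
    NULL
  }

  out <- with_seed(seed, {
    cond <- sample_until(base_cond, spec$max_emotion_run)
    side <- sample_until(base_side, spec$max_side_run)
    list(cond = cond, side = side)
  })

  # deterministic repair: canonical interleaving has the shortest runs the
  # multiset allows
  interleave <- function(labels, times) {
    as.vector(t(matrix(rep(labels, times), nrow = length(labels))))
  }
  if (is.null(out$cond)) out$cond <- interleave(spec$conditions, spec$trials_per_condition)
  if (is.null(out$side)) out$side <- rep(c("left", "right"), length.out = n)

  if (!schedule_satisfies(out$cond, out$side, spec)) {
    stop("infeasible protocol spec: run-length constraints cannot be met ",
         "with ", spec$trials_per_condition, " trials per condition",
         call. = FALSE)
  }
  tibble::tibble(
    trial_index = seq_len(n) - 1L,
    condition = out$cond,
    distractor_side = out$side
  )
}

#' Write / read a trial schedule
#'
#' Tab-delimited with columns `trial_index`, `condition`, `distractor_side`.
#'
#' @param schedule Tibble as returned by [generate_schedule()].
#' @param path File path.
#' @return `read_schedule` returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  write_tsv_file(schedule[, c("trial_index", "condition", "distractor_side")], path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read_tsv_file(path)
  check_that(all(c("trial_index", "condition", "distractor_side") %in% names(df)),
             "schedule file must have columns trial_index, condition, distractor_side")
  tibble::as_tibble(df)
}

#' Build the areas of interest for scoring
#'
#' The central AOI is the face rectangle centered at the origin; the lateral
#' AOIs are the distractor rectangles, mirror images about the vertical
#' midline. The printed face-distractor distance is interpreted as the
#' nearest-edge separation by default; `separation = "center"` switches to a
#' center-to-center reading.
#'
#' AOI membership uses closed rectangles: a gaze sample exactly on an edge
#' counts as inside.
#'
#' @param spec A [protocol_spec()].
#' @param separation Either `"edge"` (nearest-edge, default) or `"center"`.
#' @return An object of class `aoi_set`: list with `central`,
#'   `distractor_left`, `distractor_right`, each `c(xmin, xmax, ymin, ymax)`.
#' @examples
#' aois <- build_aois(protocol_spec())
#' aois$central          # x in [-7.9, 7.9]
#' aois$distractor_right # nearest edge at 7.9 + 13.6 = 21.5
#' @export
build_aois <- function(spec, separation = c("edge", "center")) {
  stopifnot(inherits(spec, "protocol_spec"))
  separation <- match.arg(separation)
  fw <- spec$face_size_deg[["width"]] / 2
  fh <- spec$face_size_deg[["height"]] / 2
  dw <- spec$distractor_size_deg[["width"]] / 2
  dh <- spec$distractor_size_deg[["height"]] / 2
  sep <- spec$face_distractor_separation_deg
  central <- c(xmin = -fw, xmax = fw, ymin = -fh, ymax = fh)
  if (separation == "edge") {
    x_inner <- fw + sep       # nearest edge of the distractor
    x_outer <- x_inner + 2 * dw
  } else {
    x_inner <- sep - dw       # center-to-center
    x_outer <- sep + dw
  }
  right <- c(xmin = x_inner, xmax = x_outer, ymin = -dh, ymax = dh)
  left <- c(xmin = -x_outer, xmax = -x_inner, ymin = -dh, ymax = dh)
  structure(list(central = central,
                 distractor_left = left,
                 distractor_right = right),
            class = "aoi_set")
}

#' Classify gaze points against a rectangle
#'
#' Closed-rectangle membership: boundary points are inside.
#'
#' @param x,y Numeric vectors of gaze coordinates (degrees).
#' @param rect Length-4 named vector `c(xmin, xmax, ymin, ymax)`.
#' @return Logical vector.
#' @export
in_rect <- function(x, y, rect) {
  x >= rect[["xmin"]] & x <= rect[["xmax"]] &
    y >= rect[["ymin"]] & y <= rect[["ymax"]]
}
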