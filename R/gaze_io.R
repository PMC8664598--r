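#' Read and write raw gaze logs
#'
#' Gaze logs are tab-delimited UTF-8 text with a `.` decimal separator and
#' header columns `t_ms`, `x_deg`, `y_deg`, `valid`. `t_ms` is session time
#' in milliseconds and must be monotone nondecreasing; `valid` is 0/1 and
#' coordinates of invalid samples are ignored by all downstream code.
#' Values are written at fixed precision (3 decimals) so a write/read cycle
#' reproduces them exactly.
#'
#' @param path File path.
#' @return `read_gaze_log` returns a tibble with columns `t_ms`, `x_deg`,
#'   `y_deg`, `valid` (logical).
#' @export
read_gaze_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  check_that(length(lines) >= 1, "gaze log is empty (missing header)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  check_that(identical(header, c("t_ms", "x_deg", "y_deg", "valid")),
             "gaze log header must be: t_ms, x_deg, y_deg, valid")
  body <- lines[-1]
  if (length(body) == 0L) {
    return(tibble::tibble(t_ms = numeric(), x_deg = numeric(),
                          y_deg = numeric(), valid = logical()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0L) {
    stop("malformed gaze log row at line ", bad[1] + 1L,
         " (expected 4 tab-separated fields)", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 1:3, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 3L)
  bad_num <- which(apply(is.na(num), 1, any) | !(m[, 4] %in% c("0", "1")))
  if (length(bad_num) > 0L) {
    stop("malformed gaze log row at line ", bad_num[1] + 1L,
         " (non-numeric value or valid flag not 0/1)", call. = FALSE)
  }
  t_ms <- num[, 1]
  if (is.unsorted(t_ms)) {
    stop("gaze log timestamps are not monotone nondecreasing", call. = FALSE)
  }
  tibble::tibble(t_ms = t_ms, x_deg = num[, 2], y_deg = num[, 3],
                 valid = m[, 4] == "1")
}

#' @rdname read_gaze_log
#' @param samples Tibble with columns `t_ms`, `x_deg`, `y_deg`, `valid`.
#' @export
write_gaze_log <- function(samples, path) {
  check_that(all(c("t_ms", "x_deg", "y_deg", "valid") %in% names(samples)),
             "`samples` must have columns t_ms, x_deg, y_deg, valid")
  check_that(!is.unsorted(samples$t_ms),
             "gaze sample timestamps must be monotone nondecreasing")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("t_ms\tx_deg\ty_deg\tvalid", con)
  if (nrow(samples) > 0L) {
    writeLines(paste(sprintf("%.3f", samples$t_ms),
                     sprintf("%.3f", samples$x_deg),
                     sprintf("%.3f", samples$y_deg),
                     as.integer(samples$valid), sep = "\t"), con)
  }
  invisible(path)
}

#' Read and write per-trial event logs
#'
#' Event logs carry one row per trial: `trial_index`, `condition`,
#' `central_onset_ms`, `distractor_onset_ms`, `distractor_side`. The
#' distractor onset must trail the central onset by the protocol's
#' central-solo duration (within one sample period).
#'
#' @param path File path.
#' @return A tibble of event records sorted by `trial_index`.
#' @export
read_event_log <- function(path) {
  df <- read_tsv_file(path)
  needed <- c("trial_index", "condition", "central_onset_ms",
              "distractor_onset_ms", "distractor_side")
  check_that(all(needed %in% names(df)),
             paste("event log must have columns:", paste(needed, collapse = ", ")))
  df <- df[order(df$trial_index), ]
  tibble::as_tibble(df)
}

#' @rdname read_event_log
#' @param events Tibble of event records.
#' @export
write_event_log <- function(events, path) {
  needed <- c("trial_index", "condition", "central_onset_ms",
              "distractor_onset_ms", "distractor_side")
  check_that(all(needed %in% names(events)), "event log columns missing")
  write_tsv_file(events[, needed], path)
}

#' Segment a continuous gaze stream into per-trial records
#'
#' Each trial covers `[central_onset_ms, distractor_onset_ms +
#' window_end_ms]`, with both edges closed (the analysis window's last
#' measured time point at 1000 ms after distractor onset belongs to the
#' trial). Trials whose window contains no samples are retained but flagged
#' empty, so downstream scoring can reject them explicitly.
#'
#' @param samples Gaze-sample tibble (see [read_gaze_log()]).
#' @param events Event tibble (see [read_event_log()]).
#' @param spec A [protocol_spec()] supplying `window_end_ms`.
#' @param sampling_rate_hz Nominal sampling rate recorded on each trial.
#' @return A list of `trial_record` objects: `event` (one-row tibble),
#'   `samples`, `empty`, `sampling_rate_hz`.
#' @export
segment_trials <- function(samples, events, spec, sampling_rate_hz = 300) {
  stopifnot(inherits(spec, "protocol_spec"))
  events <- events[order(events$trial_index), ]
  starts <- events$central_onset_ms
  ends <- events$distractor_onset_ms + spec$window_end_ms
  if (nrow(events) > 1L &&
      any(starts[-1] < ends[-length(ends)])) {
    stop("overlapping trial intervals in event log", call. = FALSE)
  }
  lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    sel <- samples$t_ms >= starts[i] & samples$t_ms <= ends[i]
    trial_samples <- samples[sel, , drop = FALSE]
    structure(list(event = ev,
                   samples = trial_samples,
                   empty = nrow(trial_samples) == 0L,
                   sampling_rate_hz = sampling_rate_hz),
              class = "trial_record")
  })
}
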