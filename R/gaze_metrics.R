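## Per-trial eye-tracking indicators from a labelled gaze-sample stream.
##
## A gaze stream is a data.frame with one row per eye-tracker sample:
##   time_ms  - milliseconds from trial start, non-decreasing
##   event    - one of "fixation", "saccade", "blink", "other"
##   pupil_mm - pupil diameter in mm; NA during blinks
##   aoi      - area of interest: "lane", "left", "right" or "none"
##
## Duration attribution rule (pinned by tests): each sample owns the interval
## up to the next sample; the last sample owns the median inter-sample gap.

GAZE_EVENTS <- c("fixation", "saccade", "blink", "other")
GAZE_AOIS <- c("lane", "left", "right", "none")

validate_gaze_stream <- function(stream) {
  if (!is.data.frame(stream) || nrow(stream) == 0L) {
    stop("gaze stream must be a non-empty data.frame", call. = FALSE)
  }
  need <- c("time_ms", "event", "pupil_mm", "aoi")
  miss <- setdiff(need, names(stream))
  if (length(miss)) {
    stop("gaze stream is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(stream$time_ms)) {
    stop("time_ms must be non-decreasing within a stream", call. = FALSE)
  }
  if (!all(stream$event %in% GAZE_EVENTS)) {
    stop("event labels must be one of: ", paste(GAZE_EVENTS, collapse = ", "), call. = FALSE)
  }
  if (!all(stream$aoi %in% GAZE_AOIS)) {
    stop("aoi labels must be one of: ", paste(GAZE_AOIS, collapse = ", "), call. = FALSE)
  }
  ok <- is.na(stream$pupil_mm) | stream$pupil_mm > 0
  if (!all(ok)) stop("pupil_mm must be positive when present", call. = FALSE)
  invisible(stream)
}

## Per-sample durations in ms under the attribution rule above.
sample_durations <- function(time_ms) {
  n <- length(time_ms)
  if (n < 2L) {
    stop("need at least two samples to attribute durations", call. = FALSE)
  }
  gaps <- diff(time_ms)
  c(gaps, stats::median(gaps))
}

#' Pupil diameter coefficient of variation
#'
#' The ratio of the standard deviation of pupil diameter to its mean, a
#' standard proxy for cognitive workload: larger relative pupil variability
#' indicates more effortful attention regulation.
#'
#' @param pupil_values numeric vector of pupil diameters in mm; `NA`s (blink
#'   samples) are dropped.
#' @param sd_denominator `"n"` (population standard deviation, the default used
#'   throughout the package) or `"n-1"` (sample standard deviation).
#' @return the coefficient of variation, `sd / mean`.
#' @examples
#' pupil_cv(c(4, 4, 4))        # 0: no variability
#' pupil_cv(rnorm(100, 4, .2)) # about 0.05
#' @export
pupil_cv <- function(pupil_values, sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  x <- pupil_values[!is.na(pupil_values)]
  if (length(x) < 2L) stop("need at least two pupil observations", call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("mean pupil diameter must be positive", call. = FALSE)
  s <- stats::sd(x)
  if (sd_denominator == "n") s <- s * sqrt((length(x) - 1) / length(x))
  s / m
}

#' Share of fixation time spent on the driving lane
#'
#' The proportion of total fixation duration whose area of interest is the
#' driving lane, out of all fixation time (including fixations on "none").
#'
#' @param stream a gaze stream data.frame (see [compute_trial_metrics()]).
#' @return a proportion in `[0, 1]`.
#' @export
lane_fixation_share <- function(stream) {
  validate_gaze_stream(stream)
  d <- sample_durations(stream$time_ms)
  fix <- stream$event == "fixation"
  tot <- sum(d[fix])
  if (tot <= 0) stop("no fixation time in stream: lane share undefined", call. = FALSE)
  sum(d[fix & stream$aoi == "lane"]) / tot
}

#' Compute the per-trial eye-tracking indicator vector
#'
#' Aggregates a labelled gaze-sample stream into the trial-level indicators
#' used for attention scoring: event-time percentages, blink rate, mean event
#' durations, pupil diameter statistics, the lane fixation share and the pupil
#' diameter coefficient of variation.
#'
#' Time percentages are event-labelled duration over total duration. Event
#' counts and mean durations are computed over contiguous runs of the same
#' event label. Pupil statistics use only samples where the diameter is
#' present (i.e. excluding blinks); the standard deviation uses the population
#' (`n`) denominator by default.
#'
#' @param stream a gaze stream data.frame with columns `time_ms`, `event`,
#'   `pupil_mm`, `aoi`.
#' @param sd_denominator passed to [pupil_cv()]; also used for `pupil_sd_mm`.
#' @return a one-row data.frame with columns `fix_time_pct`, `sacc_time_pct`,
#'   `blink_per_min`, `avg_fixation_ms`, `avg_saccade_ms`, `avg_blink_ms`,
#'   `pupil_mean_mm`, `pupil_sd_mm`, `pupil_max_mm`, `pupil_min_mm`,
#'   `lane_fix_share`, `pupil_cv`. Percentages are proportions in `[0, 1]`.
#' @export
compute_trial_metrics <- function(stream, sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  validate_gaze_stream(stream)
  d <- sample_durations(stream$time_ms)
  total <- sum(d)
  if (total <= 0) stop("stream has zero total duration", call. = FALSE)

  ev_time <- function(ev) sum(d[stream$event == ev])
  runs <- rle(stream$event)
  run_count <- function(ev) sum(runs$values == ev)
  avg_run_ms <- function(ev) {
    k <- run_count(ev)
    if (k == 0L) NA_real_ else ev_time(ev) / k
  }

  pupil <- stream$pupil_mm[!is.na(stream$pupil_mm)]
  if (length(pupil) == 0L) {
    warning("all-blink stream: pupil statistics flagged missing", call. = FALSE)
    p_mean <- p_sd <- p_max <- p_min <- p_cv <- NA_real_
  } else {
    p_mean <- mean(pupil)
    p_max <- max(pupil)
    p_min <- min(pupil)
    if (length(pupil) >= 2L) {
      p_sd <- stats::sd(pupil)
      if (sd_denominator == "n") {
        p_sd <- p_sd * sqrt((length(pupil) - 1) / length(pupil))
      }
      p_cv <- pupil_cv(stream$pupil_mm, sd_denominator)
    } else {
      warning("single pupil observation: variability flagged missing", call. = FALSE)
      p_sd <- p_cv <- NA_real_
    }
  }

  lane <- tryCatch(lane_fixation_share(stream), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NA_real_
  })

  data.frame(
    fix_time_pct = ev_time("fixation") / total,
    sacc_time_pct = ev_time("saccade") / total,
    blink_per_min = run_count("blink") / (total / 60000),
    avg_fixation_ms = avg_run_ms("fixation"),
    avg_saccade_ms = avg_run_ms("saccade"),
    avg_blink_ms = avg_run_ms("blink"),
    pupil_mean_mm = p_mean,
    pupil_sd_mm = p_sd,
    pupil_max_mm = p_max,
    pupil_min_mm = p_min,
    lane_fix_share = lane,
    pupil_cv = p_cv
  )
}

#' Read / write gaze streams as CSV
#'
#' Columns: `time_ms`, `event`, `pupil_mm`, `aoi`; comma-separated, UTF-8,
#' header row, `.` decimal.
#'
#' @param path file path.
#' @param stream gaze stream data.frame.
#' @return `read_gaze_stream()` returns a validated gaze stream.
#' @export
read_gaze_stream <- function(path) {
  stream <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_gaze_stream(stream)
  stream
}

#' @rdname read_gaze_stream
#' @export
write_gaze_stream <- function(stream, path) {
  validate_gaze_stream(stream)
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}
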