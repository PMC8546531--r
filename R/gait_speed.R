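# From step events to gait speed: stride model, walking-bout segmentation,
# bout-level speed.
#
# Speed model: step length is a sex-specific constant times body height
# (pedometry convention: 0.415 for men, 0.413 for women).  Each quantized
# step interval yields an instantaneous speed step_length / interval; a
# bout's speed is the arithmetic mean of its instantaneous speeds.

#' Step length from the sex-constant-times-height model
#'
#' @param height body height in meters, within \[1.0, 2.5\].
#' @param sex `"male"` or `"female"`.
#' @param k_male,k_female sex-specific multipliers; defaults 0.415 and 0.413,
#'   the pedometry convention for distance covered per step.
#' @return Step length in meters.
#' @examples
#' step_length(1.70, "male")   # 0.7055
#' step_length(1.60, "female") # 0.6608
#' @export
step_length <- function(height, sex, k_male = 0.415, k_female = 0.413) {
  check_height(height)
  check_sex(sex)
  check_number(k_male, "k_male", positive = TRUE)
  check_number(k_female, "k_female", positive = TRUE)
  if (sex == "male") k_male * height else k_female * height
}

#' Segment step events into walking bouts
#'
#' A walking bout is a maximal run of consecutive steps in which every
#' inter-step gap is at most `max_gap` seconds; runs with fewer than
#' `min_steps` steps are discarded.  One bout yields one gait speed
#' measurement.
#'
#' @param steps a [step_series()] or numeric vector of strictly increasing
#'   step times (seconds).
#' @param max_gap largest within-bout inter-step gap, seconds (default 2.5 s).
#' @param min_steps minimum steps per bout (default 8, about 4 s of walking;
#'   excludes shuffles and isolated steps).
#' @return A list of `walking_bout` objects (possibly empty), ordered in time,
#'   non-overlapping.  Each bout has `participant_id`, `start_time`,
#'   `end_time`, `step_times` (seconds since the recording start) and
#'   `n_steps`.
#' @export
segment_bouts <- function(steps, max_gap = 2.5, min_steps = 8) {
  check_number(max_gap, "max_gap", positive = TRUE)
  check_number(min_steps, "min_steps")
  if (min_steps < 2) stop_gait("`min_steps` must be >= 2", "parameter_error")
  if (inherits(steps, "step_series")) {
    times <- steps$step_times
    pid <- steps$participant_id
    origin <- steps$recording_start
  } else {
    times <- as.numeric(steps)
    pid <- "unknown"
    origin <- parse_time("2000-01-03T00:00:00")
  }
  if (length(times) == 0L) return(list())
  if (any(diff(times) <= 0))
    stop_gait("step times must be strictly increasing", "validation_error")

  run_id <- cumsum(c(1, as.integer(diff(times) > max_gap)))
  runs <- split(times, run_id)
  runs <- runs[lengths(runs) >= min_steps]
  unname(lapply(runs, function(ts) {
    structure(list(participant_id = pid,
                   start_time = origin + ts[1],
                   end_time = origin + ts[length(ts)],
                   step_times = ts,
                   n_steps = length(ts)),
              class = "walking_bout")
  }))
}

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf("<walking_bout> participant %s: %d steps, %.2f s at %s\n",
              x$participant_id, x$n_steps,
              x$step_times[x$n_steps] - x$step_times[1],
              format_time(x$start_time)))
  invisible(x)
}

#' Bout-level gait speed
#'
#' Instantaneous speed over each quantized step interval is
#' `step_length / interval`; the bout's speed is the arithmetic mean of these.
#' Duration is last minus first step time; the measurement timestamp is the
#' bout start.
#'
#' @param bout a `walking_bout` from [segment_bouts()] (at least 2 steps).
#' @param step_length step length in meters, from [step_length()].
#' @return A one-row measurements data frame: `participant_id`, `timestamp`,
#'   `speed` (m/s), `duration` (s), `n_steps`, `hour_of_day`, `day_of_week`,
#'   `is_weekend`.
#' @export
bout_speed <- function(bout, step_length) {
  if (!inherits(bout, "walking_bout"))
    stop_gait("`bout` must be a walking_bout", "parameter_error")
  check_number(step_length, "step_length", positive = TRUE)
  if (bout$n_steps < 2L)
    stop_gait("a bout needs at least 2 steps to have a speed",
              "insufficient_steps_error")
  intervals <- step_intervals(bout$step_times)
  new_measurements(
    participant_id = bout$participant_id,
    timestamp = bout$start_time,
    speed = mean(step_length / intervals),
    duration = bout$step_times[bout$n_steps] - bout$step_times[1],
    n_steps = bout$n_steps)
}

#' Full step-series-to-measurements pipeline
#'
#' Segments a step series into walking bouts and computes one gait speed
#' measurement per bout.
#'
#' @inheritParams segment_bouts
#' @param height,sex participant anthropometrics for [step_length()].
#' @param ... passed on to [step_length()] (constant overrides).
#' @return A measurements data frame, one row per bout (zero rows when no run
#'   of steps survives the bout filter).
#' @export
measure_gait_speed <- function(steps, height, sex, max_gap = 2.5, min_steps = 8,
                               ...) {
  len <- step_length(height, sex, ...)
  bouts <- segment_bouts(steps, max_gap = max_gap, min_steps = min_steps)
  if (length(bouts) == 0L)
    return(new_measurements(character(0),
                            parse_time(character(0)),
                            numeric(0), numeric(0), integer(0)))
  do.call(rbind, lapply(bouts, bout_speed, step_length = len))
}
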