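# Readers/writers for the package's CSV dialects, plus the core record types.
#
# All timestamps are timezone-naive local clock time.  Internally they are
# stored as POSIXct pinned to UTC so that arithmetic never crosses DST
# boundaries; day-of-week and hour-of-day therefore always reflect the local
# clock the device recorded under.

GAIT_TZ <- "UTC"
TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

parse_time <- function(x, name = "start_time") {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = GAIT_TZ))
  out <- as.POSIXct(x, format = TIME_FMT, tz = GAIT_TZ)
  if (anyNA(out))
    stop_gait(sprintf("`%s` is not an ISO-8601 date-time (YYYY-MM-DDTHH:MM:SS): \"%s\"",
                      name, paste(x[is.na(out)][1])), "parse_error")
  out
}

format_time <- function(x) format(x, format = TIME_FMT, tz = GAIT_TZ)

# Monday = 1 ... Sunday = 7.  Computed arithmetically from the epoch offset
# (valid because all times are pinned to UTC): 1970-01-01 was a Thursday.
day_of_week_index <- function(ts) {
  d <- floor(as.numeric(ts) / 86400)
  as.integer((d + 3) %% 7 + 1)
}

DOW_LABELS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

day_of_week_label <- function(ts) DOW_LABELS[day_of_week_index(ts)]

hour_of_day <- function(ts) as.integer(floor(as.numeric(ts) %% 86400 / 3600))

MEASUREMENT_COLUMNS <- c("participant_id", "timestamp", "speed", "duration",
                         "n_steps", "hour_of_day", "day_of_week", "is_weekend")

# accel_recording -------------------------------------------------------------

#' Construct a triaxial accelerometer recording
#'
#' A recording is a uniformly sampled triaxial acceleration series anchored to
#' a participant and a wall-clock start time.  Sample `i` (1-based) occurs at
#' `start_time + (i - 1) / sampling_rate`; recordings with gaps must be split
#' before construction.
#'
#' @param samples data frame with numeric columns `ax`, `ay`, `az`, in units
#'   of g.
#' @param sampling_rate samples per second; strictly positive.
#' @param start_time recording start, `POSIXct` or an ISO-8601 string
#'   (`YYYY-MM-DDTHH:MM:SS`), interpreted as timezone-naive local time.
#' @param participant_id opaque participant identifier.
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(samples, sampling_rate,
                            start_time = "2000-01-03T00:00:00",
                            participant_id = "unknown") {
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.data.frame(samples) || !all(c("ax", "ay", "az") %in% names(samples)))
    stop_gait("`samples` must be a data frame with columns ax, ay, az", "format_error")
  for (axis in c("ax", "ay", "az"))
    if (!is.numeric(samples[[axis]]))
      stop_gait(sprintf("acceleration column \"%s\" is not numeric", axis), "parse_error")
  structure(
    list(participant_id = as.character(participant_id),
         sampling_rate = sampling_rate,
         start_time = parse_time(start_time),
         samples = samples[c("ax", "ay", "az")]),
    class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<accel_recording> participant %s: %d samples @ %g Hz (%.2f s) from %s\n",
              x$participant_id, n, x$sampling_rate,
              if (n > 0) n / x$sampling_rate else 0, format_time(x$start_time)))
  invisible(x)
}

#' Number of samples and duration of a recording
#'
#' @param recording an [accel_recording()].
#' @return `n_samples()` the sample count; `recording_duration()` the covered
#'   time span in seconds, i.e. the time of the last sample,
#'   `(n - 1) / sampling_rate`.
#' @export
n_samples <- function(recording) nrow(recording$samples)

#' @rdname n_samples
#' @export
recording_duration <- function(recording)
  max(nrow(recording$samples) - 1L, 0L) / recording$sampling_rate

#' Read a triaxial accelerometer CSV
#'
#' Expects header columns `ax`, `ay`, `az` (a `t` column, if present, is
#' ignored: the sample clock is defined by `sampling_rate`).  Rows are kept in
#' file order; no row is ever silently dropped.
#'
#' @param path CSV file path.
#' @inheritParams accel_recording
#' @return An [accel_recording()].
#' @export
read_accelerometer_csv <- function(path, sampling_rate,
                                   start_time = "2000-01-03T00:00:00",
                                   participant_id = "unknown") {
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop_gait(sprintf("empty recording: \"%s\" has no sample rows", path),
              "empty_recording_error")
  for (axis in c("ax", "ay", "az")) {
    if (!axis %in% names(df))
      stop_gait(sprintf("missing acceleration column \"%s\" in \"%s\"", axis, path),
                "format_error")
    if (!is.numeric(df[[axis]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[axis]]))))[1]
      stop_gait(sprintf("non-numeric value in column \"%s\", row %d of \"%s\"",
                        axis, bad, path), "parse_error")
    }
  }
  accel_recording(df, sampling_rate, start_time, participant_id)
}

#' Write a recording back to the accelerometer CSV dialect
#'
#' @param recording an [accel_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accelerometer_csv <- function(recording, path) {
  df <- recording$samples
  df <- cbind(t = (seq_len(nrow(df)) - 1) / recording$sampling_rate, df)
  write.csv(format_full_precision(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 17 significant digits round-trips every double exactly through text.
format_full_precision <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col)
  df
}

# participant table -----------------------------------------------------------

PARTICIPANT_COLUMNS <- c("participant_id", "sex", "age", "height_m", "weight_kg",
                         "grip1_kg", "grip2_kg", "grip3_kg", "asm_kg",
                         "usual_gait_speed_ms", "hypertension", "diabetes",
                         "angina", "arthritis", "smoking")

#' Read and validate a participant table
#'
#' One row per participant with anthropometrics, three handgrip trials,
#' appendicular skeletal muscle mass (ASM, kg), laboratory usual gait speed,
#' comorbidity flags and smoking status.  Two derived columns are appended:
#' `grip_mean` (mean of the three trials, kg) and `asm_index`
#' (ASM / height^2, kg/m^2).  The ASM index is always recomputed from `asm_kg`
#' and `height_m`; an index column present in the file is ignored with a
#' warning so there is a single source of truth.
#'
#' @param path CSV with the columns listed under Details.
#' @details Required columns:
#'   `participant_id, sex, age, height_m, weight_kg, grip1_kg, grip2_kg,
#'   grip3_kg, asm_kg, usual_gait_speed_ms, hypertension, diabetes, angina,
#'   arthritis, smoking`.  `sex` must be `male`/`female`; `smoking` one of
#'   `current`, `ex`, `never`; heights must lie in \[1.0, 2.5\] m (a height of
#'   17 is rejected as centimetres entered as metres); strength, mass and
#'   speed values must be strictly positive where present.
#' @return A `data.frame` of validated profiles, class `participant_table`.
#' @export
read_participant_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PARTICIPANT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop_gait(paste0("participant table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")), "format_error")
  if (any(c("asm_index", "asmi") %in% names(df)))
    warning("file-supplied ASM index column ignored; recomputed from asm_kg and height_m")
  validate_participants(df)
}

validate_participants <- function(df) {
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    check_sex(row$sex)
    if (!is.finite(row$height_m) || row$height_m < 1.0 || row$height_m > 2.5)
      stop_gait(sprintf("participant %s: height %s m outside [1.0, 2.5]",
                        row$participant_id, format(row$height_m)), "validation_error")
    positive_fields <- c("weight_kg", "grip1_kg", "grip2_kg", "grip3_kg",
                         "asm_kg", "usual_gait_speed_ms")
    for (f in positive_fields) {
      v <- row[[f]]
      if (!is.na(v) && v <= 0)
        stop_gait(sprintf("participant %s: %s must be strictly positive (got %g)",
                          row$participant_id, f, v), "validation_error")
    }
    if (!row$smoking %in% c("current", "ex", "never"))
      stop_gait(sprintf("participant %s: unknown smoking status \"%s\"",
                        row$participant_id, row$smoking), "validation_error")
  }
  df$grip_mean <- rowMeans(df[c("grip1_kg", "grip2_kg", "grip3_kg")])
  df$asm_index <- df$asm_kg / df$height_m^2
  class(df) <- c("participant_table", "data.frame")
  df
}

#' Write a participant table
#'
#' Inverse of [read_participant_table()]; derived columns are not written.
#'
#' @param participants a `participant_table` or compatible data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_participant_table <- function(participants, path) {
  write.csv(format_full_precision(as.data.frame(participants)[PARTICIPANT_COLUMNS]),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# measurements ----------------------------------------------------------------

#' Write gait speed measurements to CSV
#'
#' One row per walking bout: `participant_id`, ISO-8601 local `timestamp`,
#' `speed_ms` (printed to 3 decimals), `duration_s`, `n_steps`,
#' `day_of_week` (Mon..Sun) and `hour_of_day` (0-23).  An empty measurement
#' set yields a header-only file.
#'
#' @param measurements a measurements data frame as produced by
#'   [measure_gait_speed()] or [simulate_participant_days()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  out <- data.frame(
    participant_id = character(0), timestamp = character(0),
    speed_ms = character(0), duration_s = numeric(0), n_steps = integer(0),
    day_of_week = character(0), hour_of_day = integer(0))
  if (nrow(measurements) > 0) {
    out <- data.frame(
      participant_id = measurements$participant_id,
      timestamp = format_time(measurements$timestamp),
      speed_ms = sprintf("%.3f", measurements$speed),
      duration_s = measurements$duration,
      n_steps = measurements$n_steps,
      day_of_week = measurements$day_of_week,
      hour_of_day = measurements$hour_of_day)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gait speed measurements written by [write_measurements_csv()]
#'
#' @param path CSV file path.
#' @return A measurements data frame with the standard columns (speeds carry
#'   the file's 3-decimal precision).
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character"))
  needed <- c("participant_id", "timestamp", "speed_ms", "duration_s", "n_steps")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop_gait(paste0("measurements file is missing column(s): ",
                     paste(missing_cols, collapse = ", ")), "format_error")
  ts <- parse_time(df$timestamp, "timestamp")
  new_measurements(df$participant_id, ts, as.numeric(df$speed_ms),
                   df$duration_s, df$n_steps)
}

# Canonical constructor: calendar context is always derived from the timestamp.
new_measurements <- function(participant_id, timestamp, speed, duration, n_steps) {
  dow <- day_of_week_index(timestamp)
  data.frame(
    participant_id = rep_len(as.character(participant_id), length(speed)),
    timestamp = timestamp,
    speed = speed,
    duration = duration,
    n_steps = as.integer(n_steps),
    hour_of_day = hour_of_day(timestamp),
    day_of_week = DOW_LABELS[dow],
    is_weekend = dow >= 6L,
    stringsAsFactors = FALSE)
}

# Fast row-bind for measurement frames (plain column concatenation; avoids
# data-frame rbind dispatch, which dominates runtime for large cohorts).
bind_measurements <- function(frames) {
  frames <- frames[vapply(frames, nrow, integer(1)) > 0]
  if (length(frames) == 0L)
    return(new_measurements(character(0), parse_time(character(0)),
                            numeric(0), numeric(0), integer(0)))
  out <- lapply(MEASUREMENT_COLUMNS, function(col)
    unlist(lapply(frames, `[[`, col), use.names = FALSE))
  names(out) <- MEASUREMENT_COLUMNS
  out$timestamp <- as.POSIXct(out$timestamp, origin = "1970-01-01", tz = GAIT_TZ)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

check_measurements <- function(measurements, single_participant = FALSE) {
  if (!is.data.frame(measurements) ||
      !all(MEASUREMENT_COLUMNS %in% names(measurements)))
    stop_gait("`measurements` must be a data frame with the standard measurement columns",
              "input_error")
  if (single_participant && nrow(measurements) > 0 &&
      length(unique(measurements$participant_id)) > 1L)
    stop_gait("measurements mix several participants; split by participant_id first",
              "input_error")
  invisible(measurements)
}

# step series CSV (CLI surface) ----------------------------------------------

#' Read/write detected step times
#'
#' Steps CSV dialect: columns `participant_id`, `step_time_s` (seconds since
#' the recording start).
#'
#' @param steps a [step_series()].
#' @param path file path.
#' @return `write_steps_csv()` returns `path` invisibly; `read_steps_csv()` a
#'   [step_series()] (`recording_start` must be supplied out of band).
#' @export
write_steps_csv <- function(steps, path) {
  write.csv(data.frame(participant_id = steps$participant_id,
                       step_time_s = steps$step_times),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_steps_csv
#' @param recording_start wall-clock time of `step_time_s == 0`.
#' @export
read_steps_csv <- function(path, recording_start = "2000-01-03T00:00:00") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "step_time_s") %in% names(df)))
    stop_gait("steps file must have columns participant_id, step_time_s", "format_error")
  pid <- if (nrow(df) > 0) df$participant_id[1] else "unknown"
  step_series(df$step_time_s, recording_start = recording_start,
              participant_id = pid)
}
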