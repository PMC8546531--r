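# Step detection: gravity-removed acceleration magnitude -> peak picking ->
# step event times -> step intervals on the 0.1-s grid.
#
# Each heel strike produces a burst of acceleration; on the magnitude signal a
# step is a local maximum that (a) stands out by at least `min_prominence` g
# over its surroundings and (b) is at least `min_peak_separation` s away from
# any higher accepted peak.  The magnitude is orientation-independent, which
# matters for a belt-worn device whose exact orientation is stable but unknown.

#' Step detection configuration
#'
#' @param smoothing_window width of the centred moving-average smoother in
#'   seconds; `0` disables smoothing.  Default 0.15 s, short enough to keep
#'   individual heel-strike peaks apart at fast cadence.
#' @param min_peak_separation minimum time between two detected steps, in
#'   seconds.  Default 0.25 s, a cadence ceiling of 4 steps/s covering fast
#'   walking.
#' @param min_prominence minimum peak prominence in g.  Default 0.05 g,
#'   below typical walking peaks (~0.2-1 g) but above sensor noise.
#' @param band optional `c(low, high)` band-pass corner frequencies in Hz
#'   (2nd-order Butterworth, forward-backward filtered); `NULL` (default)
#'   disables it.  Human cadence lives in roughly 0.5-3 Hz.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(smoothing_window = 0.15,
                             min_peak_separation = 0.25,
                             min_prominence = 0.05,
                             band = NULL) {
  check_number(smoothing_window, "smoothing_window")
  if (smoothing_window < 0)
    stop_gait("`smoothing_window` must be >= 0", "parameter_error")
  check_number(min_peak_separation, "min_peak_separation", positive = TRUE)
  check_number(min_prominence, "min_prominence")
  if (!is.null(band)) {
    if (!is.numeric(band) || length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
      stop_gait("`band` must be c(low, high) with 0 < low < high", "parameter_error")
  }
  structure(list(smoothing_window = smoothing_window,
                 min_peak_separation = min_peak_separation,
                 min_prominence = min_prominence,
                 band = band),
            class = "detection_config")
}

#' Detected step event times
#'
#' @param step_times strictly increasing step times, seconds since
#'   `recording_start`.
#' @param recording_start wall-clock anchor of time zero.
#' @param participant_id participant identifier.
#' @return An object of class `step_series`.
#' @export
step_series <- function(step_times, recording_start = "2000-01-03T00:00:00",
                        participant_id = "unknown") {
  step_times <- as.numeric(step_times)
  if (length(step_times) > 1 && any(diff(step_times) <= 0))
    stop_gait("step times must be strictly increasing", "validation_error")
  if (length(step_times) > 0 && any(step_times < 0))
    stop_gait("step times must be >= 0", "validation_error")
  structure(list(participant_id = as.character(participant_id),
                 step_times = step_times,
                 recording_start = parse_time(recording_start)),
            class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("<step_series> participant %s: %d steps", x$participant_id,
              length(x$step_times)))
  if (length(x$step_times) > 0)
    cat(sprintf(" over %.2f s from %s", diff(range(x$step_times)),
                format_time(x$recording_start)))
  cat("\n")
  invisible(x)
}

#' Gravity-removed acceleration magnitude
#'
#' Per-sample Euclidean magnitude `sqrt(ax^2 + ay^2 + az^2)` minus the series
#' median.  Subtracting the median removes the static 1-g gravity component
#' (and any constant sensor offset) without assuming which axis is vertical.
#'
#' @param recording an [accel_recording()] with at least one sample.
#' @return Numeric vector, one value per sample, in g.
#' @export
acceleration_magnitude <- function(recording) {
  if (!inherits(recording, "accel_recording"))
    stop_gait("`recording` must be an accel_recording", "parameter_error")
  s <- recording$samples
  if (nrow(s) == 0L)
    stop_gait("empty recording: no samples to compute a magnitude from",
              "empty_input_error")
  mag <- sqrt(s$ax^2 + s$ay^2 + s$az^2)
  mag - median(mag)
}

# centred moving average; edges use shrinking one-sided windows so no sample
# is dropped and a symmetric peak stays in place.
smooth_signal <- function(x, window_samples) {
  k <- as.integer(window_samples)
  if (k < 2L) return(x)
  if (k %% 2L == 0L) k <- k + 1L               # force symmetry
  half <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima with plateau handling: a run of equal values is one candidate
# peak, represented by its first sample (earlier tie-break).  Signal ends are
# never peaks.  Returns 1-based indices.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  inner <- 2:(k - 1L)
  is_peak <- r$values[inner] > r$values[inner - 1L] &
    r$values[inner] > r$values[inner + 1L]
  starts[inner][is_peak]
}

# Topographic prominence of peak at index p: height minus the higher of the
# two key saddles (the minimum between the peak and the nearest strictly
# higher ground on each side; the signal end counts as a base).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- min(left[seq.int(from = if (length(higher_l)) max(higher_l) else 1L,
                             to = p - 1L)])
    right <- x[seq.int(p + 1L, length(x))]
    higher_r <- which(right > h)
    rmin <- min(right[seq.int(1L, if (length(higher_r)) min(higher_r) else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
}

# Enforce minimum separation: accept peaks from highest to lowest (ties ->
# earlier), dropping any candidate closer than min_sep samples to an already
# accepted peak.
enforce_separation <- function(x, peaks, min_sep_samples) {
  if (length(peaks) <= 1L) return(peaks)
  ord <- peaks[order(-x[peaks], peaks)]
  accepted <- integer(0)
  for (p in ord) {
    if (!any(abs(accepted - p) < min_sep_samples)) accepted <- c(accepted, p)
  }
  sort(accepted)
}

#' Detect steps in an acceleration signal
#'
#' Finds local maxima of the (optionally band-passed and smoothed) signal with
#' prominence at least `min_prominence` and pairwise separation at least
#' `min_peak_separation`; when two candidate peaks are closer than the
#' separation the higher one is kept (ties keep the earlier).  Step times are
#' `(<sample index> - 1) / sampling_rate`.
#'
#' @param signal numeric vector (typically [acceleration_magnitude()] output),
#'   or an [accel_recording()] from which the magnitude is computed.
#' @param sampling_rate samples per second (taken from the recording when one
#'   is given).
#' @param config a [detection_config()].
#' @param recording_start wall-clock anchor for the returned series (ignored
#'   when `signal` is a recording).
#' @param participant_id identifier for the returned series (ignored when
#'   `signal` is a recording).
#' @return A [step_series()].
#' @export
detect_steps <- function(signal, sampling_rate = NULL,
                         config = detection_config(),
                         recording_start = "2000-01-03T00:00:00",
                         participant_id = "unknown") {
  if (inherits(signal, "accel_recording")) {
    rec <- signal
    return(detect_steps(acceleration_magnitude(rec), rec$sampling_rate, config,
                        recording_start = rec$start_time,
                        participant_id = rec$participant_id))
  }
  if (is.null(sampling_rate) || !is.numeric(sampling_rate) ||
      length(sampling_rate) != 1L || sampling_rate <= 0)
    stop_gait("`sampling_rate` must be a single positive number", "parameter_error")
  if (!inherits(config, "detection_config"))
    stop_gait("`config` must be a detection_config", "parameter_error")
  x <- as.numeric(signal)
  if (length(x) < 2L)
    stop_gait("signal must have at least 2 samples", "parameter_error")

  if (!is.null(config$band)) {
    nyq <- sampling_rate / 2
    hi <- min(config$band[2], 0.99 * nyq)
    bf <- signal::butter(2, c(config$band[1], hi) / nyq, type = "pass")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  x <- smooth_signal(x, config$smoothing_window * sampling_rate)

  peaks <- find_local_maxima(x)
  if (length(peaks) > 0) {
    prom <- peak_prominence(x, peaks)
    peaks <- peaks[prom >= config$min_prominence]
  }
  peaks <- enforce_separation(x, peaks, config$min_peak_separation * sampling_rate)

  step_series((peaks - 1L) / sampling_rate,
              recording_start = recording_start,
              participant_id = participant_id)
}

# 0.1-s grid ------------------------------------------------------------------

# Round to the nearest 0.1 s with decimal ties (x.x5) rounding up.  The tiny
# epsilon makes values that are decimal ties but sit a few ulp below the
# binary midpoint (e.g. 0.35 stored as 0.34999...) still round up.
quantize_interval <- function(x) {
  q <- floor(x * 10 + 0.5 + 1e-9) / 10
  pmax(q, 0.1)
}

#' Quantized step intervals
#'
#' The interval between consecutive detected steps, rounded to the nearest
#' multiple of 0.1 s (the device's step-interval resolution).  Ties round up;
#' an interval that rounds to 0.0 is clamped to 0.1 s, since a step interval
#' cannot be zero.
#'
#' @param steps a [step_series()] or a numeric vector of at least two strictly
#'   increasing step times (seconds).
#' @return Numeric vector of positive multiples of 0.1 s, one per consecutive
#'   step pair.
#' @export
step_intervals <- function(steps) {
  times <- if (inherits(steps, "step_series")) steps$step_times else as.numeric(steps)
  if (length(times) < 2L)
    stop_gait("at least two step times are needed to form an interval",
              "insufficient_steps_error")
  if (any(diff(times) <= 0))
    stop_gait("step times must be strictly increasing", "validation_error")
  quantize_interval(diff(times))
}
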