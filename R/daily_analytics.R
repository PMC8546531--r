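# Daily-life gait analytics: per-day summaries, diurnal/weekly profiles,
# speed relative to the laboratory usual gait speed, dispersion, eligibility.

#' Default time-of-day bins
#'
#' Twelve 2-hour bins starting at 01:00: \[1,3), \[3,5), \[5,7), ..., \[23,1).
#' The grid is chosen so that the early-morning window 5-7 AM is a single
#' bin.  A bin-edge vector is the ascending sequence of bin start hours; the
#' last bin wraps past midnight to the first edge.
#'
#' @return Numeric vector of bin start hours.
#' @export
default_diurnal_bins <- function() seq(1, 23, by = 2)

check_bin_edges <- function(bin_edges) {
  if (!is.numeric(bin_edges) || length(bin_edges) < 1L ||
      any(!is.finite(bin_edges)) || any(bin_edges < 0) || any(bin_edges >= 24) ||
      (length(bin_edges) > 1 && any(diff(bin_edges) <= 0)))
    stop_gait("`bin_edges` must be strictly increasing hours in [0, 24); together they partition the 24-h clock",
              "parameter_error")
  invisible(bin_edges)
}

bin_label <- function(bin_edges) {
  k <- length(bin_edges)
  sprintf("[%g,%g)", bin_edges, c(bin_edges[-1], bin_edges[1]))
}

# index of the bin containing hour h (h in [0, 24)); hours before the first
# edge fall in the wrapping last bin.
assign_bin <- function(hours, bin_edges) {
  idx <- findInterval(hours, bin_edges)
  idx[idx == 0L] <- length(bin_edges)
  idx
}

#' Per-day gait summaries for one participant
#'
#' One row per calendar date with at least one measurement: the unweighted
#' mean speed over that date's measurements, total walking time (sum of bout
#' durations, minutes) and the measurement count.
#'
#' @param measurements measurements data frame for a single participant.
#' @return Data frame `participant_id`, `date`, `mean_speed` (m/s),
#'   `walking_time` (min), `n_measurements`.
#' @export
aggregate_daily <- function(measurements) {
  check_measurements(measurements, single_participant = TRUE)
  if (nrow(measurements) == 0L)
    return(data.frame(participant_id = character(0), date = as.Date(character(0)),
                      mean_speed = numeric(0), walking_time = numeric(0),
                      n_measurements = integer(0)))
  date <- as.Date(measurements$timestamp, tz = GAIT_TZ)
  agg <- lapply(split(seq_len(nrow(measurements)), date), function(idx) {
    data.frame(participant_id = measurements$participant_id[idx[1]],
               mean_speed = mean(measurements$speed[idx]),
               walking_time = sum(measurements$duration[idx]) / 60,
               n_measurements = length(idx))
  })
  out <- do.call(rbind, agg)
  out <- cbind(out[1], date = as.Date(names(agg)), out[-1])
  rownames(out) <- NULL
  out
}

#' Daily-life speed relative to the usual gait speed
#'
#' Each measurement is expressed as a percentage of the participant's own
#' laboratory usual gait speed, `r_i = 100 * speed_i / usual`.  The summary
#' "percentile vs usual" is the median of the `r_i`; also reported are the
#' fractions of measurements more than 25% faster (`r_i > 125`) and more than
#' 25% slower (`r_i < 75`) than usual (strict inequalities).
#'
#' @param measurements measurements data frame (>= 1 row).
#' @param usual_gait_speed the participant's usual gait speed, m/s, > 0.
#' @return List with `percentile_vs_usual`, `pct_faster25`, `pct_slower25`
#'   (all percent) and `n`.
#' @export
percentile_vs_usual <- function(measurements, usual_gait_speed) {
  check_measurements(measurements)
  check_number(usual_gait_speed, "usual_gait_speed", positive = TRUE)
  if (nrow(measurements) == 0L)
    stop_gait("at least one measurement is required", "parameter_error")
  r <- 100 * measurements$speed / usual_gait_speed
  list(percentile_vs_usual = median(r),
       pct_faster25 = 100 * sum(r > 125) / length(r),
       pct_slower25 = 100 * sum(r < 75) / length(r),
       n = length(r))
}

#' Mean speed by time of day
#'
#' @param measurements measurements data frame.
#' @param bin_edges ascending bin start hours in \[0,24) (the last bin wraps);
#'   default [default_diurnal_bins()].
#' @return Data frame `bin` (label), `start_hour`, `mean_speed`, `n`; bins
#'   with no measurements have `mean_speed = NA` (missing, not zero).
#' @export
diurnal_profile <- function(measurements, bin_edges = default_diurnal_bins()) {
  check_measurements(measurements)
  check_bin_edges(bin_edges)
  k <- length(bin_edges)
  idx <- assign_bin(measurements$hour_of_day, bin_edges)
  n <- tabulate(idx, nbins = k)
  mean_speed <- rep(NA_real_, k)
  for (b in unique(idx)) mean_speed[b] <- mean(measurements$speed[idx == b])
  data.frame(bin = bin_label(bin_edges), start_hour = bin_edges,
             mean_speed = mean_speed, n = n)
}

#' Weekday/weekend split of speed and walking time
#'
#' Measurements are partitioned by timestamp into Mon-Fri and Sat-Sun.  Mean
#' speed is computed per partition over measurements; walking minutes per day
#' divide the partition's total bout duration by the number of distinct
#' calendar days observed in that partition.  An empty partition yields `NA`.
#'
#' @param measurements measurements data frame (>= 1 row).
#' @return List `weekday_mean`, `weekend_mean` (m/s), `weekday_walk_min`,
#'   `weekend_walk_min` (min/day), `n_weekday`, `n_weekend`.
#' @export
weekly_split <- function(measurements) {
  check_measurements(measurements)
  if (nrow(measurements) == 0L)
    stop_gait("at least one measurement is required", "parameter_error")
  part <- function(keep) {
    m <- measurements[keep, , drop = FALSE]
    if (nrow(m) == 0L)
      return(list(mean = NA_real_, walk_min = NA_real_, n = 0L))
    days <- length(unique(as.Date(m$timestamp, tz = GAIT_TZ)))
    list(mean = mean(m$speed), walk_min = sum(m$duration) / 60 / days,
         n = nrow(m))
  }
  wd <- part(!measurements$is_weekend)
  we <- part(measurements$is_weekend)
  list(weekday_mean = wd$mean, weekend_mean = we$mean,
       weekday_walk_min = wd$walk_min, weekend_walk_min = we$walk_min,
       n_weekday = wd$n, n_weekend = we$n)
}

#' Participant-level daily-life gait profile
#'
#' Assembles the full per-participant summary: mean/median/SD and coefficient
#' of variation of speed over all measurements (not over daily means), the
#' diurnal and day-of-week profiles, weekday/weekend split, speed relative to
#' the usual gait speed, wear days, and eligibility (at least `min_wear_days`
#' distinct calendar dates with a measurement).
#'
#' @param measurements measurements data frame for one participant (>= 1 row).
#' @param usual_gait_speed laboratory usual gait speed, m/s; `NA` skips the
#'   percentile block.
#' @param min_wear_days eligibility threshold in distinct wear days
#'   (default 10).
#' @param bin_edges time-of-day bins, see [diurnal_profile()].
#' @return An object of class `gait_profile` (a named list).
#' @export
gait_profile <- function(measurements, usual_gait_speed = NA,
                         min_wear_days = 10,
                         bin_edges = default_diurnal_bins()) {
  check_measurements(measurements, single_participant = TRUE)
  check_number(min_wear_days, "min_wear_days")
  if (min_wear_days < 1) stop_gait("`min_wear_days` must be >= 1", "parameter_error")
  if (nrow(measurements) == 0L)
    stop_gait("cannot build a profile from zero measurements", "empty_profile_error")

  speeds <- measurements$speed
  mean_speed <- mean(speeds)
  sd_speed <- if (length(speeds) > 1) sd(speeds) else 0
  wk <- weekly_split(measurements)
  dow_means <- setNames(rep(NA_real_, 7L), DOW_LABELS)
  obs <- tapply(speeds, factor(measurements$day_of_week, levels = DOW_LABELS), mean)
  dow_means[names(obs)] <- obs
  wear_days <- length(unique(as.Date(measurements$timestamp, tz = GAIT_TZ)))

  pct <- if (is.na(usual_gait_speed)) {
    list(percentile_vs_usual = NA_real_, pct_faster25 = NA_real_,
         pct_slower25 = NA_real_)
  } else percentile_vs_usual(measurements, usual_gait_speed)

  structure(list(
    participant_id = measurements$participant_id[1],
    n_measurements = nrow(measurements),
    mean = mean_speed,
    median = median(speeds),
    sd = sd_speed,
    cv = if (mean_speed > 0) 100 * sd_speed / mean_speed else NA_real_,
    hourly_profile = diurnal_profile(measurements, bin_edges),
    dow_profile = dow_means,
    weekday_mean = wk$weekday_mean,
    weekend_mean = wk$weekend_mean,
    weekday_walk_min = wk$weekday_walk_min,
    weekend_walk_min = wk$weekend_walk_min,
    percentile_vs_usual = pct$percentile_vs_usual,
    pct_faster25 = pct$pct_faster25,
    pct_slower25 = pct$pct_slower25,
    wear_days = wear_days,
    eligible = wear_days >= min_wear_days),
    class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf("<gait_profile> participant %s: %d measurements over %d wear day(s)%s\n",
              x$participant_id, x$n_measurements, x$wear_days,
              if (x$eligible) "" else " (not eligible)"))
  cat(sprintf("  speed %.3f m/s (median %.3f, SD %.3f, CV %.1f%%)\n",
              x$mean, x$median, x$sd, x$cv))
  if (!is.na(x$percentile_vs_usual))
    cat(sprintf("  vs usual: median %.1f%%; >25%% faster %.2f%%, >25%% slower %.2f%%\n",
                x$percentile_vs_usual, x$pct_faster25, x$pct_slower25))
  invisible(x)
}
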