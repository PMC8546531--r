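# Synthetic data layer.  Two generators:
#
#  * walking accelerometer signals with analytically known step times, for
#    exercising the detection chain end to end;
#  * multi-day, multi-participant gait-speed measurement streams and cohort
#    tables with the statistical structure of an older-men wearable study
#    (diurnal modulation peaking 5-7 AM, a small weekday effect, and a
#    sarcopenic subgroup that is slower, weaker and has less muscle mass),
#    with full ground truth returned alongside the data.
#
# Everything is deterministic for a fixed seed, and seeds never leak into the
# caller's RNG stream.

#' Walking-signal specification
#'
#' The signal model is a two-harmonic sinusoid riding on the 1-g gravity
#' baseline, plus white noise: it is not biomechanical, but it gives peak
#' detection an analytic ground truth.  The fundamental is phased so that its
#' maxima - the true step times - fall at `(k + 1/2) / cadence` seconds, and
#' the second harmonic is phased to peak at the same instants, so the
#' noiseless summed signal has its local maxima exactly at the true step
#' times (guaranteed for `harmonic_fraction < 0.25`).
#'
#' @param cadence steps per second, in (0.5, 4).
#' @param duration signal length, seconds.
#' @param sampling_rate samples per second; must be at least `4 * cadence` so
#'   peaks are resolvable.
#' @param peak_amplitude fundamental amplitude, g (default 0.5, a typical
#'   walking peak at the waist).
#' @param harmonic_fraction second-harmonic amplitude as a fraction of
#'   `peak_amplitude`, in \[0, 0.25) (default 0.2).
#' @param noise_sd white-noise SD, g (>= 0).
#' @param seed RNG seed for reproducibility (`NULL` uses the current stream).
#' @return An object of class `walk_signal_spec`.
#' @export
walk_signal_spec <- function(cadence = 1.8, duration = 60, sampling_rate = 50,
                             peak_amplitude = 0.5, harmonic_fraction = 0.2,
                             noise_sd = 0.05, seed = NULL) {
  check_number(cadence, "cadence")
  if (cadence <= 0.5 || cadence >= 4)
    stop_gait("`cadence` must lie in (0.5, 4) steps/s", "parameter_error")
  check_number(duration, "duration", positive = TRUE)
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (sampling_rate < 4 * cadence)
    stop_gait(sprintf(
      "sampling_rate %g cannot resolve cadence %g steps/s (need >= 4x cadence)",
      sampling_rate, cadence), "aliasing_error")
  check_number(peak_amplitude, "peak_amplitude", positive = TRUE)
  check_number(harmonic_fraction, "harmonic_fraction")
  if (harmonic_fraction < 0 || harmonic_fraction >= 0.25)
    stop_gait("`harmonic_fraction` must lie in [0, 0.25) so peaks stay at the fundamental maxima",
              "parameter_error")
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_gait("`noise_sd` must be >= 0", "parameter_error")
  structure(list(cadence = cadence, duration = duration,
                 sampling_rate = sampling_rate, peak_amplitude = peak_amplitude,
                 harmonic_fraction = harmonic_fraction, noise_sd = noise_sd,
                 seed = seed),
            class = "walk_signal_spec")
}

#' Simulate a walking accelerometer signal with known step times
#'
#' The vertical axis carries
#' `1 - A*cos(2*pi*c*t) + f*A*cos(4*pi*c*t) + N(0, noise_sd)` (g), where `A`
#' is `peak_amplitude`, `c` the cadence and `f` the harmonic fraction; the
#' other two axes carry low-level noise (`N(0, noise_sd / 2)`).  True step
#' times are the analytic maxima of the noiseless fundamental,
#' `(k + 1/2) / c` for every such time inside the recording.
#'
#' @param spec a [walk_signal_spec()].
#' @param participant_id,start_time anchoring for the returned recording.
#' @return List with `recording` (an [accel_recording()]) and
#'   `true_step_times` (seconds).
#' @export
simulate_walk_signal <- function(spec, participant_id = "sim",
                                 start_time = "2000-01-03T08:00:00") {
  if (!inherits(spec, "walk_signal_spec"))
    stop_gait("`spec` must be a walk_signal_spec", "parameter_error")
  n <- floor(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  A <- spec$peak_amplitude
  az0 <- 1 - A * cos(2 * pi * spec$cadence * t) +
    spec$harmonic_fraction * A * cos(4 * pi * spec$cadence * t)
  samples <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      data.frame(ax = rnorm(n, 0, spec$noise_sd / 2),
                 ay = rnorm(n, 0, spec$noise_sd / 2),
                 az = az0 + rnorm(n, 0, spec$noise_sd))
    } else data.frame(ax = numeric(n), ay = numeric(n), az = az0)
  })
  k_max <- floor(spec$cadence * spec$duration - 0.5)
  true_steps <- if (k_max >= 0) (0:k_max + 0.5) / spec$cadence else numeric(0)
  list(recording = accel_recording(samples, spec$sampling_rate, start_time,
                                   participant_id),
       true_step_times = true_steps)
}

# Diurnal modulation shape: a Gaussian bump centred at 06:00 (SD 1.5 h) so
# the 5-7 AM window is the fastest, re-centred to have zero mean under
# uniform sampling of the waking hours.  Peak-to-baseline contrast is 1.
diurnal_shape <- function(hour, waking = c(5, 23)) {
  mu <- 6; s <- 1.5
  bump <- function(h) exp(-(h - mu)^2 / (2 * s^2))
  # mean of the bump over Uniform(waking): closed form via the normal CDF
  avg <- s * sqrt(2 * pi) *
    (pnorm((waking[2] - mu) / s) - pnorm((waking[1] - mu) / s)) /
    (waking[2] - waking[1])
  bump(hour) - avg
}

# Draw from N(mean, sd) truncated to (lower, upper) by resampling.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
    guard <- guard + 1L
    if (guard > 1000L)
      stop_gait("truncated-normal rejection budget exhausted; bounds exclude nearly all mass",
                "rejection_budget_error")
  }
  x
}

#' Simulate one participant's multi-day measurement stream
#'
#' Bout timestamps are drawn within waking hours on each of `days`
#' consecutive calendar days (bout counts per day are Poisson); bout speed is
#' `base_speed + diurnal_amplitude * g(hour) + weekday_effect * [weekday]
#' + N(0, noise_sd)`, truncated to be greater than 0.3 m/s.  The diurnal
#' shape `g` peaks in the 5-7 AM window and has zero mean over the waking
#' hours, so `base_speed` is also the expected speed up to the weekday term.
#'
#' @param participant_id identifier.
#' @param days number of consecutive days simulated (>= 1; default 28, a
#'   4-week wear period).
#' @param base_speed participant's underlying daily-life gait speed, m/s.
#' @param diurnal_amplitude peak diurnal speed-up, m/s (default 0.06).
#' @param weekday_effect speed added on Mon-Fri, m/s (default 0.01).
#' @param noise_sd within-participant bout-to-bout SD, m/s (default 0.25).
#' @param measurements_per_day Poisson mean of bouts per day (default 73,
#'   about 2050 bouts over 4 weeks).
#' @param mean_bout_s mean bout duration, seconds (gamma distributed, shape
#'   2; default 72 s, about 88 min of walking per day at the default rate).
#' @param waking_hours `c(start, end)` hours within which bouts occur
#'   (default 05:00-23:00).
#' @param height,sex anthropometrics used to give each bout a plausible step
#'   count.
#' @param start_date first calendar day (default `"2000-01-03"`, a Monday).
#' @param seed RNG seed.
#' @return List with `measurements` (standard measurements data frame) and
#'   `truth` (generator parameters plus `expected_mean_speed`, the implied
#'   expectation of a measurement's speed: `base_speed + weekday_effect *
#'   <weekday fraction of days>`).
#' @export
simulate_participant_days <- function(participant_id = "sim", days = 28,
                                      base_speed = 1.23,
                                      diurnal_amplitude = 0.06,
                                      weekday_effect = 0.01,
                                      noise_sd = 0.25,
                                      measurements_per_day = 73,
                                      mean_bout_s = 72,
                                      waking_hours = c(5, 23),
                                      height = 1.67, sex = "male",
                                      start_date = "2000-01-03",
                                      seed = NULL) {
  check_number(days, "days")
  if (days < 1) stop_gait("`days` must be >= 1", "parameter_error")
  check_number(base_speed, "base_speed", positive = TRUE)
  check_number(noise_sd, "noise_sd")
  origin <- parse_time(paste0(start_date, "T00:00:00"), "start_date")
  step_len <- step_length(height, sex)

  with_seed(seed, {
    n_per_day <- rpois(days, measurements_per_day)
    n <- sum(n_per_day)
    if (n == 0L) {
      meas <- new_measurements(character(0), parse_time(character(0)),
                               numeric(0), numeric(0), integer(0))
    } else {
      day_idx <- rep(seq_len(days) - 1L, n_per_day)
      hour <- runif(n, waking_hours[1], waking_hours[2])
      ts <- origin + day_idx * 86400 + hour * 3600
      is_weekday <- day_of_week_index(ts) <= 5L
      speed <- rnorm_trunc(
        n,
        base_speed + diurnal_amplitude * diurnal_shape(hour, waking_hours) +
          weekday_effect * is_weekday,
        noise_sd, lower = 0.3)
      duration <- rgamma(n, shape = 2, scale = mean_bout_s / 2)
      n_steps <- pmax(8L, as.integer(round(duration * speed / step_len)))
      ord <- order(ts)
      meas <- new_measurements(participant_id, ts[ord], speed[ord],
                               duration[ord], n_steps[ord])
    }
    weekday_days <- sum(day_of_week_index(origin + (seq_len(days) - 1L) * 86400) <= 5L)
    list(measurements = meas,
         truth = list(participant_id = participant_id,
                      base_speed = base_speed,
                      diurnal_amplitude = diurnal_amplitude,
                      weekday_effect = weekday_effect,
                      noise_sd = noise_sd,
                      expected_mean_speed = base_speed +
                        weekday_effect * weekday_days / days,
                      days = days))
  })
}

#' Cohort specification
#'
#' Group sizes and per-group attribute distributions (mean, SD) for a
#' two-group cohort of older men, one group sarcopenic and one normal.
#' Defaults are the observed group statistics of a 106-man wearable-belt
#' study: 13 sarcopenic / 93 normal; daily-life speed 1.12 (0.11) vs
#' 1.23 (0.08) m/s; usual gait speed 0.97 (0.12) vs 1.28 (0.16) m/s;
#' handgrip 27.4 (5.4) vs 37.2 (5.8) kg; ASM index 6.39 (0.34) vs
#' 6.79 (0.77) kg/m^2; age 76.0 (6.2) vs 70.5 (7.6) years; BMI 25.0 (2.5)
#' vs 24.5 (2.5) kg/m^2.  Height is N(1.67, 0.06) m for both groups (not
#' tabulated in the source cohort; a typical value for older Korean men).
#'
#' @param n_sarcopenic,n_normal group sizes.
#' @param sarcopenic,normal named lists of `c(mean, sd)` pairs for
#'   `daily_speed`, `usual_speed`, `grip`, `asmi`, `age`, `bmi` (any subset;
#'   the rest keep defaults).
#' @param height `c(mean, sd)` of height in meters, shared by both groups.
#' @param diurnal_amplitude,weekday_effect,noise_sd,measurements_per_day,days,mean_bout_s
#'   measurement-stream parameters, see [simulate_participant_days()].
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sarcopenic = 13, n_normal = 93,
                        sarcopenic = list(), normal = list(),
                        height = c(1.67, 0.06),
                        diurnal_amplitude = 0.06, weekday_effect = 0.01,
                        noise_sd = 0.25, measurements_per_day = 73,
                        days = 28, mean_bout_s = 72, seed = NULL) {
  defaults <- list(
    sarcopenic = list(daily_speed = c(1.12, 0.11), usual_speed = c(0.97, 0.12),
                      grip = c(27.4, 5.4), asmi = c(6.39, 0.34),
                      age = c(76.0, 6.2), bmi = c(25.0, 2.5),
                      hypertension = 0.846, diabetes = 0.231, angina = 0.462,
                      arthritis = 0.154, smoking = c(0.462, 0.462, 0.077)),
    normal = list(daily_speed = c(1.23, 0.08), usual_speed = c(1.28, 0.16),
                  grip = c(37.2, 5.8), asmi = c(6.79, 0.77),
                  age = c(70.5, 7.6), bmi = c(24.5, 2.5),
                  hypertension = 0.602, diabetes = 0.269, angina = 0.172,
                  arthritis = 0.172, smoking = c(0.108, 0.753, 0.140)))
  defaults$sarcopenic[names(sarcopenic)] <- sarcopenic
  defaults$normal[names(normal)] <- normal
  for (g in c("sarcopenic", "normal"))
    for (v in c("daily_speed", "usual_speed", "grip", "asmi", "age", "bmi"))
      if (defaults[[g]][[v]][2] < 0)
        stop_gait(sprintf("SD of %s (%s group) must be >= 0", v, g), "parameter_error")
  if (n_sarcopenic < 0 || n_normal < 0 || n_sarcopenic + n_normal < 1)
    stop_gait("group sizes must be non-negative and sum to >= 1", "parameter_error")
  structure(list(n_sarcopenic = n_sarcopenic, n_normal = n_normal,
                 groups = defaults, height = height,
                 diurnal_amplitude = diurnal_amplitude,
                 weekday_effect = weekday_effect, noise_sd = noise_sd,
                 measurements_per_day = measurements_per_day, days = days,
                 mean_bout_s = mean_bout_s, seed = seed),
            class = "cohort_spec")
}

# Draw one participant's AWGS-relevant attributes by rejection sampling until
# the diagnosis matches the intended group.
draw_attributes <- function(g, sarcopenic, cutoffs, max_attempts = 10000L) {
  for (attempt in seq_len(max_attempts)) {
    grip_target <- rnorm(1, g$grip[1], g$grip[2])
    trials <- grip_target + rnorm(3, 0, 0.8)
    if (any(trials <= 5)) next
    grip <- mean(trials)
    usual <- rnorm(1, g$usual_speed[1], g$usual_speed[2])
    if (usual <= 0.3) next
    asmi <- rnorm(1, g$asmi[1], g$asmi[2])
    if (asmi <= 3) next
    dx <- asmi < cutoffs$asmi_kgm2 &&
      (grip < cutoffs$grip_kg || usual < cutoffs$speed_ms)
    if (dx == sarcopenic)
      return(list(trials = trials, grip = grip, usual = usual, asmi = asmi))
  }
  stop_gait(sprintf(
    "could not draw a %s participant consistent with the AWGS rule in %d attempts; the spec is (nearly) unsatisfiable",
    if (sarcopenic) "sarcopenic" else "normal", max_attempts),
    "rejection_budget_error")
}

#' Simulate a full cohort with ground truth
#'
#' Draws participant attributes per group from the spec's (truncated) normal
#' distributions, with rejection sampling so that every sarcopenic-group
#' member satisfies the AWGS diagnosis rule and every normal-group member
#' does not; then generates each participant's multi-day measurement stream
#' via [simulate_participant_days()].
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; overrides `spec$seed` when given.
#' @param include_measurements generate the per-participant measurement
#'   streams (default `TRUE`); `FALSE` returns attributes only, which is much
#'   faster when only the cohort table is needed.
#' @return List with `participants` (a validated `participant_table`),
#'   `measurements` (all participants' streams, row-bound) and `truth`
#'   (per-participant group, base speed and expected mean speed, plus the
#'   spec).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            include_measurements = TRUE) {
  if (!inherits(spec, "cohort_spec"))
    stop_gait("`spec` must be a cohort_spec", "parameter_error")
  if (is.null(seed)) seed <- spec$seed
  cutoffs <- awgs_cutoffs()
  n_total <- spec$n_sarcopenic + spec$n_normal
  group <- rep(c("sarcopenia", "normal"), c(spec$n_sarcopenic, spec$n_normal))

  with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n_total))
    rows <- vector("list", n_total)
    base_speed <- numeric(n_total)
    for (i in seq_len(n_total)) {
      sarcopenic <- group[i] == "sarcopenia"
      g <- spec$groups[[if (sarcopenic) "sarcopenic" else "normal"]]
      att <- draw_attributes(g, sarcopenic, cutoffs)
      h <- rnorm_trunc(1, spec$height[1], spec$height[2], 1.45, 1.95)
      bmi <- rnorm_trunc(1, g$bmi[1], g$bmi[2], 15, 40)
      age <- as.integer(round(rnorm_trunc(1, g$age[1], g$age[2], 50, 95)))
      base_speed[i] <- rnorm_trunc(1, g$daily_speed[1], g$daily_speed[2], 0.3)
      smoking <- sample(c("current", "ex", "never"), 1, prob = g$smoking)
      rows[[i]] <- data.frame(
        participant_id = ids[i], sex = "male", age = age,
        height_m = h, weight_kg = bmi * h^2,
        grip1_kg = att$trials[1], grip2_kg = att$trials[2],
        grip3_kg = att$trials[3],
        asm_kg = att$asmi * h^2,
        usual_gait_speed_ms = att$usual,
        hypertension = rbinom(1, 1, g$hypertension),
        diabetes = rbinom(1, 1, g$diabetes),
        angina = rbinom(1, 1, g$angina),
        arthritis = rbinom(1, 1, g$arthritis),
        smoking = smoking)
    }
    participants <- validate_participants(do.call(rbind, rows))

    measurements <- NULL
    expected_mean <- base_speed
    if (include_measurements) {
      streams <- vector("list", n_total)
      for (i in seq_len(n_total)) {
        sim <- simulate_participant_days(
          participant_id = ids[i], days = spec$days,
          base_speed = base_speed[i],
          diurnal_amplitude = spec$diurnal_amplitude,
          weekday_effect = spec$weekday_effect,
          noise_sd = spec$noise_sd,
          measurements_per_day = spec$measurements_per_day,
          mean_bout_s = spec$mean_bout_s,
          height = participants$height_m[i], sex = "male",
          seed = NULL)
        streams[[i]] <- sim$measurements
        expected_mean[i] <- sim$truth$expected_mean_speed
      }
      measurements <- bind_measurements(streams)
    }
    list(participants = participants,
         measurements = measurements,
         truth = list(participant_id = ids, group = group,
                      base_speed = base_speed,
                      expected_mean_speed = expected_mean,
                      spec = spec))
  })
}
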