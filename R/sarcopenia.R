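# AWGS sarcopenia classification and its component measurements.
#
# The rule: sarcopenia = low appendicular skeletal muscle mass AND (low
# muscle strength OR low physical performance).  Component cutoffs for men:
# handgrip < 28 kg, usual gait speed < 1.0 m/s, ASM/height^2 < 7.0 kg/m^2.
# All comparisons are strict; a value exactly at a cutoff is normal.

#' AWGS component cutoffs
#'
#' Defaults are the male cutoffs (the cohorts this tooling targets are
#' male-only); supply the female AWGS values here to reuse the classifier.
#'
#' @param grip_kg low-strength cutoff, kg (default 28).
#' @param speed_ms low-performance cutoff, m/s (default 1.0).
#' @param asmi_kgm2 low-mass cutoff on ASM/height^2, kg/m^2 (default 7.0).
#' @return Named list of cutoffs.
#' @export
awgs_cutoffs <- function(grip_kg = 28, speed_ms = 1.0, asmi_kgm2 = 7.0) {
  check_number(grip_kg, "grip_kg", positive = TRUE)
  check_number(speed_ms, "speed_ms", positive = TRUE)
  check_number(asmi_kgm2, "asmi_kgm2", positive = TRUE)
  list(grip_kg = grip_kg, speed_ms = speed_ms, asmi_kgm2 = asmi_kgm2)
}

#' Handgrip strength from three trials
#'
#' The protocol takes three consecutive measurements of the dominant hand and
#' records their average.
#'
#' @param trials numeric vector of exactly three positive values, kg.
#' @return Arithmetic mean, kg.
#' @export
handgrip_mean <- function(trials) {
  if (!is.numeric(trials) || length(trials) != 3L)
    stop_gait("exactly three handgrip trials are required", "validation_error")
  if (any(!is.finite(trials)) || any(trials <= 0))
    stop_gait("handgrip trials must all be strictly positive", "validation_error")
  mean(trials)
}

#' Usual gait speed from a timed walkway
#'
#' Speed over the timed section of a walkway (the default 4.5 m section is
#' preceded and followed by 1-m acceleration/deceleration phases that are not
#' timed).
#'
#' @param elapsed time to cover the timed section, seconds.
#' @param distance timed-section length, meters (default 4.5).
#' @return Speed in m/s.
#' @export
usual_gait_speed <- function(elapsed, distance = 4.5) {
  check_number(distance, "distance", positive = TRUE)
  check_number(elapsed, "elapsed", positive = TRUE)
  distance / elapsed
}

#' Classify sarcopenia under the AWGS rule
#'
#' Component flags are `low_strength` (grip mean below the grip cutoff),
#' `low_performance` (usual gait speed below the speed cutoff) and `low_mass`
#' (ASM index below the mass cutoff), all strict.  The diagnosis is
#' `low_mass AND (low_strength OR low_performance)`.
#'
#' @param profile a list or one-row data frame providing `participant_id`
#'   (optional), `grip_mean` (kg; or `handgrip_trials`, three values),
#'   `usual_gait_speed` (m/s; column `usual_gait_speed_ms` also accepted),
#'   and either `asm_index` (kg/m^2) or both `asm` (kg; `asm_kg` accepted) and
#'   `height` (m; `height_m` accepted), from which the index is recomputed.
#'   When both the index and its inputs are present the index is recomputed
#'   and the supplied value ignored.
#' @param cutoffs an [awgs_cutoffs()] list.
#' @return An object of class `sarcopenia_assessment`: the three flags, the
#'   diagnosis, and the component values they were derived from.
#' @export
classify_awgs <- function(profile, cutoffs = awgs_cutoffs()) {
  profile <- as.list(profile)
  get1 <- function(...) {
    for (nm in c(...)) {
      v <- profile[[nm]]
      if (!is.null(v) && length(v) >= 1 && !all(is.na(v))) return(v)
    }
    NULL
  }
  grip <- get1("grip_mean")
  if (is.null(grip)) {
    trials <- get1("handgrip_trials")
    if (is.null(trials)) {
      trials <- c(profile$grip1_kg, profile$grip2_kg, profile$grip3_kg)
      if (length(trials) != 3L || anyNA(trials)) trials <- NULL
    }
    if (!is.null(trials)) grip <- handgrip_mean(trials)
  }
  usual <- get1("usual_gait_speed", "usual_gait_speed_ms")
  asm <- get1("asm", "asm_kg")
  height <- get1("height", "height_m")
  asmi <- if (!is.null(asm) && !is.null(height)) {
    check_height(height)
    check_number(asm, "asm", positive = TRUE)
    asm / height^2
  } else get1("asm_index")

  missing_parts <- c(if (is.null(grip)) "handgrip",
                     if (is.null(usual)) "usual gait speed",
                     if (is.null(asmi)) "ASM index")
  if (length(missing_parts) > 0)
    stop_gait(paste0("incomplete assessment; missing component(s): ",
                     paste(missing_parts, collapse = ", ")),
              "incomplete_assessment_error")

  low_strength <- grip < cutoffs$grip_kg
  low_performance <- usual < cutoffs$speed_ms
  low_mass <- asmi < cutoffs$asmi_kgm2
  structure(list(
    participant_id = if (is.null(profile$participant_id)) "unknown" else
      as.character(profile$participant_id),
    low_strength = low_strength,
    low_performance = low_performance,
    low_mass = low_mass,
    diagnosis = low_mass && (low_strength || low_performance),
    grip_mean = grip,
    asm_index = asmi,
    usual_gait_speed = usual,
    cutoffs = cutoffs),
    class = "sarcopenia_assessment")
}

#' @export
print.sarcopenia_assessment <- function(x, ...) {
  flag <- function(f) if (f) "LOW" else "normal"
  cat(sprintf("<sarcopenia_assessment> participant %s: %s\n", x$participant_id,
              if (x$diagnosis) "SARCOPENIA" else "no sarcopenia"))
  cat(sprintf("  grip %.1f kg [%s]  usual speed %.2f m/s [%s]  ASM index %.2f kg/m2 [%s]\n",
              x$grip_mean, flag(x$low_strength),
              x$usual_gait_speed, flag(x$low_performance),
              x$asm_index, flag(x$low_mass)))
  invisible(x)
}

#' Classify every participant in a table
#'
#' @param participants a [read_participant_table()] table (or compatible data
#'   frame with `grip_mean`/grip trials, `usual_gait_speed_ms`, `asm_kg`,
#'   `height_m`).
#' @param cutoffs an [awgs_cutoffs()] list.
#' @return Data frame with one row per participant: component values, the
#'   three flags and the diagnosis.
#' @export
classify_cohort <- function(participants, cutoffs = awgs_cutoffs()) {
  rows <- lapply(seq_len(nrow(participants)), function(i) {
    a <- classify_awgs(participants[i, , drop = FALSE], cutoffs)
    data.frame(participant_id = a$participant_id, grip_mean = a$grip_mean,
               usual_gait_speed = a$usual_gait_speed, asm_index = a$asm_index,
               low_strength = a$low_strength, low_performance = a$low_performance,
               low_mass = a$low_mass, diagnosis = a$diagnosis)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
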