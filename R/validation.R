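# Step-detection validation against annotated ground truth: tolerance-based
# matching of detected to true step times, and the three reporting metrics
# (step-count consistency, sensitivity, positive predictive value).

#' Match detected steps to ground truth
#'
#' One-to-one greedy matching: true steps are scanned in order and each is
#' matched to the nearest still-unmatched detected step within
#' `+/- tolerance` seconds.  Matched pairs are true positives; unmatched
#' detected steps are false positives; unmatched true steps are false
#' negatives.  Greedy matching is provably optimal whenever inter-step
#' spacing exceeds `2 * tolerance` on both sequences (each step then has at
#' most one candidate partner).
#'
#' Metrics (all percent): sensitivity `100 * tp / (tp + fn)`, positive
#' predictive value `100 * tp / (tp + fp)`, and step-count consistency
#' `100 * (1 - |n_detected - n_true| / n_true)`, floored at 0.
#'
#' @param detected detected step times: numeric vector or [step_series()],
#'   strictly increasing.
#' @param truth annotated true step times, strictly increasing, non-empty.
#' @param tolerance matching half-window in seconds (default 0.3 s, about
#'   half a typical step interval).
#' @return An object of class `step_match`: `tp`, `fp`, `fn`, `sensitivity`,
#'   `ppv`, `consistency`, `tolerance`, `n_detected`, `n_true`.
#' @export
match_steps <- function(detected, truth, tolerance = 0.3) {
  det <- if (inherits(detected, "step_series")) detected$step_times else as.numeric(detected)
  tru <- if (inherits(truth, "step_series")) truth$step_times else as.numeric(truth)
  check_number(tolerance, "tolerance", positive = TRUE)
  if (length(tru) == 0L)
    stop_gait("empty ground truth: step-count consistency is undefined",
              "undefined_consistency_error")
  if (anyNA(tru) || anyNA(det))
    stop_gait("step times must not contain missing values", "validation_error")
  if (length(tru) > 1 && any(diff(tru) <= 0))
    stop_gait("true step times must be strictly increasing", "validation_error")
  if (length(det) > 1 && any(diff(det) <= 0))
    stop_gait("detected step times must be strictly increasing", "validation_error")

  available <- rep(TRUE, length(det))
  tp <- 0L
  for (t in tru) {
    if (!any(available)) break
    idx <- which(available)
    d <- abs(det[idx] - t)
    j <- idx[which.min(d)]
    if (abs(det[j] - t) <= tolerance) {
      available[j] <- FALSE
      tp <- tp + 1L
    }
  }
  fp <- length(det) - tp
  fn <- length(tru) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = 100 * tp / length(tru),
    ppv = if (length(det) > 0) 100 * tp / length(det) else NA_real_,
    consistency = max(0, 100 * (1 - abs(length(det) - length(tru)) / length(tru))),
    tolerance = tolerance,
    n_detected = length(det), n_true = length(tru)),
    class = "step_match")
}

#' @export
print.step_match <- function(x, ...) {
  cat(sprintf(
    "<step_match> tp %d fp %d fn %d | sensitivity %.1f%% ppv %s consistency %.1f%% (tol %.2f s)\n",
    x$tp, x$fp, x$fn, x$sensitivity,
    if (is.na(x$ppv)) "NA" else sprintf("%.1f%%", x$ppv), x$consistency,
    x$tolerance))
  invisible(x)
}

#' Benchmark the detector over a grid of signal conditions
#'
#' For each grid row, simulates `n_reps` walking signals, runs
#' [detect_steps()] and scores against the analytic step times with
#' [match_steps()]; reports the mean and SD of each metric per cell.
#'
#' @param grid data frame whose columns are [walk_signal_spec()] arguments
#'   (`cadence`, `duration`, `sampling_rate`, `peak_amplitude`,
#'   `harmonic_fraction`, `noise_sd`); one row per condition.
#' @param config a [detection_config()].
#' @param n_reps replicate signals per cell (default 5).
#' @param tolerance matching tolerance in seconds.
#' @param seed base seed; cell/replicate seeds are derived from it, so the
#'   whole table is reproducible.
#' @return The grid with appended columns `sensitivity_mean`,
#'   `sensitivity_sd`, `ppv_mean`, `ppv_sd`, `consistency_mean`,
#'   `consistency_sd`.
#' @export
evaluate_detector <- function(grid, config = detection_config(), n_reps = 5,
                              tolerance = 0.3, seed = 1) {
  grid <- as.data.frame(grid)
  allowed <- c("cadence", "duration", "sampling_rate", "peak_amplitude",
               "harmonic_fraction", "noise_sd")
  extra <- setdiff(names(grid), allowed)
  if (length(extra) > 0)
    stop_gait(paste0("unknown grid column(s): ", paste(extra, collapse = ", ")),
              "parameter_error")
  metrics <- c("sensitivity", "ppv", "consistency")
  out <- matrix(NA_real_, nrow(grid), 2 * length(metrics))
  for (i in seq_len(nrow(grid))) {
    vals <- matrix(NA_real_, n_reps, length(metrics))
    for (r in seq_len(n_reps)) {
      args <- as.list(grid[i, , drop = FALSE])
      args$seed <- (seed + 7919L * (i - 1L) + r) %% .Machine$integer.max
      spec <- do.call(walk_signal_spec, args)
      sim <- simulate_walk_signal(spec)
      steps <- detect_steps(sim$recording, config = config)
      m <- match_steps(steps, sim$true_step_times, tolerance)
      vals[r, ] <- c(m$sensitivity, m$ppv, m$consistency)
    }
    out[i, ] <- c(rbind(colMeans(vals), apply(vals, 2, sd)))
  }
  colnames(out) <- as.vector(rbind(paste0(metrics, "_mean"), paste0(metrics, "_sd")))
  cbind(grid, as.data.frame(out))
}
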