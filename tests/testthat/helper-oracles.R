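# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the rule definitions, not from the package code.

# --- peak detection oracle ---------------------------------------------------
# Enumerate every local maximum (first sample of a plateau), compute its
# topographic prominence by direct scanning, drop those below min_prominence,
# then repeatedly accept the highest remaining candidate (ties: earliest) and
# discard candidates closer than min_separation.
oracle_peaks <- function(x, fs, min_prominence, min_separation) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(cand) > 0) {
    prom <- vapply(cand, function(p) {
      h <- x[p]
      lmin <- h
      for (q in (p - 1L):1L) {
        if (x[q] > h) break
        lmin <- min(lmin, x[q])
      }
      rmin <- h
      for (q in (p + 1L):n) {
        if (x[q] > h) break
        rmin <- min(rmin, x[q])
      }
      h - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  kept <- integer(0)
  remaining <- cand
  while (length(remaining) > 0) {
    best <- remaining[order(-x[remaining], remaining)][1]
    kept <- c(kept, best)
    remaining <- remaining[abs(remaining - best) / fs >= min_separation &
                             remaining != best]
  }
  sort(kept)
}

# --- step matching oracle ----------------------------------------------------
# Exhaustive optimal one-to-one assignment maximizing the number of matched
# pairs within tolerance.  For sorted sequences an optimal non-crossing
# matching exists, so the O(n*m) alignment DP is exact.
oracle_optimal_matches <- function(truth, detected, tolerance) {
  nt <- length(truth); nd <- length(detected)
  if (nt == 0L || nd == 0L) return(0L)
  f <- matrix(0L, nt + 1L, nd + 1L)
  for (i in nt:1) for (j in nd:1) {
    best <- max(f[i + 1L, j], f[i, j + 1L])
    if (abs(truth[i] - detected[j]) <= tolerance)
      best <- max(best, f[i + 1L, j + 1L] + 1L)
    f[i, j] <- best
  }
  if (nt == 0L || nd == 0L) 0L else f[1L, 1L]
}

# --- bout segmentation oracle ------------------------------------------------
# Plain loop: cut wherever the gap exceeds max_gap, keep runs >= min_steps.
oracle_runs <- function(times, max_gap, min_steps) {
  runs <- list()
  current <- times[1]
  for (t in times[-1]) {
    if (t - current[length(current)] <= max_gap) current <- c(current, t)
    else {
      runs <- c(runs, list(current))
      current <- t
    }
  }
  runs <- c(runs, list(current))
  runs[vapply(runs, length, integer(1)) >= min_steps]
}

# --- AWGS oracle -------------------------------------------------------------
# Diagnosis by direct enumeration of the rule over the three flags.
oracle_awgs <- function(low_strength, low_performance, low_mass) {
  low_mass && (low_strength || low_performance)
}

# --- shared fixtures ---------------------------------------------------------

# A spiky signal with known isolated peaks (triangular bumps on a flat base).
make_spiky_signal <- function(peak_samples, heights, n, base = 0) {
  x <- rep(base, n)
  for (k in seq_along(peak_samples)) {
    p <- peak_samples[k]
    x[p] <- base + heights[k]
    if (p > 1) x[p - 1] <- base + heights[k] / 2
    if (p < n) x[p + 1] <- base + heights[k] / 2
  }
  x
}

measurements_at <- function(times, speeds, durations = 60, pid = "P1") {
  ts <- as.POSIXct(times, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  gaitbelt:::new_measurements(pid, ts, speeds,
                              rep_len(durations, length(speeds)),
                              rep_len(10L, length(speeds)))
}
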