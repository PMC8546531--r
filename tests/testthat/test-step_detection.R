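test_that("acceleration magnitude removes the gravity baseline", {
  rec <- accel_recording(data.frame(ax = 0, ay = 0, az = rep(1, 10)), 50)
  expect_equal(acceleration_magnitude(rec), rep(0, 10))

  # one (3,4,0) sample among zeros: Pythagorean magnitude 5 before baseline
  s <- data.frame(ax = c(0, 0, 3, 0, 0), ay = c(0, 0, 4, 0, 0), az = 0)
  expect_equal(acceleration_magnitude(accel_recording(s, 50)),
               c(0, 0, 5, 0, 0))

  expect_error(acceleration_magnitude(accel_recording(
    data.frame(ax = numeric(0), ay = numeric(0), az = numeric(0)), 50)),
    class = "gaitbelt_empty_input_error")
})

test_that("magnitude of a noiseless simulated walk matches the closed form", {
  spec <- walk_signal_spec(cadence = 2, duration = 5, sampling_rate = 50,
                           peak_amplitude = 0.5, harmonic_fraction = 0.2,
                           noise_sd = 0)
  sim <- simulate_walk_signal(spec)
  t <- (seq_len(n_samples(sim$recording)) - 1) / 50
  az <- 1 - 0.5 * cos(2 * pi * 2 * t) + 0.1 * cos(4 * pi * 2 * t)
  expect_lt(max(abs(acceleration_magnitude(sim$recording) - (az - median(az)))),
            1e-9)
})

test_that("detector finds sinusoid peaks at the analytic step times", {
  expect_length(detect_steps(rep(0, 100), 50)$step_times, 0)

  # pure 1.8 Hz sinusoid, 10 s, amplitude 0.5 g -> 18 steps within half a sample
  spec <- walk_signal_spec(cadence = 1.8, duration = 10, sampling_rate = 50,
                           peak_amplitude = 0.5, harmonic_fraction = 0,
                           noise_sd = 0)
  sim <- simulate_walk_signal(spec)
  st <- detect_steps(sim$recording,
                     config = detection_config(min_prominence = 0.1))
  expect_length(st$step_times, 18)
  expect_true(all(abs(st$step_times - sim$true_step_times) <= 0.5 / 50 + 1e-12))
})

test_that("peak counts agree with an independent peak finder on clean signals", {
  sim <- simulate_walk_signal(walk_signal_spec(cadence = 1.8, duration = 10,
                                               harmonic_fraction = 0,
                                               noise_sd = 0))
  mag <- acceleration_magnitude(sim$recording)
  ours <- detect_steps(mag, 50, detection_config(smoothing_window = 0))
  ref <- pracma::findpeaks(mag, minpeakdistance = ceiling(0.25 * 50))
  expect_equal(length(ours$step_times), nrow(ref))
})

test_that("peak separation keeps the higher of two close peaks", {
  fs <- 100
  # peaks 0.1 s apart (samples 31 and 41), heights 1 and 0.6
  x <- make_spiky_signal(c(31, 41, 81), c(1, 0.6, 0.8), n = 120)
  cfg <- detection_config(smoothing_window = 0, min_peak_separation = 0.25,
                          min_prominence = 0.05)
  st <- detect_steps(x, fs, cfg)
  expect_equal(st$step_times, c(30, 80) / fs)
  expect_equal(st$step_times,
               (oracle_peaks(x, fs, 0.05, 0.25) - 1) / fs)
})

test_that("detection equals the brute-force peak oracle on random signals", {
  set.seed(42)
  for (case in 1:40) {
    n <- sample(30:120, 1)
    x <- cumsum(rnorm(n, sd = 0.3))              # wandering signal, many peaks
    prom <- runif(1, 0.05, 0.5)
    sep <- sample(c(0.1, 0.2, 0.3), 1)
    fs <- 20
    cfg <- detection_config(smoothing_window = 0, min_peak_separation = sep,
                            min_prominence = prom)
    got <- detect_steps(x, fs, cfg)$step_times
    want <- (oracle_peaks(x, fs, prom, sep) - 1) / fs
    expect_equal(got, want, info = sprintf("case %d", case))
  }
})

test_that("detection is translation-equivariant and scale-invariant above threshold", {
  fs <- 50
  peaks <- c(40, 80, 130, 190)
  x <- make_spiky_signal(peaks, c(0.9, 0.7, 1.0, 0.8), n = 240)
  cfg <- detection_config(smoothing_window = 0)
  base <- detect_steps(x, fs, cfg)$step_times
  # shift by 25 samples (flat padding): every step time shifts by 0.5 s
  shifted <- detect_steps(c(rep(0, 25), x), fs, cfg)$step_times
  expect_equal(shifted, base + 25 / fs)
  # scaling up never removes a detected step
  for (c_mult in c(1.5, 3, 10))
    expect_equal(detect_steps(c_mult * x, fs, cfg)$step_times, base)
})

test_that("zero-noise simulated walks yield exactly the generated step count", {
  for (cad in c(1.0, 1.4, 1.8, 2.2)) {
    sim <- simulate_walk_signal(walk_signal_spec(cadence = cad, duration = 30,
                                                 sampling_rate = 50, noise_sd = 0))
    st <- detect_steps(sim$recording)
    expect_length(st$step_times, length(sim$true_step_times))
  }
})

test_that("step intervals are quantized to the 0.1-s grid with ties up", {
  expect_equal(step_intervals(c(0.0, 0.52, 1.09)), c(0.5, 0.6))
  expect_equal(step_intervals(c(0.0, 0.04)), 0.1)       # post-rounding clamp
  expect_equal(step_intervals(c(0.0, 0.25)), 0.3)       # tie rounds up
  expect_equal(step_intervals(c(0.0, 0.35)), 0.4)       # tie not exactly representable
  expect_error(step_intervals(1.0), class = "gaitbelt_insufficient_steps_error")
  expect_error(step_intervals(c(1, 1)), class = "gaitbelt_validation_error")
})

test_that("quantized intervals stay within 0.05 s of raw differences", {
  set.seed(7)
  for (case in 1:1000) {
    times <- cumsum(runif(sample(2:12, 1), 0.05, 2))
    q <- step_intervals(times)
    raw <- diff(times)
    expect_true(all(abs(q - raw) <= 0.05 + 1e-9 | (q == 0.1 & raw < 0.05)))
    expect_true(all(abs(q * 10 - round(q * 10)) < 1e-9))
    expect_true(all(q >= 0.1))
  }
})

test_that("detection config rejects invalid parameters", {
  expect_error(detection_config(smoothing_window = -1),
               class = "gaitbelt_parameter_error")
  expect_error(detection_config(min_peak_separation = 0),
               class = "gaitbelt_parameter_error")
  expect_error(detection_config(band = c(3, 1)),
               class = "gaitbelt_parameter_error")
  expect_error(detect_steps(rnorm(10), sampling_rate = 0),
               class = "gaitbelt_parameter_error")
})
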