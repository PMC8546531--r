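test_that("daily aggregation averages speeds and sums walking time per date", {
  m <- measurements_at(c("2000-01-03T08:00:00", "2000-01-03T19:00:00"),
                       c(1.0, 1.4), durations = 60)
  d <- aggregate_daily(m)
  expect_equal(nrow(d), 1L)
  expect_equal(d$mean_speed, 1.2)
  expect_equal(d$walking_time, 2.0)
  expect_equal(d$n_measurements, 2L)

  m3 <- measurements_at(c("2000-01-03T08:00:00", "2000-01-04T08:00:00",
                          "2000-01-07T08:00:00"), c(1, 1, 1))
  expect_equal(nrow(aggregate_daily(m3)), 3L)

  mixed <- rbind(m, measurements_at("2000-01-03T09:00:00", 1.1, pid = "P2"))
  expect_error(aggregate_daily(mixed), class = "gaitbelt_input_error")
})

test_that("daily walking time conserves the simulator's total bout time", {
  sim <- simulate_participant_days("P1", days = 14, seed = 3)
  d <- aggregate_daily(sim$measurements)
  expect_equal(sum(d$walking_time) * 60, sum(sim$measurements$duration),
               tolerance = 1e-6)
  expect_equal(sum(d$n_measurements), nrow(sim$measurements))
})

test_that("percentile vs usual gait speed uses median ratio and strict 25% bands", {
  m <- measurements_at(rep("2000-01-03T08:00:00", 3), c(1.1, 1.1, 1.1))
  p <- percentile_vs_usual(m, 1.1)
  expect_equal(p$percentile_vs_usual, 100)
  expect_equal(p$pct_faster25, 0)
  expect_equal(p$pct_slower25, 0)

  m2 <- measurements_at(rep("2000-01-03T08:00:00", 3), c(0.5, 1.0, 2.0))
  p2 <- percentile_vs_usual(m2, 1.0)
  expect_equal(p2$percentile_vs_usual, 100)
  expect_equal(p2$pct_faster25, 100 / 3)
  expect_equal(p2$pct_slower25, 100 / 3)

  # exactly +/-25% is not "more than 25%"
  m3 <- measurements_at(rep("2000-01-03T08:00:00", 2), c(1.25, 0.75))
  p3 <- percentile_vs_usual(m3, 1.0)
  expect_equal(p3$pct_faster25 + p3$pct_slower25, 0)

  expect_error(percentile_vs_usual(m, 0), class = "gaitbelt_parameter_error")
})

test_that("percentile counts match a brute-force scan on simulated data", {
  sim <- simulate_participant_days("P1", days = 28,
                                   measurements_per_day = 360, seed = 9)
  m <- sim$measurements
  usual <- 1.24
  p <- percentile_vs_usual(m, usual)
  r <- 100 * m$speed / usual
  expect_identical(p$pct_faster25, 100 * sum(r > 125) / nrow(m))
  expect_identical(p$pct_slower25, 100 * sum(r < 75) / nrow(m))
  expect_identical(p$percentile_vs_usual, median(r))
  expect_identical(p$percentile_vs_usual, 100 * median(m$speed) / usual)
})

test_that("diurnal profile bins by hour and reports empty bins as missing", {
  m <- measurements_at(rep("2000-01-03T06:00:00", 5), rep(1.2, 5))
  prof <- diurnal_profile(m)
  expect_equal(prof$n[prof$bin == "[5,7)"], 5L)
  expect_true(all(is.na(prof$mean_speed[prof$bin != "[5,7)"])))

  m2 <- measurements_at(c("2000-01-03T02:00:00", "2000-01-03T10:00:00",
                          "2000-01-03T10:30:00"), c(1.0, 1.2, 1.4))
  prof2 <- diurnal_profile(m2, bin_edges = c(0, 6, 12, 18))
  expect_equal(prof2$mean_speed, c(1.0, 1.3, NA, NA))

  expect_error(diurnal_profile(m, bin_edges = c(5, 3)),
               class = "gaitbelt_parameter_error")
  expect_error(diurnal_profile(m, bin_edges = c(1, 25)),
               class = "gaitbelt_parameter_error")
})

test_that("bin-weighted diurnal means recover the pooled mean exactly", {
  sim <- simulate_participant_days("P1", days = 7, seed = 13)
  prof <- diurnal_profile(sim$measurements)
  keep <- prof$n > 0
  expect_equal(sum(prof$mean_speed[keep] * prof$n[keep]) / sum(prof$n),
               mean(sim$measurements$speed))
})

test_that("hours after midnight fall into the wrapping [23,1) bin", {
  m <- measurements_at(c("2000-01-03T23:30:00", "2000-01-04T00:30:00"),
                       c(1.0, 1.2))
  prof <- diurnal_profile(m)
  expect_equal(prof$n[prof$bin == "[23,1)"], 2L)
})

test_that("the fastest time-of-day bin is 5-7 AM on diurnal cohorts", {
  set.seed(101)
  hits <- 0L
  for (run in 1:100) {
    streams <- lapply(1:6, function(i)
      simulate_participant_days(paste0("P", i), days = 28,
                                base_speed = rnorm(1, 1.23, 0.08),
                                seed = NULL)$measurements)
    pooled <- do.call(rbind, streams)
    pooled$participant_id <- "pooled"
    prof <- diurnal_profile(pooled)
    if (identical(prof$bin[which.max(prof$mean_speed)], "[5,7)"))
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("weekday/weekend split partitions by calendar day", {
  sat <- measurements_at(rep("2000-01-08T10:00:00", 3), c(1, 1.1, 1.2))
  w <- weekly_split(sat)
  expect_true(is.na(w$weekday_mean))
  expect_equal(w$weekend_mean, 1.1)

  mw <- rbind(measurements_at("2000-01-03T10:00:00", 1.3),   # Monday
              measurements_at("2000-01-09T10:00:00", 1.1))   # Sunday
  w2 <- weekly_split(mw)
  expect_equal(w2$weekday_mean, 1.3)
  expect_equal(w2$weekend_mean, 1.1)
  # walking minutes normalise by distinct days in each partition
  expect_equal(w2$weekday_walk_min, 1)
  expect_equal(w2$weekend_walk_min, 1)
})

test_that("a +0.01 m/s weekday effect is recovered in direction", {
  set.seed(202)
  hits <- 0L
  n_runs <- 20L
  for (run in seq_len(n_runs)) {
    streams <- lapply(1:50, function(i)
      simulate_participant_days(paste0("P", i), days = 28,
                                base_speed = rnorm(1, 1.23, 0.08),
                                weekday_effect = 0.01,
                                measurements_per_day = 100,
                                seed = NULL)$measurements)
    pooled <- do.call(rbind, streams)
    pooled$participant_id <- "pooled"
    w <- weekly_split(pooled)
    if (w$weekday_mean > w$weekend_mean) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_runs))
})

test_that("participant profile assembles dispersion, calendar and eligibility fields", {
  # 9 wear-days -> not eligible at the default 10-day threshold
  times <- sprintf("2000-01-%02dT10:00:00", 3:11)
  m <- measurements_at(times, rep(1.0, 9))
  prof <- gait_profile(m)
  expect_equal(prof$wear_days, 9L)
  expect_false(prof$eligible)
  # adding a wear-day can only turn eligibility on
  m10 <- rbind(m, measurements_at("2000-01-12T10:00:00", 1.0))
  expect_true(gait_profile(m10)$eligible)

  expect_equal(prof$sd, 0)
  expect_equal(prof$cv, 0)
  expect_error(gait_profile(m[0, ]), class = "gaitbelt_empty_profile_error")
  expect_error(gait_profile(m, min_wear_days = 0),
               class = "gaitbelt_parameter_error")
})

test_that("profile statistics concentrate on the generator mean at large n", {
  sim <- simulate_participant_days("P1", days = 28, base_speed = 1.23,
                                   weekday_effect = 0, seed = 17)
  expect_gt(nrow(sim$measurements), 1800)
  prof <- gait_profile(sim$measurements, usual_gait_speed = 1.24)
  expect_lt(abs(prof$mean - 1.23), 0.02)
  expect_equal(prof$cv, 100 * prof$sd / prof$mean)
  expect_identical(prof$percentile_vs_usual,
                   100 * median(sim$measurements$speed) / 1.24)
})
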