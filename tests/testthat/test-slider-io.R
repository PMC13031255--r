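test_that("slider logs parse, validate and round-trip", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("device_time_ms,host_time_s,value",
               "0,0,0", "4,0.004,10", "8,0.008,255"), f)
  log <- parse_slider_log(f)
  expect_identical(nrow(log), 3L)
  expect_identical(log$value, c(0L, 10L, 255L))

  writeLines(c("device_time_ms,host_time_s,value",
               "0,0,0", "4,0.004,300"), f)
  expect_error(parse_slider_log(f), "row 2")
  writeLines(c("device_time_ms,host_time_s,value",
               "0,0,0", "4,0.004,9", "3,0.008,9"), f)
  expect_error(parse_slider_log(f), "row 3")

  p <- quiet_participant(1, drift_ppm = 250)
  sim <- simulate_trial(p, 2, 5, fs = 50, seed = 1)
  write_slider_log(sim$log, f)
  back <- parse_slider_log(f)
  expect_equal(back$device_time_ms, sim$log$device_time_ms)
  expect_identical(back$value, sim$log$value)
})

test_that("clock drift is estimated from paired timestamps", {
  p <- quiet_participant(2, drift_ppm = 400)
  sim <- simulate_trial(p, 1, 30, fs = 50, seed = 1)
  fit <- estimate_clock_drift(sim$log)
  expect_equal(fit$rate_ratio, 1.0004, tolerance = 1e-7)
  expect_equal(fit$drift_fraction, 4e-4, tolerance = 1e-7)
  expect_lt(fit$max_residual, 1e-9)

  # identical clocks: unit ratio, constant offset
  log0 <- data.frame(device_time_ms = (0:99) * 4 + 500,
                     host_time_s = (0:99) * 0.004, value = 0L)
  fit0 <- estimate_clock_drift(log0)
  expect_equal(fit0$rate_ratio, 1)
  expect_equal(fit0$offset, 0.5)

  # the device leads by 15 ms after 30 s at the 0.05% bound
  expect_equal(30 * 5e-4, 0.015)
  expect_error(estimate_clock_drift(log0[1, ]), "at least 2")
})

test_that("drift correction brings timestamps within one sample period", {
  p <- quiet_participant(3, drift_ppm = 500)
  sim <- simulate_trial(p, 1, 30, fs = 250, seed = 2)
  fit <- estimate_clock_drift(sim$log)
  corrected <- (sim$log$device_time_ms / 1000 - fit$offset) / fit$rate_ratio
  expect_lt(max(abs(corrected - sim$log$host_time_s)), 0.004)
  # uncorrected end-of-trial discrepancy exceeds a sample period
  expect_gt(max(abs(sim$log$device_time_ms / 1000 - sim$log$host_time_s)),
            0.004)
})

test_that("traces are normalized, resampled by hold, and recover the latent", {
  log <- data.frame(device_time_ms = (0:49) * 4, host_time_s = (0:49) * 0.004,
                    value = 255L)
  tr <- to_trace(log, fs = 250)
  expect_true(all(tr$values == 1))

  p <- quiet_participant(4)
  sim <- simulate_trial(p, 1, 29, seed = 3)
  tr29 <- to_trace(sim$log, fs = 250, duration_s = 29)
  expect_identical(length(tr29$values), 7250L)
  expect_lt(max(abs(tr29$values - sim$latent$values)), 1 / 255 + 1e-9)

  # hold semantics: a single change at t = 1 s gives a step function
  step_log <- data.frame(device_time_ms = c(0, 1000, 2000),
                         host_time_s = c(0, 1, 2), value = c(0L, 255L, 255L))
  trs <- to_trace(step_log, fs = 10, duration_s = 2)
  oracle <- stats::approx(c(0, 1, 2), c(0, 1, 1), xout = (0:19) / 10,
                          method = "constant", f = 0, rule = 2)$y
  expect_equal(trs$values, oracle)

  # per-trial min-max normalization option
  part <- data.frame(device_time_ms = (0:3) * 4, host_time_s = (0:3) * 0.004,
                     value = c(50L, 100L, 150L, 100L))
  trn <- to_trace(part, fs = 250, normalize = "trial", duration_s = 0.012)
  expect_equal(range(trn$values), c(0, 1))
})

test_that("expected sample counts use half-up rounding", {
  expect_identical(expected_sample_count(29, 250), 7250L)
  expect_identical(expected_sample_count(14.55, 250), 3638L)
  expect_identical(expected_sample_count(10.93, 250), 2733L)
  expect_identical(expected_sample_count(7.28, 250), 1820L)
  expect_identical(expected_sample_count(5.81, 250), 1453L)
  expect_identical(expected_sample_count(0, 250), 0L)
  expect_error(expected_sample_count(-1, 250), "non-negative")
})

test_that("median score matches a sort-based oracle", {
  expect_equal(median_score(const_trace(0.6)), 0.6)
  ramp <- slider_trace(seq(0, 1, length.out = 101), fs = 250)
  expect_equal(median_score(ramp), 0.5)
  set.seed(1)
  v <- runif(251)
  tr <- slider_trace(v, fs = 250)
  sorted <- sort(v)
  expect_equal(median_score(tr), sorted[126])
})

test_that("initial-movement cropping uses the per-rate cutoffs", {
  tr <- const_trace(0.5, n = 7250, fs = 250)
  cropped <- crop_initial_movement(tr, rate = 1)
  expect_equal(length(cropped$values) / 250, 24)
  expect_equal(cropped$t0, 5)

  tr5 <- const_trace(0.5, n = expected_sample_count(5.81, 250), fs = 250)
  c5 <- crop_initial_movement(tr5, rate = 5)
  expect_equal(length(c5$values) / 250, 5.81 - 1.5, tolerance = 1 / 250)

  same <- crop_initial_movement(tr5, rate = 5, cutoffs = c(`5` = 0))
  expect_identical(same$values, tr5$values)
  expect_error(crop_initial_movement(const_trace(0.5, n = 10, fs = 250), 1),
               "cutoff")
})

test_that("differentials are first differences", {
  expect_true(all(differential(const_trace(0.3)) == 0))
  ramp <- slider_trace(seq(0, 0.99, by = 0.01), fs = 100)
  expect_equal(differential(ramp), rep(0.01, 99))
  set.seed(2)
  v <- runif(40)
  expect_equal(differential(slider_trace(v, fs = 10)),
               v[-1] - v[-length(v)])
  expect_error(differential(const_trace(1, n = 1)), "at least 2")
})

test_that("pentile trace scores partition the trace", {
  ramp <- slider_trace(seq(0, 1, length.out = 10), fs = 10)
  expect_true(all(diff(pentile_trace_scores(ramp)) > 0))
  expect_equal(pentile_trace_scores(const_trace(0.4)), rep(0.4, 5))
  idx13 <- compslide:::pentile_index(13)
  expect_identical(as.integer(table(idx13)), c(3L, 3L, 3L, 2L, 2L))
  # bins concatenate back to the trace
  set.seed(3)
  v <- runif(13)
  expect_identical(unlist(split(v, idx13), use.names = FALSE), v)
})

test_that("movement outlier check flags extreme participants", {
  mk <- function(id, scale = 1) {
    set.seed(42)  # identical movement pattern for every clone
    structure(list(participant_id = id,
                   trace = slider_trace(clip01(cumsum(rnorm(200, 0, 0.01)) *
                                                 scale), fs = 50)),
              class = "trial_record")
  }
  clip01 <- function(x) pmin(1, pmax(0, x))
  clones <- lapply(sprintf("p%02d", 1:30), mk)
  none <- movement_outlier_check(clones)
  expect_false(any(none$flagged))

  spiky <- c(lapply(sprintf("p%02d", 1:29), mk), list(mk("p30", scale = 10)))
  flags <- movement_outlier_check(spiky)
  expect_identical(flags$participant_id[flags$flagged], "p30")

  loose <- movement_outlier_check(spiky, threshold = 1.0)
  expect_gte(sum(loose$flagged), sum(flags$flagged))
  expect_error(movement_outlier_check(clones[1]), "2 participants")
})
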