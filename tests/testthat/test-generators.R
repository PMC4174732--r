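test_that("noise-free timekeeper process is exactly isochronous", {
  s <- gen_event_based(500, timekeeper_sd = 0, motor_delay_sd = 0,
                       n = 100, seed = 1)
  expect_identical(length(s), 100L)
  expect_true(all(durations(s) == 500))
  expect_identical(s$regime, "event_based")
})

test_that("event-based autocovariance follows the two-level closed form", {
  # lag-one autocorrelation -sd_M^2 / (sd_T^2 + 2 sd_M^2)
  cases <- list(
    list(sd_t = 0, sd_m = 10, rho1 = -0.5),
    list(sd_t = 20, sd_m = 10, rho1 = -100 / 600),
    list(sd_t = 10, sd_m = 10, rho1 = -100 / 300)
  )
  for (cs in cases) {
    s <- gen_event_based(500, cs$sd_t, cs$sd_m, n = 1e5, seed = 42)
    expect_within(lag_one_autocorr(s), cs$rho1, 0.02)
    expect_within(lag_one_autocorr(s, lag = 2), 0, 0.02)
    expect_within(lag_one_autocorr(s, lag = 3), 0, 0.02)
  }
})

test_that("emergent process matches its AR(1) autocorrelation at every lag", {
  s0 <- gen_emergent(500, ar_coefficient = 0, innovation_sd = 10,
                     n = 1e5, seed = 7)
  expect_within(lag_one_autocorr(s0), 0, 0.02)
  s4 <- gen_emergent(500, ar_coefficient = 0.4, innovation_sd = 10,
                     n = 1e5, seed = 8)
  for (k in 1:3) {
    expect_within(lag_one_autocorr(s4, lag = k), 0.4^k, 0.02)
  }
  const <- gen_emergent(500, 0.3, innovation_sd = 0, n = 50, seed = 9)
  expect_true(all(durations(const) == 500))
})

test_that("generators reject invalid parameters", {
  expect_error(gen_event_based(500, 10, 10, n = 1, seed = 1), "at least 2")
  expect_error(gen_event_based(500, -1, 10, n = 10, seed = 1), "non-negative")
  expect_error(gen_event_based(-5, 1, 1, n = 10, seed = 1), "positive")
  expect_error(gen_emergent(500, 0.5, 10, n = 10, seed = 1), "0, 0.5")
  expect_error(gen_emergent(500, -0.1, 10, n = 10, seed = 1), "0, 0.5")
  expect_error(gen_switching(list(), seed = 1), "non-empty")
})

test_that("identical parameters and seed give bit-identical series", {
  a <- gen_event_based(500, 20, 10, n = 1000, seed = 11)
  b <- gen_event_based(500, 20, 10, n = 1000, seed = 11)
  expect_identical(durations(a), durations(b))
  c1 <- gen_emergent(500, 0.3, 10, n = 1000, seed = 12)
  c2 <- gen_emergent(500, 0.3, 10, n = 1000, seed = 12)
  expect_identical(durations(c1), durations(c2))
})

test_that("a single-segment switching series reproduces the plain generator", {
  seg <- list(list(process = "event_based", mean_interval = 500,
                   timekeeper_sd = 20, motor_delay_sd = 10, n = 200))
  sw <- gen_switching(seg, seed = 5)
  eb <- gen_event_based(500, 20, 10, n = 200, seed = 5)
  expect_identical(durations(sw), durations(eb))
  expect_identical(sw$regime, "event_based")
})

test_that("zero-noise switching segments form a step function with labels", {
  sw <- gen_switching(list(
    list(process = "event_based", mean_interval = 400,
         timekeeper_sd = 0, motor_delay_sd = 0, n = 10),
    list(process = "emergent", mean_interval = 600,
         ar_coefficient = 0, innovation_sd = 0, n = 10)
  ), seed = 1)
  expect_identical(durations(sw), c(rep(400, 10), rep(600, 10)))
  expect_identical(sw$regime, "switching")
  expect_identical(sw$regime_labels,
                   c(rep("event_based", 10), rep("emergent", 10)))
})

test_that("windowed autocorrelation flips sign across a regime switch", {
  segs <- list(
    list(process = "event_based", mean_interval = 500,
         timekeeper_sd = 20, motor_delay_sd = 10, n = 200),
    list(process = "emergent", mean_interval = 500,
         ar_coefficient = 0.4, innovation_sd = 10, n = 200)
  )
  ok <- vapply(1:50, function(r) {
    sw <- gen_switching(segs, seed = 100 + r)
    w <- windowed_lag_one(sw, window_length = 30)
    # windows fully inside each regime
    mean(w[1:171] < 0) > 0.5 && mean(w[201:371] > 0) > 0.5
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("noise-free traces put minima exactly on interval boundaries", {
  tr <- gen_accel_trace(rep(500, 20), sample_rate = 200, noise_sd = 0,
                        seed = 1, pad_s = 0)
  ev <- detect_flexion_minima(tr, extraction_config(trim_seconds = 0))
  expect_equal(diff(ev), rep(0.5, length(ev) - 1), tolerance = 1e-6)
  # 500 ms at 200 Hz: spacing of exactly 100 samples
  expect_equal(diff(ev) * 200, rep(100, length(ev) - 1), tolerance = 1e-4)
})

test_that("trace generation rejects degenerate inputs", {
  expect_error(gen_accel_trace(numeric(0)), "non-empty")
  expect_error(gen_accel_trace(rep(500, 5), sample_rate = 0), "positive")
})

test_that("a zero-variance design reproduces expected durations exactly", {
  des <- small_design(within_individual_sd = 0, within_set_sd = 0,
                      residual_sd_nktt = 0, mean_error_slow = 0,
                      tempo_effect = 0)
  st <- gen_study(des, seed = 3)
  expect_equal(st$observations$duration_ms, st$observations$expected_ms)
})

test_that("the same seed reproduces the identical study", {
  des <- small_design()
  a <- gen_study(des, seed = 21)
  b <- gen_study(des, seed = 21)
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations$duration_ms,
                         gen_study(des, seed = 22)$observations$duration_ms))
})

test_that("pooled residual variances converge to the design ratio", {
  des <- study_design(n_subjects = 2, sets_per_case = 40,
                      intervals_per_set = 200,
                      reference_tempi_ms = c(937.21, 340.95),
                      within_individual_sd = 0, within_set_sd = 0,
                      mean_error_slow = 0, tempo_effect = 0,
                      ktt_variance_ratio = 0.8635)
  st <- gen_study(des, seed = 33)
  o <- st$observations
  v <- tapply(o$error_s, o$case, stats::var)
  expect_equal(unname(v[["KTT"]] / v[["N/KTT"]]), 0.8635, tolerance = 0.05)
})

test_that("study errors carry the event-based lag-one signature", {
  des <- study_design(n_subjects = 1, sets_per_case = 2,
                      intervals_per_set = 5000,
                      reference_tempi_ms = 937.21,
                      within_individual_sd = 0, within_set_sd = 0)
  st <- gen_study(des, seed = 14)
  rho <- vapply(st$sets, lag_one_autocorr, numeric(1))
  expect_within(mean(rho), -1 / 6, 0.03)
})
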