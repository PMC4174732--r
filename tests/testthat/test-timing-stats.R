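test_that("coefficient of variation matches its definition and scale-invariance", {
  expect_equal(coefficient_of_variation(c(500, 500, 500)), 0)
  expect_equal(coefficient_of_variation(c(400, 500, 600)), 20)
  set.seed(1)
  for (r in 1:10) {
    x <- runif(50, 300, 900)
    k <- runif(1, 0.1, 10)
    expect_equal(coefficient_of_variation(k * x), coefficient_of_variation(x))
  }
  expect_error(coefficient_of_variation(500), "at least 2")
})

test_that("lag-one autocorrelation matches stats::acf and known series", {
  set.seed(2)
  for (r in 1:20) {
    x <- rnorm(200, 500, 40)
    expect_equal(lag_one_autocorr(x),
                 unname(stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]),
                 tolerance = 1e-12)
  }
  alt <- rep(c(450, 550), 500)
  expect_equal(lag_one_autocorr(alt), -1, tolerance = 0.02)
  set.seed(3)
  expect_equal(lag_one_autocorr(rnorm(1e5, 500, 20)), 0, tolerance = 0.02)
  expect_error(lag_one_autocorr(rep(500, 50)), "zero-variance")
  expect_error(lag_one_autocorr(c(1, 2)), "too short")
})

test_that("windowed series has the expected count and matches per-window slices", {
  set.seed(4)
  x <- rnorm(100, 500, 30)
  expect_length(windowed_lag_one(x[1:31], window_length = 30), 2)
  w <- windowed_lag_one(x, window_length = 30)
  expect_length(w, 71)
  for (i in c(1, 25, 71)) {
    expect_equal(w[i], lag_one_autocorr(x[i:(i + 29)]))
  }
  # count arithmetic for arbitrary window/step combinations
  for (cfg in list(c(100, 30, 5), c(64, 10, 3), c(40, 12, 12))) {
    wi <- windowed_lag_one(rnorm(cfg[1], 500, 10), cfg[2], cfg[3])
    expect_length(wi, floor((cfg[1] - cfg[2]) / cfg[3]) + 1)
  }
  expect_error(windowed_lag_one(x[1:20], window_length = 30), "shorter")
  wn <- windowed_lag_one(x, window_length = 30, nested_mean = TRUE)
  expect_length(wn, 71 - 30 + 1)
  expect_equal(wn[1], mean(w[1:30]))
})

test_that("sliding windows of a stationary AR(1) stay mostly positive", {
  pos <- vapply(1:100, function(r) {
    s <- gen_emergent(500, 0.4, 10, n = 2000, seed = 500 + r)
    mean(windowed_lag_one(s, window_length = 30)) > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})

test_that("windowed summary obeys the Fisher-Z and percentage contracts", {
  s0 <- summarize_wgamma(rep(0, 10))
  expect_equal(s0$mean_wgamma, 0)
  expect_equal(s0$pct_positive, 0)
  expect_equal(s0$pct_negative, 100)
  s1 <- summarize_wgamma(c(0.2, 0.2, 0.2))
  expect_equal(s1$mean_wgamma, 0.2)
  expect_equal(s1$pct_positive, 100)
  s2 <- summarize_wgamma(c(-0.5, 0.5))
  expect_equal(s2$mean_wgamma, 0)  # atanh antisymmetry
  expect_equal(s2$pct_positive, 50)
  expect_warning(s3 <- summarize_wgamma(c(1, 0.2)), "clipped")
  expect_true(is.finite(s3$mean_wgamma))
  # the two percentages always sum to 100, and the Z-mean is
  # permutation invariant
  set.seed(5)
  for (r in 1:10) {
    w <- runif(40, -0.9, 0.9)
    a <- summarize_wgamma(w)
    b <- summarize_wgamma(sample(w))
    expect_equal(a$pct_positive + a$pct_negative, 100)
    expect_equal(a$mean_wgamma, b$mean_wgamma)
  }
})

test_that("differential percent reproduces the taped-vs-untaped comparison", {
  d <- differential_percent(38.57, 24.73)
  expect_equal(d$difference, 13.84)
  expect_equal(d$equivalent_increase, 55.96)
  d2 <- differential_percent(45.26, 38.91)
  expect_equal(d2$difference, 6.35)
  expect_equal(d2$equivalent_increase, 16.32)
  expect_identical(differential_percent(40, 40),
                   list(difference = 0, equivalent_increase = 0))
  expect_error(differential_percent(120, 10), "0, 100")
  expect_error(differential_percent(10, 0), "undefined")
  expect_identical(differential_percent(0, 0),
                   list(difference = 0, equivalent_increase = 0))
})

test_that("timing-mode classification separates the two processes", {
  eb <- gen_event_based(500, 20, 10, n = 500, seed = 61)
  em <- gen_emergent(500, 0.4, 10, n = 500, seed = 62)
  mode_of <- function(s) {
    classify_timing_mode(summarize_wgamma(windowed_lag_one(s, 30), 30))
  }
  expect_identical(mode_of(eb), "event_based")
  expect_identical(mode_of(em), "emergent")
  # a boundary summary with zero mean is mixed
  sm <- summarize_wgamma(c(-0.3, 0.3))
  expect_identical(classify_timing_mode(sm), "mixed")
})
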