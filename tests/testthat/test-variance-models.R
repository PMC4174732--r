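test_that("variance ratio reproduces the printed factor-specific ratios", {
  expect_equal(variance_ratio(0.0006625549, 0.00076729), 0.8635)
  expect_equal(variance_ratio(0.0008080108, 0.00085849), 0.9412)
  expect_equal(variance_ratio(0.0007996383, 0.00082369), 0.9708)
  expect_equal(variance_ratio(3e-4, 3e-4), 1.0)
  expect_error(variance_ratio(0, 1e-4), "positive")
  expect_error(variance_ratio(1e-4, -1), "positive")
})

test_that("with negligible random effects the fit reduces to pooled group variances", {
  des <- small_design(n_subjects = 8, sets_per_case = 8,
                      intervals_per_set = 40,
                      within_individual_sd = 0, within_set_sd = 0,
                      ktt_variance_ratio = 0.5, regime = "event_based")
  mf <- study_frame(des, seed = 41)
  fit <- suppressWarnings(fit_hetero_lmm(mf))
  # oracle: pooled variance of responses around case x speed cell means
  cell <- interaction(mf$case, mf$speed)
  resid <- mf$response - ave(mf$response, cell)
  oracle <- stats::var(resid[mf$case == "KTT"]) /
    stats::var(resid[mf$case == "N/KTT"])
  expect_equal(fit$variance_ratio, oracle, tolerance = 0.02)
})

test_that("the ratio estimate is consistent under homoscedastic truth", {
  des <- study_design(n_subjects = 10, sets_per_case = 8,
                      intervals_per_set = 40,
                      reference_tempi_ms = c(937.21, 340.95, 750.19, 370.37),
                      ktt_variance_ratio = 1)
  fit <- fit_hetero_lmm(study_frame(des, seed = 52))  # 6400 observations
  expect_gte(fit$variance_ratio, 0.9)
  expect_lte(fit$variance_ratio, 1.1)
})

test_that("a single study fit recovers the generating parameters", {
  des <- study_design(n_subjects = 25)  # full-scale defaults
  fit <- fit_hetero_lmm(study_frame(des, seed = 63))
  expect_lte(fit$variance_ratio_ci[1], des$ktt_variance_ratio)
  expect_gte(fit$variance_ratio_ci[2], des$ktt_variance_ratio)
  expect_equal(fit$within_individual_sd, des$within_individual_sd,
               tolerance = 0.4)
  expect_equal(fit$within_set_sd, des$within_set_sd, tolerance = 0.2)
  expect_equal(fit$residual_sd_nktt, des$residual_sd_nktt, tolerance = 0.05)
  # fixed effects carry ordered CIs and the slow-tempo mean error sign
  fx <- fit$fixed_effects
  expect_true(all(fx$lower < fx$upper))
  expect_lt(fx$estimate[fx$term == "(Intercept)"], 0)
})

test_that("estimates are invariant to subject and set relabeling", {
  des <- small_design()
  mf <- study_frame(des, seed = 77)
  fit1 <- suppressWarnings(fit_hetero_lmm(mf))
  mf2 <- mf
  perm <- sample(unique(mf$subject))
  mf2$subject <- paste0("X", match(mf$subject, perm))
  mf2$set <- paste0("set", as.integer(factor(mf$set)))
  fit2 <- suppressWarnings(fit_hetero_lmm(mf2))
  expect_equal(fit2$variance_ratio, fit1$variance_ratio, tolerance = 1e-6)
  expect_equal(fit2$log_likelihood, fit1$log_likelihood, tolerance = 1e-6)
})

test_that("the heteroscedastic term never lowers the restricted likelihood", {
  des <- small_design(ktt_variance_ratio = 1)
  for (s in 1:5) {
    mf <- study_frame(des, seed = 80 + s)
    full <- suppressWarnings(fit_hetero_lmm(mf))
    restricted <- suppressWarnings(fit_hetero_lmm(mf, heteroscedastic = FALSE))
    lrt <- lrt_heteroscedasticity(restricted, full)
    expect_gte(lrt$statistic, 0)
    expect_gte(lrt$p_value, 0)
    expect_lte(lrt$p_value, 1)
  }
})

test_that("the LRT rejects mismatched fits and detects a real variance ratio", {
  des <- small_design()
  mf_a <- study_frame(des, seed = 91)
  mf_b <- study_frame(des, seed = 92)
  full_a <- suppressWarnings(fit_hetero_lmm(mf_a))
  restr_b <- suppressWarnings(fit_hetero_lmm(mf_b[1:500, ],
                                             heteroscedastic = FALSE))
  expect_error(lrt_heteroscedasticity(restr_b, full_a), "same data")
  expect_error(lrt_heteroscedasticity(full_a, full_a), "homoscedastic")
  # power at a strong ratio with a moderate design
  des6 <- study_design(n_subjects = 10, sets_per_case = 8,
                       intervals_per_set = 30,
                       reference_tempi_ms = c(937.21, 340.95, 750.19, 370.37),
                       ktt_variance_ratio = 0.6)
  rej <- suppressWarnings(
    lrt_rejection_simulation(n_reps = 25, design = des6, seed = 700))
  expect_gte(rej$rejection_rate, 0.8)
})

test_that("the windowed-autocorrelation ANOVA detects a taping shift in Z means", {
  sim_anova <- function(seed, shift_ktt = 0, shift_inter = 0) {
    set.seed(seed)
    g <- expand.grid(subject = sprintf("S%02d", 1:25), set = 1:4,
                     case = c("N/KTT", "KTT"), speed = c("slow", "fast"))
    g$z <- rnorm(nrow(g), 0, 0.15) +
      rep(rnorm(25, 0, 0.1), times = nrow(g) / 25) +
      shift_ktt * (g$case == "KTT") +
      shift_inter * (g$case == "KTT") * (g$speed == "fast")
    fit_wgamma_anova(g)
  }
  p_ktt <- vapply(1:200, function(r) {
    av <- sim_anova(900 + r, shift_ktt = 0.15)
    av$p_value[av$term == "case"]
  }, numeric(1))
  expect_gte(mean(p_ktt < 0.05), 0.8)
})

test_that("the windowed-autocorrelation ANOVA is calibrated under the null", {
  p_null <- t(vapply(1:100, function(r) {
    set.seed(2000 + r)
    g <- expand.grid(subject = sprintf("S%02d", 1:20), set = 1:2,
                     case = c("N/KTT", "KTT"), speed = c("slow", "fast"))
    g$z <- rnorm(nrow(g), 0, 0.15) + rep(rnorm(20, 0, 0.1), times = nrow(g) / 20)
    fit_wgamma_anova(g)$p_value
  }, numeric(3)))
  # binomial(100, 0.05) bounds per term
  for (j in 1:3) expect_lte(mean(p_null[, j] < 0.05), 0.12)
})

test_that("an interaction-only shift loads on the interaction term", {
  hits <- t(vapply(1:50, function(r) {
    set.seed(3000 + r)
    g <- expand.grid(subject = sprintf("S%02d", 1:25), set = 1:4,
                     case = c("N/KTT", "KTT"), speed = c("slow", "fast"))
    # opposite taping shifts for fast vs slow: no marginal case effect
    g$z <- rnorm(nrow(g), 0, 0.15) +
      0.15 * (g$case == "KTT") * ifelse(g$speed == "fast", 1, -1)
    av <- fit_wgamma_anova(g)
    c(inter = av$p_value[av$term == "case:speed"] < 0.05,
      main = av$p_value[av$term == "case"] < 0.05)
  }, logical(2)))
  expect_gte(mean(hits[, "inter"]), 0.7)
  expect_lt(mean(hits[, "main"]), mean(hits[, "inter"]))
})
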