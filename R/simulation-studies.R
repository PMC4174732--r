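# Replicated simulation studies: parameter recovery, likelihood-ratio
# test calibration, and timing-mode classification accuracy. These are
# the package's evidence that the estimators behave as advertised under
# the generating model.

#' Convert simulated-study observations to a model frame
#'
#' @param study a `simulated_study` from [gen_study()].
#' @return data.frame with `response` (error in s), `subject`, `set`
#'   (unique within subject), `case`, `speed` — the layout
#'   [fit_hetero_lmm()] expects.
#' @export
study_model_frame <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  o <- study$observations
  data.frame(
    response = o$error_s,
    subject = o$subject,
    set = paste(o$case, o$condition, o$set_index, sep = "."),
    case = o$case,
    speed = o$speed,
    stringsAsFactors = FALSE
  )
}

#' Parameter-recovery simulation for the variance ratio
#'
#' Repeatedly simulates a study from `design`, fits the heteroscedastic
#' model, and checks whether the 95% Wald CI of the residual variance
#' ratio covers the design's true ratio.
#'
#' @param n_reps number of replicates.
#' @param design generating [study_design()].
#' @param seed integer base seed; replicate r uses `seed + r`.
#' @return List with `results` (per-replicate ratio, CI, coverage flag)
#'   and `coverage` (proportion of replicates whose CI covers the true
#'   ratio; `NA` CIs count as non-covering).
#' @export
recovery_simulation <- function(n_reps = 200, design = study_design(),
                                seed = 1) {
  rows <- lapply(seq_len(n_reps), function(r) {
    st <- gen_study(design, seed = seed + r)
    fit <- fit_hetero_lmm(study_model_frame(st), heteroscedastic = TRUE)
    ci <- fit$variance_ratio_ci
    data.frame(
      rep = r,
      ratio = fit$variance_ratio,
      lower = ci[1], upper = ci[2],
      covered = is.finite(ci[1]) && is.finite(ci[2]) &&
        ci[1] <= design$ktt_variance_ratio &&
        design$ktt_variance_ratio <= ci[2]
    )
  })
  results <- do.call(rbind, rows)
  list(results = results, coverage = mean(results$covered),
       true_ratio = design$ktt_variance_ratio)
}

#' Rejection rate of the heteroscedasticity likelihood-ratio test
#'
#' Repeatedly simulates from `design`, fits the homoscedastic and
#' heteroscedastic models and applies the LRT. With
#' `ktt_variance_ratio = 1` in the design this measures the test's
#' type-I error; with a ratio away from 1 it measures power.
#'
#' @inheritParams recovery_simulation
#' @param alpha nominal test level.
#' @return List with `p_values` and `rejection_rate` at `alpha`.
#' @export
lrt_rejection_simulation <- function(n_reps = 500, design = study_design(),
                                     seed = 1, alpha = 0.05) {
  p <- vapply(seq_len(n_reps), function(r) {
    st <- gen_study(design, seed = seed + r)
    mf <- study_model_frame(st)
    full <- fit_hetero_lmm(mf, heteroscedastic = TRUE)
    restricted <- fit_hetero_lmm(mf, heteroscedastic = FALSE)
    lrt_heteroscedasticity(restricted, full)$p_value
  }, numeric(1))
  list(p_values = p, rejection_rate = mean(p < alpha), alpha = alpha)
}

#' Timing-mode classification accuracy simulation
#'
#' Simulates event-based and emergent interval series of length `n`,
#' classifies each from its windowed lag-one autocorrelation summary,
#' and reports the per-process accuracy.
#'
#' @param n_reps replicates per process.
#' @param n intervals per series.
#' @param window_length wgamma(1) window length.
#' @param seed integer base seed.
#' @param mean_interval mean duration (ms).
#' @param timekeeper_sd,motor_delay_sd event-based process SDs (ms).
#' @param ar_coefficient,innovation_sd emergent process parameters.
#' @return List with `accuracy_event_based`, `accuracy_emergent` and the
#'   per-replicate classifications.
#' @export
classification_simulation <- function(n_reps = 100, n = 500,
                                      window_length = 30, seed = 1,
                                      mean_interval = 500,
                                      timekeeper_sd = 20, motor_delay_sd = 10,
                                      ar_coefficient = 0.4,
                                      innovation_sd = 10) {
  classify_one <- function(s) {
    classify_timing_mode(summarize_wgamma(
      windowed_lag_one(s, window_length = window_length),
      window_length = window_length))
  }
  eb <- vapply(seq_len(n_reps), function(r) {
    classify_one(gen_event_based(mean_interval, timekeeper_sd, motor_delay_sd,
                                 n, seed = seed + r))
  }, character(1))
  em <- vapply(seq_len(n_reps), function(r) {
    classify_one(gen_emergent(mean_interval, ar_coefficient, innovation_sd,
                              n, seed = seed + n_reps + r))
  }, character(1))
  list(
    accuracy_event_based = mean(eb == "event_based"),
    accuracy_emergent = mean(em == "emergent"),
    modes_event_based = eb,
    modes_emergent = em
  )
}
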