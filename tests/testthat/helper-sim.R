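# Shared builders for desk-scale simulated designs. The tempo list mixes
# slow and fast references so the speed covariate always has both levels.

small_design <- function(...) {
  args <- list(
    n_subjects = 6,
    sets_per_case = 4,
    intervals_per_set = 40,
    reference_tempi_ms = c(937.21, 340.95, 750.19, 370.37)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(study_design, args)
}

# observations of a simulated study in fit_hetero_lmm() layout
study_frame <- function(design, seed) {
  study_model_frame(gen_study(design, seed))
}

# absolute-tolerance comparison for autocorrelations near zero
expect_within <- function(actual, target, tol) {
  expect_lt(abs(actual - target), tol)
}
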