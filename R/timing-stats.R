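# Per-set variability and timing-mode statistics.
#
# Two summary statistics carry the analysis: the coefficient of
# variation of the interval durations (timing precision) and the
# windowed lag-one autocorrelation wgamma(1) (timing mode). A lag-one
# autocorrelation in (-0.5, 0) is the signature of event-based
# (timekeeper) control; a value in (0, 0.5) is the signature of emergent
# control. Computed in sliding windows along the series, the statistic
# tracks changes of timing mode within one performance; per-set
# summaries are the Fisher-Z-averaged mean and the percentage of
# positive windowed values.

#' Coefficient of variation of an interval series
#'
#' @param series an [interval_series] or numeric vector of durations.
#' @return `100 * sd/mean` (percent), with the sample (n-1) SD.
#' @examples
#' coefficient_of_variation(c(400, 500, 600)) # 20
#' @export
coefficient_of_variation <- function(series) {
  x <- durations(series)
  if (length(x) < 2L) stop_domain("need at least 2 intervals for a CV")
  m <- mean(x)
  if (m <= 0) stop_domain("mean duration must be positive")
  100 * stats::sd(x) / m
}

#' Lag-one autocorrelation
#'
#' Sample autocorrelation at lag 1: mean-centered cross-products at lag
#' 1 divided by the lag-0 sum of squares (the standard biased-normalised
#' estimator, as in `stats::acf`).
#'
#' @param series an [interval_series] or numeric vector (length >= 3).
#' @param lag lag at which to evaluate (default 1).
#' @return Autocorrelation coefficient in `[-1, 1]`.
#' @export
lag_one_autocorr <- function(series, lag = 1L) {
  x <- durations(series)
  n <- length(x)
  if (n < lag + 2L) stop_domain("series too short for this lag")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop_domain("zero-variance series: autocorrelation undefined")
  sum(xc[1:(n - lag)] * xc[(1 + lag):n]) / denom
}

#' Windowed lag-one autocorrelation series
#'
#' Computes the lag-one autocorrelation inside each sliding window of
#' `window_length` consecutive intervals, advanced by `step`. With
#' `nested_mean = TRUE` each reported value is instead the mean of
#' `window_length` consecutive base windowed coefficients (a smoothed
#' variant; see the methods vignette for why both readings exist).
#'
#' @param series an [interval_series] or numeric vector.
#' @param window_length window length in intervals (default 30).
#' @param step window advance in intervals (default 1).
#' @param nested_mean report means of `window_length` consecutive
#'   windowed coefficients instead of the coefficients themselves.
#' @return Numeric vector of `floor((n - w)/step) + 1` coefficients
#'   (fewer under `nested_mean`). Zero-variance windows yield `NA`.
#' @export
windowed_lag_one <- function(series, window_length = 30L, step = 1L,
                             nested_mean = FALSE) {
  x <- durations(series)
  n <- length(x)
  if (window_length < 3L) stop_domain("`window_length` must be at least 3")
  if (step < 1L) stop_domain("`step` must be at least 1")
  if (n < window_length + 1L) {
    stop_domain("series shorter than `window_length` + 1")
  }
  starts <- seq.int(1L, n - window_length + 1L, by = step)
  w <- vapply(starts, function(s) {
    win <- x[s:(s + window_length - 1L)]
    if (stats::sd(win) == 0) return(NA_real_)
    lag_one_autocorr(win)
  }, numeric(1))
  if (nested_mean) {
    if (length(w) < window_length) {
      stop_domain("too few windowed values for the nested-mean variant")
    }
    w <- vapply(seq_len(length(w) - window_length + 1L), function(s) {
      mean(w[s:(s + window_length - 1L)])
    }, numeric(1))
  }
  w
}

#' Summarise a windowed lag-one autocorrelation series
#'
#' The per-set summary of wgamma(1): the Fisher-Z-averaged mean (values
#' are atanh-transformed, averaged, and back-transformed, normalising
#' the correlation distribution) and the percentages of positive and
#' negative windowed values. Zero values count as non-positive, so the
#' two percentages always sum to 100. Coefficients at exactly +/-1 are
#' clipped to +/-(1 - 1e-12) with a warning before the transform.
#'
#' @param windowed numeric vector of windowed coefficients (as from
#'   [windowed_lag_one()]); `NA`s are dropped.
#' @param window_length window length used (metadata, default 30).
#' @return A `wgamma_summary`: list with `windowed_values`,
#'   `mean_wgamma` (Fisher-Z mean), `mean_wgamma_raw` (arithmetic mean),
#'   `pct_positive`, `pct_negative`, `window_length`, `n_windows`.
#' @export
summarize_wgamma <- function(windowed, window_length = 30L) {
  w <- windowed[!is.na(windowed)]
  if (length(w) == 0L) stop_domain("need at least one windowed value")
  if (any(abs(w) > 1)) stop_domain("autocorrelations must lie in [-1, 1]")
  if (any(abs(w) == 1)) {
    warning("windowed coefficient at +/-1 clipped before Fisher-Z transform")
    w_t <- sign(w) * pmin(abs(w), 1 - 1e-12)
  } else {
    w_t <- w
  }
  z <- atanh(w_t)
  pct_pos <- 100 * mean(w > 0)
  structure(
    list(
      windowed_values = w,
      z_values = z,
      mean_wgamma = tanh(mean(z)),
      mean_wgamma_raw = mean(w),
      pct_positive = pct_pos,
      pct_negative = 100 - pct_pos,
      window_length = as.integer(window_length),
      n_windows = length(w)
    ),
    class = "wgamma_summary"
  )
}

#' @export
print.wgamma_summary <- function(x, ...) {
  cat(sprintf(
    "<wgamma_summary> %d windows (w=%d): mean wg(1) %.3f (Z-averaged), %.1f%% positive\n",
    x$n_windows, x$window_length, x$mean_wgamma, x$pct_positive
  ))
  invisible(x)
}

#' Differential percent of positive windowed autocorrelations
#'
#' Compares the percentage of positive wgamma(1) values between the
#' taped (KTT) and untaped (N/KTT) cases: the difference in percentage
#' points and the equivalent relative increase over the untaped case.
#'
#' @param pct_ktt percentage of positive values under KTT, in `[0, 100]`.
#' @param pct_nktt percentage of positive values under N/KTT.
#' @return List with `difference` (`pct_ktt - pct_nktt`) and
#'   `equivalent_increase` (`100 * difference / pct_nktt`), both rounded
#'   half-up to 2 decimals.
#' @examples
#' differential_percent(38.57, 24.73) # difference 13.84, increase 55.96
#' @export
differential_percent <- function(pct_ktt, pct_nktt) {
  for (p in c(pct_ktt, pct_nktt)) {
    if (!is.finite(p) || p < 0 || p > 100) {
      stop_domain("percentages must lie in [0, 100]")
    }
  }
  diff_raw <- pct_ktt - pct_nktt
  if (pct_nktt == 0 && diff_raw != 0) {
    stop_domain("equivalent increase undefined: reference percentage is 0")
  }
  list(
    difference = round_half_up(diff_raw, 2),
    equivalent_increase =
      if (diff_raw == 0) 0 else round_half_up(100 * diff_raw / pct_nktt, 2)
  )
}

#' Classify the timing mode of a performance
#'
#' A performance is called event-based when its Z-averaged mean
#' wgamma(1) is negative and at least `threshold_pct` of windowed values
#' are negative; emergent in the mirrored case; mixed otherwise. The
#' percentage threshold is a package convention (the boundary between a
#' dominant and a transient mode is not sharp); it is exposed so callers
#' can tighten or relax it.
#'
#' @param summary a `wgamma_summary`.
#' @param threshold_pct dominance threshold in percent (default 60).
#' @return `"event_based"`, `"emergent"` or `"mixed"`.
#' @export
classify_timing_mode <- function(summary, threshold_pct = 60) {
  stopifnot(inherits(summary, "wgamma_summary"))
  check_scalar_positive(threshold_pct, "threshold_pct")
  if (summary$mean_wgamma < 0 && summary$pct_negative >= threshold_pct) {
    "event_based"
  } else if (summary$mean_wgamma > 0 && summary$pct_positive >= threshold_pct) {
    "emergent"
  } else {
    "mixed"
  }
}
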