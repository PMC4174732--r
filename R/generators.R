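# Synthetic timing-process and study generators.
#
# Two generating models cover the two classical modes of temporal
# control of repetitive movement:
#
#   * event-based timing: a two-level timekeeper model. Interval n is
#     C_n + D_{n+1} - D_n, where C_n are central timekeeper intervals
#     and D_n peripheral motor delays, both iid normal. The differenced
#     delays induce a negative lag-one autocovariance of -sd_D^2, so the
#     lag-one autocorrelation -sd_D^2/(sd_C^2 + 2 sd_D^2) lies in
#     [-0.5, 0], with -0.5 attained when the timekeeper is noiseless.
#
#   * emergent timing: temporal regularity arising from dynamic control
#     rather than an explicit timekeeper; its observable signature is a
#     positive lag-one autocorrelation in (0, 0.5). It is simulated as a
#     stationary AR(1) on the periods, whose lag-k autocorrelation is
#     phi^k: the simplest surrogate with that signature in closed form.

.MAX_RESAMPLE <- 100L

# Core generators draw from the current RNG stream (no seeding) so that
# regime-switching series can share one stream.
.core_event_based <- function(mean_interval, timekeeper_sd, motor_delay_sd, n) {
  ticks <- stats::rnorm(n, 0, timekeeper_sd)
  delays <- stats::rnorm(n + 1L, 0, motor_delay_sd)
  mean_interval + ticks + diff(delays)
}

.core_emergent <- function(mean_interval, ar_coefficient, innovation_sd, n) {
  e <- numeric(n)
  e[1L] <- stats::rnorm(1, 0, innovation_sd / sqrt(1 - ar_coefficient^2))
  if (n > 1L) {
    eta <- stats::rnorm(n - 1L, 0, innovation_sd)
    for (i in 2:n) e[i] <- ar_coefficient * e[i - 1L] + eta[i - 1L]
  }
  mean_interval + e
}

# Redraw the whole series while any duration is non-positive, preserving
# the process autocovariance; physically a movement cannot have a
# non-positive period.
.resample_positive <- function(draw) {
  for (attempt in seq_len(.MAX_RESAMPLE)) {
    d <- draw()
    if (all(d > 0)) {
      if (attempt > 1L) {
        message(sprintf("non-positive durations: resampled series (%d attempts)",
                        attempt))
      }
      return(d)
    }
  }
  stop_domain("could not draw a positive interval series; noise SDs are too large relative to the mean interval")
}

#' Simulate an event-based (timekeeper) interval series
#'
#' @param mean_interval mean interval duration in ms (> 0).
#' @param timekeeper_sd SD of the central timekeeper intervals, ms (>= 0).
#' @param motor_delay_sd SD of the peripheral motor delays, ms (>= 0).
#' @param n number of intervals (>= 2).
#' @param seed integer seed; identical arguments give identical output.
#' @return An [interval_series] with regime `"event_based"`.
#' @examples
#' s <- gen_event_based(500, timekeeper_sd = 20, motor_delay_sd = 10,
#'                      n = 1000, seed = 1)
#' lag_one_autocorr(s) # near -1/6
#' @export
gen_event_based <- function(mean_interval, timekeeper_sd, motor_delay_sd,
                            n, seed) {
  check_scalar_positive(mean_interval, "mean_interval")
  check_scalar_nonneg(timekeeper_sd, "timekeeper_sd")
  check_scalar_nonneg(motor_delay_sd, "motor_delay_sd")
  if (n < 2L) stop_domain("`n` must be at least 2")
  set.seed(seed)
  d <- .resample_positive(function()
    .core_event_based(mean_interval, timekeeper_sd, motor_delay_sd, n))
  interval_series(d, regime = "event_based")
}

#' Simulate an emergent (autoregressive) interval series
#'
#' @param mean_interval mean interval duration in ms (> 0).
#' @param ar_coefficient AR(1) coefficient in `[0, 0.5)`; equals the
#'   stationary lag-one autocorrelation of the series.
#' @param innovation_sd SD of the AR innovations, ms (>= 0).
#' @param n number of intervals (>= 2).
#' @param seed integer seed.
#' @return An [interval_series] with regime `"emergent"`.
#' @export
gen_emergent <- function(mean_interval, ar_coefficient, innovation_sd,
                         n, seed) {
  check_scalar_positive(mean_interval, "mean_interval")
  check_scalar_nonneg(innovation_sd, "innovation_sd")
  if (!is.numeric(ar_coefficient) || length(ar_coefficient) != 1L ||
      ar_coefficient < 0 || ar_coefficient >= 0.5) {
    stop_domain("`ar_coefficient` must lie in [0, 0.5)")
  }
  if (n < 2L) stop_domain("`n` must be at least 2")
  set.seed(seed)
  d <- .resample_positive(function()
    .core_emergent(mean_interval, ar_coefficient, innovation_sd, n))
  interval_series(d, regime = "emergent")
}

#' Simulate a regime-switching interval series
#'
#' Concatenates segments generated by different timing processes from a
#' single RNG stream, recording a per-interval regime label. A series
#' whose timing mode changes over time lets the windowed lag-one
#' classifier be tested against a known switch point.
#'
#' @param segments list of segment specifications. Each element is a list
#'   with `process` (`"event_based"` or `"emergent"`), `n` (>= 2) and the
#'   process parameters (`mean_interval` plus `timekeeper_sd`/
#'   `motor_delay_sd` or `ar_coefficient`/`innovation_sd`).
#' @param seed integer seed. A single event-based segment reproduces
#'   [gen_event_based()] exactly for the same seed.
#' @return An [interval_series] with per-interval `regime_labels`; regime
#'   is the segment's process when there is one segment, `"switching"`
#'   otherwise.
#' @export
gen_switching <- function(segments, seed) {
  if (!is.list(segments) || length(segments) == 0L) {
    stop_domain("`segments` must be a non-empty list of segment specifications")
  }
  set.seed(seed)
  out <- vector("list", length(segments))
  labels <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    if (is.null(sg$n) || sg$n < 2L) stop_domain("each segment needs `n` >= 2")
    check_scalar_positive(sg$mean_interval, "mean_interval")
    d <- switch(sg$process,
      event_based = {
        check_scalar_nonneg(sg$timekeeper_sd, "timekeeper_sd")
        check_scalar_nonneg(sg$motor_delay_sd, "motor_delay_sd")
        .resample_positive(function()
          .core_event_based(sg$mean_interval, sg$timekeeper_sd,
                            sg$motor_delay_sd, sg$n))
      },
      emergent = {
        if (sg$ar_coefficient < 0 || sg$ar_coefficient >= 0.5) {
          stop_domain("`ar_coefficient` must lie in [0, 0.5)")
        }
        check_scalar_nonneg(sg$innovation_sd, "innovation_sd")
        .resample_positive(function()
          .core_emergent(sg$mean_interval, sg$ar_coefficient,
                         sg$innovation_sd, sg$n))
      },
      stop_domain(sprintf("unknown process \"%s\"", sg$process))
    )
    out[[i]] <- d
    labels[[i]] <- rep(sg$process, sg$n)
  }
  regime <- if (length(segments) == 1L) segments[[1L]]$process else "switching"
  interval_series(unlist(out), regime = regime,
                  regime_labels = unlist(labels))
}

#' Synthesize a tri-axial accelerometer trace from an interval series
#'
#' One channel carries a raised-cosine oscillation whose local minima
#' fall exactly on the cumulative interval boundaries (the signal
#' minimum marks maximal wrist flexion); the other two channels are pure
#' noise. When `pad_s > 0` the trace is padded with lead-in and lead-out
#' cycles at the first/last interval's period so that transient trimming
#' in the extraction stage is exercised: all padding minima lie strictly
#' inside the first and last `pad_s` seconds, and the first and last true
#' boundaries sit `min(0.5 s, period/2)` inside the retained region.
#'
#' @param intervals an [interval_series] or numeric vector of durations
#'   (ms); must be non-empty.
#' @param sample_rate sampling rate in Hz (> 0), default 200.
#' @param noise_sd SD of additive white measurement noise (signal units,
#'   where the oscillation has amplitude 1).
#' @param seed integer seed for the noise.
#' @param pad_s lead-in/lead-out padding duration in s (>= 0), default 5.
#' @return An `accel_trace`: list with `time_s`, `channels` (n x 3 matrix,
#'   columns ax/ay/az), `sample_rate`, and a `truth` element holding the
#'   true event times (`boundaries_s`) for validation.
#' @export
gen_accel_trace <- function(intervals, sample_rate = 200, noise_sd = 0,
                            seed = 1, pad_s = 5) {
  d_ms <- durations(intervals)
  if (length(d_ms) == 0L) stop_domain("`intervals` must be non-empty")
  if (any(d_ms <= 0)) stop_domain("interval durations must be positive")
  check_scalar_positive(sample_rate, "sample_rate")
  check_scalar_nonneg(noise_sd, "noise_sd")
  check_scalar_nonneg(pad_s, "pad_s")

  d_s <- d_ms / 1000
  d1 <- d_s[1L]
  dk <- d_s[length(d_s)]

  if (pad_s > 0) {
    m1 <- min(0.5, d1 / 2)
    m2 <- min(0.5, dk / 2)
    lead_total <- pad_s + m1
    k1 <- ceiling(lead_total / d1)
    lead_b <- lead_total - (k1:1) * d1        # ascending; first <= 0
    tail_total <- pad_s + m2
    k2 <- ceiling(tail_total / dk)
  } else {
    lead_total <- 0
    lead_b <- numeric(0)
    tail_total <- 0
    k2 <- 0L
  }

  real_b <- lead_total + c(0, cumsum(d_s))
  t_real_end <- real_b[length(real_b)]
  tail_b <- if (k2 > 0) t_real_end + (1:k2) * dk else numeric(0)
  b_all <- c(lead_b, real_b, tail_b)
  t_total <- t_real_end + tail_total

  n_samp <- floor(t_total * sample_rate + 1e-9) + 1L
  t <- (seq_len(n_samp) - 1L) / sample_rate
  widths <- diff(b_all)
  j <- findInterval(t, b_all)
  j <- pmin(pmax(j, 1L), length(widths))
  phase <- (t - b_all[j]) / widths[j]
  sig <- -cos(2 * pi * phase)

  set.seed(seed)
  ax <- sig + stats::rnorm(n_samp, 0, noise_sd)
  ay <- stats::rnorm(n_samp, 0, noise_sd)
  az <- stats::rnorm(n_samp, 0, noise_sd)

  structure(
    list(
      time_s = t,
      channels = cbind(ax = ax, ay = ay, az = az),
      sample_rate = sample_rate,
      truth = list(boundaries_s = real_b, lead_s = lead_total)
    ),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples at %g Hz (%.1f s), 3 channels\n",
              length(x$time_s), x$sample_rate,
              x$time_s[length(x$time_s)]))
  invisible(x)
}

#' Hierarchical study design
#'
#' Describes the generating model of a full synthetic study: per-interval
#' timing error (s) decomposed as
#' `mean_error_slow + tempo_effect * fast + subject + set + residual`,
#' with normal subject and set random intercepts and a residual series
#' whose marginal SD is `residual_sd_nktt`, multiplied by
#' `sqrt(ktt_variance_ratio)` under taping (KTT). Defaults follow the
#' magnitudes estimated for the paced-clicks condition: within-individual
#' SD 0.0045 s, within-set SD 0.0049 s, residual variance 0.00076729 s^2
#' (N/KTT), KTT residual variance ratio 0.8635, mean error -0.0063 s for
#' slow tempi and +0.0021 s tempo correction for fast tempi.
#'
#' @param n_subjects number of subjects.
#' @param conditions condition labels drawn from Fr, Cl, Cl2, Mu, Mu2.
#' @param reference_tempi_ms reference stimulus periods (ms); sets cycle
#'   through these. Default: the eight tempo-range references.
#' @param cases taping cases; both levels are needed for the
#'   heteroscedastic fit.
#' @param sets_per_case sets performed per subject and case.
#' @param intervals_per_set intervals per set. Default 50: a 60 s set
#'   minus 10 s of trimmed transients spans roughly 53-147 cycles over
#'   the study's tempo range; 50 is the conservative slow-tempo end.
#' @param within_individual_sd subject random-intercept SD (s).
#' @param within_set_sd set random-intercept SD (s).
#' @param residual_sd_nktt marginal residual SD without taping (s).
#' @param ktt_variance_ratio residual variance ratio KTT / N-KTT (> 0).
#' @param mean_error_slow mean timing error at slow tempi (s).
#' @param tempo_effect additive error shift for fast tempi (s).
#' @param regime timing process generating the per-set residual series:
#'   `"event_based"` (lag-one -1/6) or `"emergent"` (AR coefficient
#'   0.25); the marginal residual SD is matched in either case.
#' @param speed_threshold_ms fast/slow boundary (ms).
#' @return A `study_design` list.
#' @export
study_design <- function(n_subjects = 25,
                         conditions = "Cl",
                         reference_tempi_ms = tempo_ranges()$reference_ms,
                         cases = c("N/KTT", "KTT"),
                         sets_per_case = 16,
                         intervals_per_set = 50,
                         within_individual_sd = 0.0045,
                         within_set_sd = 0.0049,
                         residual_sd_nktt = sqrt(0.00076729),
                         ktt_variance_ratio = 0.8635,
                         mean_error_slow = -0.0063,
                         tempo_effect = 0.0021,
                         regime = c("event_based", "emergent"),
                         speed_threshold_ms = 517.33) {
  regime <- match.arg(regime)
  stopifnot(n_subjects >= 1, sets_per_case >= 1, intervals_per_set >= 2)
  if (!all(conditions %in% c("Fr", "Cl", "Cl2", "Mu", "Mu2"))) {
    stop_domain("`conditions` must be drawn from Fr, Cl, Cl2, Mu, Mu2")
  }
  check_scalar_nonneg(within_individual_sd, "within_individual_sd")
  check_scalar_nonneg(within_set_sd, "within_set_sd")
  check_scalar_nonneg(residual_sd_nktt, "residual_sd_nktt")
  check_scalar_positive(ktt_variance_ratio, "ktt_variance_ratio")
  check_scalar_positive(speed_threshold_ms, "speed_threshold_ms")
  if (any(reference_tempi_ms <= 0)) {
    stop_domain("`reference_tempi_ms` must be positive")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      conditions = conditions,
      reference_tempi_ms = reference_tempi_ms,
      cases = cases,
      sets_per_case = as.integer(sets_per_case),
      intervals_per_set = as.integer(intervals_per_set),
      within_individual_sd = within_individual_sd,
      within_set_sd = within_set_sd,
      residual_sd_nktt = residual_sd_nktt,
      ktt_variance_ratio = ktt_variance_ratio,
      mean_error_slow = mean_error_slow,
      tempo_effect = tempo_effect,
      regime = regime,
      speed_threshold_ms = speed_threshold_ms
    ),
    class = "study_design"
  )
}

# Residual series (s) with given marginal SD, drawn from the design's
# timing process so the set's serial structure carries the corresponding
# lag-one signature. Uses the current RNG stream.
.residual_series <- function(regime, sd_s, n) {
  if (sd_s == 0) return(numeric(n))
  if (regime == "event_based") {
    # var = sd_C^2 + 2 sd_D^2 = sd_s^2 with lag-one -1/6:
    # sd_D^2 = sd_s^2/6, sd_C^2 = 2 sd_s^2/3
    .core_event_based(0, sqrt(2 / 3) * sd_s, sd_s / sqrt(6), n)
  } else {
    phi <- 0.25
    .core_emergent(0, phi, sd_s * sqrt(1 - phi^2), n)
  }
}

#' Generate a full hierarchical study dataset
#'
#' Draws subject and set random intercepts, then a per-set residual
#' series from the design's timing process, and assembles per-interval
#' observed durations `expected + 1000 * error_s`. Residual SD under KTT
#' is `residual_sd_nktt * sqrt(ktt_variance_ratio)`. Per-set residual
#' streams are seeded from deterministic substreams of `seed`, so the
#' same seed always reproduces the identical dataset.
#'
#' @param design a [study_design()].
#' @param seed integer seed.
#' @return A `simulated_study`: list with `design`, `seed`, `sets` (list
#'   of [interval_series]) and `observations`, a long data.frame with one
#'   row per interval (subject, case, condition, set_index, expected_ms,
#'   speed, interval_index, duration_ms, error_s, regime).
#' @export
gen_study <- function(design, seed) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  subj_eff <- stats::rnorm(design$n_subjects, 0, design$within_individual_sd)
  n_sets_total <- design$n_subjects * length(design$cases) * design$sets_per_case
  set_eff <- stats::rnorm(n_sets_total, 0, design$within_set_sd)

  sets <- list()
  obs <- vector("list", n_sets_total)
  global_set <- 0L
  for (i in seq_len(design$n_subjects)) {
    subj_id <- sprintf("S%02d", i)
    for (case in design$cases) {
      for (k in seq_len(design$sets_per_case)) {
        global_set <- global_set + 1L
        cond <- design$conditions[(k - 1L) %% length(design$conditions) + 1L]
        tempo <- design$reference_tempi_ms[
          (k - 1L) %% length(design$reference_tempi_ms) + 1L]
        fast <- tempo < design$speed_threshold_ms
        sd_res <- design$residual_sd_nktt *
          if (case == "KTT") sqrt(design$ktt_variance_ratio) else 1
        set.seed(substream_seed(seed, i, global_set))
        resid <- .residual_series(design$regime, sd_res,
                                  design$intervals_per_set)
        err <- design$mean_error_slow + design$tempo_effect * fast +
          subj_eff[i] + set_eff[global_set] + resid
        dur <- tempo + 1000 * err
        if (any(dur <= 0)) {
          stop_domain("design produced non-positive durations; SDs too large relative to tempi")
        }
        s <- interval_series(dur, subject = subj_id, case = case,
                             condition = cond, expected_ms = tempo,
                             set_index = k, regime = design$regime)
        sets[[length(sets) + 1L]] <- s
        obs[[global_set]] <- data.frame(
          subject = subj_id,
          case = case,
          condition = cond,
          set_index = k,
          expected_ms = tempo,
          speed = if (fast) "fast" else "slow",
          interval_index = seq_len(design$intervals_per_set),
          duration_ms = dur,
          error_s = err,
          regime = design$regime,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(
      design = design,
      seed = seed,
      sets = sets,
      observations = do.call(rbind, obs)
    ),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d subjects, %d sets, %d observations (seed %d)\n",
    x$design$n_subjects, length(x$sets), nrow(x$observations), x$seed
  ))
  invisible(x)
}
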