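#' Ordered series of movement intervals
#'
#' The basic unit of analysis: the ordered durations (ms) of consecutive
#' movement cycles in one recorded set, together with the metadata the
#' downstream models need (subject, taping case, condition, expected
#' stimulus duration, tempo rank, and the generating regime when the
#' series is synthetic).
#'
#' @param durations_ms numeric vector of positive interval durations (ms).
#' @param subject subject identifier.
#' @param case taping case, `"N/KTT"` or `"KTT"`.
#' @param condition condition label: `"Fr"`, `"Cl"`, `"Cl2"`, `"Mu"` or
#'   `"Mu2"`.
#' @param expected_ms expected (stimulus) duration in ms; `NA` for the
#'   free condition, which has no external reference tempo.
#' @param set_index index of the set within the session.
#' @param regime generating timing process for synthetic series:
#'   `"event_based"`, `"emergent"` or `"switching"`; `NA` for measured
#'   data.
#' @param regime_labels optional per-interval regime labels (used by
#'   regime-switching series).
#' @return An object of class `interval_series`.
#' @export
interval_series <- function(durations_ms,
                            subject = NA_character_,
                            case = NA_character_,
                            condition = NA_character_,
                            expected_ms = NA_real_,
                            set_index = NA_integer_,
                            regime = NA_character_,
                            regime_labels = NULL) {
  durations_ms <- as.numeric(durations_ms)
  if (length(durations_ms) == 0L) {
    stop_domain("an interval series needs at least one duration")
  }
  if (any(!is.finite(durations_ms)) || any(durations_ms <= 0)) {
    stop_domain("interval durations must be positive and finite")
  }
  if (!is.na(case) && !case %in% c("N/KTT", "KTT")) {
    stop_domain("`case` must be \"N/KTT\" or \"KTT\"")
  }
  if (!is.na(condition) && !condition %in% c("Fr", "Cl", "Cl2", "Mu", "Mu2")) {
    stop_domain("`condition` must be one of Fr, Cl, Cl2, Mu, Mu2")
  }
  if (!is.null(regime_labels) && length(regime_labels) != length(durations_ms)) {
    stop_domain("`regime_labels` must have one label per interval")
  }
  structure(
    list(
      durations_ms = durations_ms,
      subject = as.character(subject),
      case = as.character(case),
      condition = as.character(condition),
      expected_ms = as.numeric(expected_ms),
      set_index = as.integer(set_index),
      regime = as.character(regime),
      regime_labels = regime_labels
    ),
    class = "interval_series"
  )
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf(
    "<interval_series> %d intervals, mean %.1f ms (subject %s, case %s, condition %s)\n",
    length(x$durations_ms), mean(x$durations_ms),
    x$subject, x$case, x$condition
  ))
  invisible(x)
}

#' @export
length.interval_series <- function(x) length(x$durations_ms)

#' Extract the duration vector from an interval series
#'
#' @param x an `interval_series` or a bare numeric vector of durations.
#' @return numeric vector of durations in ms.
#' @export
durations <- function(x) {
  if (inherits(x, "interval_series")) x$durations_ms else as.numeric(x)
}
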