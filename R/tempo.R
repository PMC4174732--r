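# Tempo unit conversions and ranked tempo ranges.
#
# Performed sets are binned into eight ranked tempo bands (named after
# musical tempo markings, Adagio..Presto). Each band is defined by a
# reference frequency and a from/to frequency range; the equivalent
# durations are 1000/Hz rounded half-up to 2 decimals. In duration units
# a band therefore runs from its `to_ms` (fastest) to its `from_ms`
# (slowest) bound. The frequency bands have gaps, so a mean duration can
# legitimately fall outside every band.

.tempo_env <- new.env(parent = emptyenv())

#' The eight ranked tempo ranges
#'
#' @return A data.frame with one row per rank (1 = slowest, 8 = fastest):
#'   `musical_name`, `rank`, `reference_hz`, `from_hz`, `to_hz`,
#'   `reference_ms`, `from_ms`, `to_ms`. In ms, `from_ms` is the slow
#'   (long-duration) bound and `to_ms` the fast bound of the band.
#' @export
tempo_ranges <- function() {
  if (is.null(.tempo_env$ranges)) {
    path <- system.file("extdata", "tempo_ranges.csv", package = "isochron",
                        mustWork = TRUE)
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
    tbl <- tbl[order(tbl$rank), ]
    .tempo_env$ranges <- tbl
  }
  .tempo_env$ranges
}

#' Convert a movement frequency to a period
#'
#' @param frequency_hz cycle frequency in Hz (> 0).
#' @return Period in ms, rounded half-up to 2 decimals (the convention of
#'   the tempo-range table).
#' @examples
#' hz_to_ms(1.067) # 937.21, the Adagio reference
#' @export
hz_to_ms <- function(frequency_hz) {
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop_domain("`frequency_hz` must be positive")
  }
  round_half_up(1000 / frequency_hz, 2)
}

#' Convert a period to a movement frequency
#'
#' @param duration_ms period in ms (> 0).
#' @return Frequency in Hz.
#' @export
ms_to_hz <- function(duration_ms) {
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0)) {
    stop_domain("`duration_ms` must be positive")
  }
  1000 / duration_ms
}

#' Convert a musical tempo in beats per minute to a beat period
#'
#' @param tempo_bpm tempo in beats per minute (> 0).
#' @return Beat period in ms, rounded half-up to 2 decimals. Note that
#'   the tempo-range table's reference periods derive from its Hz column
#'   (e.g. 64 bpm is listed as 937.21 ms via 1.067 Hz, not 937.50 ms);
#'   the Hz column is authoritative for range membership.
#' @export
bpm_to_ms <- function(tempo_bpm) {
  if (any(!is.finite(tempo_bpm)) || any(tempo_bpm <= 0)) {
    stop_domain("`tempo_bpm` must be positive")
  }
  round_half_up(60000 / tempo_bpm, 2)
}

#' Assign a mean movement duration to a tempo rank
#'
#' Membership is tested on the duration scale with inclusive bounds:
#' rank r contains `x` iff `to_ms[r] <= x <= from_ms[r]`. Because the
#' frequency bands have gaps, values between bands return `NA` rather
#' than being snapped to the nearest rank.
#'
#' @param mean_duration_ms mean interval duration in ms (> 0); vectorised.
#' @return Integer rank 1–8, or `NA_integer_` when the duration falls in
#'   a gap between bands.
#' @examples
#' assign_rank(750.19) # 2 (Andante reference)
#' assign_rank(833.33) # NA: between the Adagio and Andante bands
#' @export
assign_rank <- function(mean_duration_ms) {
  if (any(!is.finite(mean_duration_ms)) || any(mean_duration_ms <= 0)) {
    stop_domain("`mean_duration_ms` must be positive")
  }
  tbl <- tempo_ranges()
  vapply(mean_duration_ms, function(x) {
    hit <- which(x >= tbl$to_ms & x <= tbl$from_ms)
    if (length(hit) == 1L) as.integer(tbl$rank[hit]) else NA_integer_
  }, integer(1))
}

#' Dichotomise a duration as fast or slow
#'
#' The study analyses dichotomise tempo at 517.33 ms (the fast bound of
#' the Moderato band): fast if strictly shorter, slow otherwise.
#'
#' @param duration_ms interval duration in ms (> 0); vectorised.
#' @param threshold_ms dichotomisation boundary, default 517.33 ms.
#' @return Character vector, `"fast"` or `"slow"`.
#' @export
classify_speed <- function(duration_ms, threshold_ms = 517.33) {
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0)) {
    stop_domain("`duration_ms` must be positive")
  }
  check_scalar_positive(threshold_ms, "threshold_ms")
  ifelse(duration_ms < threshold_ms, "fast", "slow")
}
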