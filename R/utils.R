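# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used wherever printed two-decimal
#' values are reproduced. `base::round()` rounds half to even, which
#' disagrees with printed tables at exact .xx5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-set substream seed derived from (seed, subject, set).
# The multipliers keep (subject, set) pairs collision-free for any design
# with fewer than ~1e5 sets per subject.
substream_seed <- function(seed, subject_index, set_index) {
  as.integer((as.numeric(seed) + 1000003 * subject_index + 7919 * set_index) %%
               2147483647L)
}

stop_domain <- function(msg) stop(msg, call. = FALSE)

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_domain(sprintf("`%s` must be a single non-negative finite number", name))
  }
  invisible(x)
}
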