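# Plain-text interchange: interval-series tables and accelerometer
# traces as CSV. The study's data shapes are small tables; no binary
# formats.

.INTERVAL_COLS <- c("subject", "case", "condition", "tempo_ms_expected",
                    "set_index", "interval_index", "duration_ms",
                    "regime_label")

#' Write interval series to CSV
#'
#' @param sets a list of [interval_series], a single `interval_series`,
#'   or a `simulated_study`.
#' @param path output CSV path.
#' @return The long-format data.frame written, invisibly.
#' @export
write_intervals <- function(sets, path) {
  if (inherits(sets, "simulated_study")) sets <- sets$sets
  if (inherits(sets, "interval_series")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    data.frame(
      subject = s$subject,
      case = s$case,
      condition = s$condition,
      tempo_ms_expected = s$expected_ms,
      set_index = s$set_index,
      interval_index = seq_along(s$durations_ms),
      duration_ms = s$durations_ms,
      regime_label = if (!is.null(s$regime_labels)) s$regime_labels else s$regime,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read interval series from CSV
#'
#' Expects the column layout written by [write_intervals()]. Each
#' distinct (subject, case, condition, set_index) combination becomes
#' one [interval_series], ordered by `interval_index`.
#'
#' @param path CSV path.
#' @return A list of [interval_series].
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  tbl <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_domain(sprintf("cannot parse %s: %s",
                                            path, conditionMessage(e)))
  )
  miss <- setdiff(.INTERVAL_COLS, names(tbl))
  if (length(miss)) {
    stop_domain(sprintf("schema error in %s: missing columns %s",
                        path, paste(miss, collapse = ", ")))
  }
  if (nrow(tbl) == 0L) stop_domain(sprintf("schema error: %s has no rows", path))
  bad <- which(!is.finite(tbl$duration_ms) | tbl$duration_ms <= 0)
  if (length(bad)) {
    stop_domain(sprintf("validation error: non-positive duration at row(s) %s",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- interaction(tbl$subject, tbl$case, tbl$condition, tbl$set_index,
                     drop = TRUE)
  lapply(split(tbl, key), function(g) {
    g <- g[order(g$interval_index), ]
    interval_series(
      g$duration_ms,
      subject = g$subject[1L],
      case = g$case[1L],
      condition = g$condition[1L],
      expected_ms = g$tempo_ms_expected[1L],
      set_index = g$set_index[1L],
      regime = g$regime_label[1L],
      regime_labels = if (length(unique(g$regime_label)) > 1L)
        g$regime_label else NULL
    )
  })
}

#' Write an accelerometer trace to CSV
#'
#' @param trace an `accel_trace`.
#' @param path output CSV path (columns `t_s`, `ax`, `ay`, `az`).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  utils::write.csv(
    data.frame(t_s = trace$time_s,
               ax = trace$channels[, 1], ay = trace$channels[, 2],
               az = trace$channels[, 3]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read an accelerometer trace from CSV
#'
#' @param path CSV with columns `t_s`, `ax`, `ay`, `az` and a uniform
#'   sampling grid.
#' @return An `accel_trace`.
#' @export
read_trace <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("t_s", "ax", "ay", "az"), names(tbl))
  if (length(miss)) {
    stop_domain(sprintf("schema error in %s: missing columns %s",
                        path, paste(miss, collapse = ", ")))
  }
  if (nrow(tbl) < 2L) stop_domain("trace needs at least 2 samples")
  dt <- diff(tbl$t_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6) {
    stop_domain("timestamps must be strictly increasing and uniform")
  }
  structure(
    list(
      time_s = tbl$t_s,
      channels = cbind(ax = tbl$ax, ay = tbl$ay, az = tbl$az),
      sample_rate = 1 / mean(dt),
      truth = NULL
    ),
    class = "accel_trace"
  )
}
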