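# End-to-end orchestration: synthetic (or read) interval sets ->
# tempo ranking -> per-set statistics -> variance models -> report
# tables mirroring the study's summary structure.

.condition_group <- function(condition) {
  ifelse(condition %in% c("Cl2", "Mu2"), "Recalls", condition)
}

#' Pipeline run configuration
#'
#' @param design a [study_design()] used when `intervals_path` is `NULL`.
#' @param seed integer seed driving every stochastic stage.
#' @param intervals_path optional CSV of interval series (layout of
#'   [write_intervals()]); when given, data are read rather than
#'   simulated.
#' @param window_length wgamma(1) window length (intervals).
#' @param speed_threshold_ms fast/slow boundary (ms).
#' @param mode_threshold_pct dominance threshold for
#'   [classify_timing_mode()].
#' @return A `run_config` list.
#' @export
run_config <- function(design = study_design(),
                       seed = 1L,
                       intervals_path = NULL,
                       window_length = 30L,
                       speed_threshold_ms = 517.33,
                       mode_threshold_pct = 60) {
  stopifnot(inherits(design, "study_design"))
  check_scalar_positive(speed_threshold_ms, "speed_threshold_ms")
  if (!is.null(intervals_path) && !file.exists(intervals_path)) {
    stop_domain(sprintf("`intervals_path` not resolvable: %s", intervals_path))
  }
  structure(
    list(design = design, seed = as.integer(seed),
         intervals_path = intervals_path,
         window_length = as.integer(window_length),
         speed_threshold_ms = speed_threshold_ms,
         mode_threshold_pct = mode_threshold_pct),
    class = "run_config"
  )
}

.per_set_stats <- function(sets, config) {
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    mean_dur <- mean(s$durations_ms)
    ref <- if (is.finite(s$expected_ms)) s$expected_ms else mean_dur
    base <- data.frame(
      subject = s$subject, case = s$case, condition = s$condition,
      set_index = s$set_index, n = length(s$durations_ms),
      mean_ms = mean_dur,
      expected_ms = s$expected_ms,
      rank = assign_rank(mean_dur),
      speed = classify_speed(ref, config$speed_threshold_ms),
      cv_pct = coefficient_of_variation(s),
      stringsAsFactors = FALSE
    )
    skipped <- FALSE
    if (length(s$durations_ms) >= config$window_length + 1L) {
      wg <- summarize_wgamma(
        windowed_lag_one(s, window_length = config$window_length),
        window_length = config$window_length
      )
      base$mean_wgamma <- wg$mean_wgamma
      base$mean_wgamma_raw <- wg$mean_wgamma_raw
      base$z_mean <- atanh(wg$mean_wgamma)
      base$pct_positive <- wg$pct_positive
      base$pct_negative <- wg$pct_negative
      base$mode <- classify_timing_mode(wg, config$mode_threshold_pct)
    } else {
      skipped <- TRUE
      base$mean_wgamma <- NA_real_
      base$mean_wgamma_raw <- NA_real_
      base$z_mean <- NA_real_
      base$pct_positive <- NA_real_
      base$pct_negative <- NA_real_
      base$mode <- NA_character_
    }
    base$wgamma_skipped <- skipped
    base
  })
  out <- do.call(rbind, rows)
  if (any(out$wgamma_skipped)) {
    warning(sprintf(
      "%d set(s) shorter than window_length + 1: wgamma skipped for them",
      sum(out$wgamma_skipped)))
  }
  out$wgamma_skipped <- NULL
  out
}

.error_observations <- function(sets) {
  rows <- lapply(sets, function(s) {
    resp <- if (s$condition == "Fr" || !is.finite(s$expected_ms)) {
      s$durations_ms / 1000
    } else {
      (s$durations_ms - s$expected_ms) / 1000
    }
    ref <- if (is.finite(s$expected_ms)) s$expected_ms else mean(s$durations_ms)
    data.frame(
      subject = s$subject, case = s$case, condition = s$condition,
      group = .condition_group(s$condition),
      set = paste(s$case, s$condition, s$set_index, sep = "."),
      speed = classify_speed(ref),
      response = resp,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) interval sets, ranks them by tempo, computes
#' per-set variability and windowed-autocorrelation statistics, fits
#' the heteroscedastic error model per condition group (with the
#' homoscedastic counterpart and likelihood-ratio test), fits the
#' mixed-model ANOVA for the per-set Z-transformed mean wgamma(1), and
#' assembles the condition- and range-level summary tables.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return A `report_bundle`: list with `per_set_stats`, `fits` (one
#'   element per condition group: the heteroscedastic fit, restricted
#'   fit and LRT), `fit_table`, `wgamma_anova`, `cv_by_range`,
#'   `wgamma_by_range`, `differential` and `provenance`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(config$intervals_path)) {
    study <- gen_study(config$design, config$seed)
    sets <- study$sets
    say("simulate: %d sets generated (seed %d)", length(sets), config$seed)
  } else {
    sets <- read_intervals(config$intervals_path)
    say("read: %d sets from %s", length(sets), config$intervals_path)
  }

  stats_tbl <- .per_set_stats(sets, config)
  say("stats: %d per-set rows", nrow(stats_tbl))

  obs <- .error_observations(sets)
  fits <- list()
  fit_rows <- list()
  for (g in unique(obs$group)) {
    og <- obs[obs$group == g, ]
    full <- fit_hetero_lmm(og, heteroscedastic = TRUE)
    restricted <- fit_hetero_lmm(og, heteroscedastic = FALSE)
    lrt <- lrt_heteroscedasticity(restricted, full)
    fits[[g]] <- list(full = full, restricted = restricted, lrt = lrt)
    fit_rows[[g]] <- data.frame(
      group = g,
      n = full$n_obs,
      term = c(full$fixed_effects$term, "within_individual_sd",
               "within_set_sd", "residual_sd_nktt", "variance_ratio",
               "lrt_statistic", "lrt_p"),
      estimate = c(full$fixed_effects$estimate, full$within_individual_sd,
                   full$within_set_sd, full$residual_sd_nktt,
                   full$variance_ratio, lrt$statistic, lrt$p_value),
      lower = c(full$fixed_effects$lower, full$within_individual_sd_ci[1],
                full$within_set_sd_ci[1], NA, full$variance_ratio_ci[1],
                NA, NA),
      upper = c(full$fixed_effects$upper, full$within_individual_sd_ci[2],
                full$within_set_sd_ci[2], NA, full$variance_ratio_ci[2],
                NA, NA),
      stringsAsFactors = FALSE
    )
    say("fit %s: ratio %.4f, LRT p %.3g", g, full$variance_ratio, lrt$p_value)
  }
  fit_table <- do.call(rbind, c(fit_rows, list(make.row.names = FALSE)))

  wg_ok <- stats_tbl[!is.na(stats_tbl$z_mean), ]
  anova_tbl <- NULL
  if (nrow(wg_ok) > 0L && length(unique(wg_ok$case)) == 2L) {
    anova_tbl <- do.call(rbind, lapply(unique(wg_ok$condition), function(cn) {
      d <- wg_ok[wg_ok$condition == cn, ]
      out <- fit_wgamma_anova(data.frame(z = d$z_mean, subject = d$subject,
                                         case = d$case, speed = d$speed))
      cbind(condition = cn, out)
    }))
    say("wgamma anova: %d condition(s)", length(unique(wg_ok$condition)))
  }

  cv_by_range <- stats::aggregate(cv_pct ~ condition + case + rank,
                                  data = stats_tbl, FUN = mean)
  if (nrow(wg_ok) > 0L) {
    wgamma_by_range <- stats::aggregate(
      cbind(mean_wgamma, pct_positive, pct_negative) ~ condition + case + rank,
      data = wg_ok, FUN = mean)
  } else {
    wgamma_by_range <- data.frame(condition = character(), case = character(),
                                  rank = integer(), mean_wgamma = numeric(),
                                  pct_positive = numeric(),
                                  pct_negative = numeric())
  }

  differential <- do.call(rbind, lapply(unique(wg_ok$condition), function(cn) {
    d <- wg_ok[wg_ok$condition == cn, ]
    pk <- mean(d$pct_positive[d$case == "KTT"])
    pn <- mean(d$pct_positive[d$case == "N/KTT"])
    if (!is.finite(pk) || !is.finite(pn)) return(NULL)
    dp <- differential_percent(pk, pn)
    data.frame(condition = cn, case = "KTT vs N/KTT",
               n = nrow(d),
               pct_positive_ktt = pk, pct_positive_nktt = pn,
               difference = dp$difference,
               equivalent_increase = dp$equivalent_increase,
               stringsAsFactors = FALSE)
  }))

  structure(
    list(
      per_set_stats = stats_tbl,
      fits = fits,
      fit_table = fit_table,
      wgamma_anova = anova_tbl,
      cv_by_range = cv_by_range,
      wgamma_by_range = wgamma_by_range,
      differential = differential,
      provenance = list(
        seed = config$seed,
        window_length = config$window_length,
        speed_threshold_ms = config$speed_threshold_ms,
        design = unclass(config$design),
        package_version = as.character(utils::packageVersion("isochron")),
        r_version = R.version.string
      )
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d sets, %d condition group fit(s)\n",
              nrow(x$per_set_stats), length(x$fits)))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes the summary tables as CSV/TSV and the provenance block as
#' JSON.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$per_set_stats, file.path(dir, "per_set_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$fit_table, file.path(dir, "fit_table.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$wgamma_anova)) {
    utils::write.csv(bundle$wgamma_anova, file.path(dir, "wgamma_anova.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$cv_by_range, file.path(dir, "cv_by_range.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$wgamma_by_range,
                   file.path(dir, "wgamma_by_range.csv"), row.names = FALSE)
  if (!is.null(bundle$differential)) {
    utils::write.csv(bundle$differential, file.path(dir, "differential.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
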