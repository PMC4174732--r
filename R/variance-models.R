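# Heteroscedastic random-effects ANOVA for repeated measurements.
#
# The error model: per-interval timing error (observed - expected
# duration, in s; the observed duration itself for unpaced sets) with
# fixed effects for the overall mean, tempo dichotomy (fast/slow) and
# taping case (N/KTT vs KTT); nested random intercepts for subject and
# for set within subject (separating within-individual from within-set
# variability); and a residual variance that differs by taping case by a
# multiplicative ratio (factor-specific residual variances). Estimation
# is REML via nlme::lme with a varIdent residual variance function; the
# heteroscedastic term is tested with a REML likelihood-ratio test,
# which is valid here because both models share the same fixed effects.

.as_case_factor <- function(x) {
  f <- factor(as.character(x), levels = c("N/KTT", "KTT"))
  if (any(is.na(f))) stop_domain("`case` must be \"N/KTT\" or \"KTT\"")
  f
}

.as_speed_factor <- function(x) {
  f <- factor(as.character(x), levels = c("slow", "fast"))
  if (any(is.na(f))) stop_domain("`speed` must be \"slow\" or \"fast\"")
  f
}

#' Ratio of factor-specific residual variances
#'
#' @param sigma2_ktt residual variance under taping (s^2, > 0).
#' @param sigma2_nktt residual variance without taping (s^2, > 0).
#' @param digits decimals for half-up rounding of the reported ratio
#'   (default 4, the reporting convention); `NULL` for no rounding.
#' @return The variance ratio `sigma2_ktt / sigma2_nktt`.
#' @examples
#' variance_ratio(0.0006625549, 0.00076729) # 0.8635
#' @export
variance_ratio <- function(sigma2_ktt, sigma2_nktt, digits = 4) {
  check_scalar_positive(sigma2_ktt, "sigma2_ktt")
  check_scalar_positive(sigma2_nktt, "sigma2_nktt")
  r <- sigma2_ktt / sigma2_nktt
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Fit the heteroscedastic random-effects error model
#'
#' @param data data.frame of per-interval observations with columns
#'   `response` (s), `subject`, `set` (set identifier, nested within
#'   subject), `case` (`"N/KTT"`/`"KTT"`) and `speed`
#'   (`"slow"`/`"fast"`).
#' @param heteroscedastic when `TRUE` (default) the residual SD is
#'   scaled by a free factor for KTT observations; when `FALSE` a single
#'   residual variance is fitted (the restricted model of the
#'   likelihood-ratio test).
#' @return A `hetero_lmm_fit`: list with `fixed_effects` (estimate, 95%
#'   CI, p per term), `within_individual_sd` and `within_set_sd` (each
#'   with CI), `residual_sd_nktt`, `variance_ratio` (+ 95% CI; `NA` for
#'   the homoscedastic fit), `log_likelihood` (REML), `n_obs`,
#'   `converged`, and the underlying `nlme::lme` fit in `$fit`.
#'   Variance-parameter CIs are Wald intervals on the log scale,
#'   back-transformed; fixed-effect CIs are t-based.
#' @export
fit_hetero_lmm <- function(data, heteroscedastic = TRUE) {
  req <- c("response", "subject", "set", "case", "speed")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop_domain(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  d <- data.frame(
    response = as.numeric(data$response),
    subject = factor(data$subject),
    set = factor(data$set),
    case = .as_case_factor(data$case),
    speed = .as_speed_factor(data$speed)
  )
  if (any(!is.finite(d$response))) stop_domain("`response` must be finite")
  if (nlevels(d$subject) < 2L) stop_domain("need at least 2 subjects")
  sets_per_subj <- tapply(d$set, d$subject,
                          function(s) length(unique(s)))
  if (any(sets_per_subj < 2L)) {
    stop_domain("need at least 2 sets per subject")
  }
  if (heteroscedastic && nlevels(droplevels(d$case)) < 2L) {
    stop_domain("both taping cases must be present for the heteroscedastic fit")
  }

  args <- list(
    fixed = response ~ speed + case,
    random = ~ 1 | subject / set,
    data = d,
    method = "REML",
    control = nlme::lmeControl(maxIter = 500, msMaxIter = 500,
                               niterEM = 50, returnObject = TRUE)
  )
  if (heteroscedastic) {
    args$weights <- nlme::varIdent(form = ~ 1 | case)
  }
  fit <- tryCatch(
    do.call(nlme::lme, args),
    error = function(e) stop_domain(paste("mixed-model fit failed:",
                                          conditionMessage(e)))
  )

  tt <- summary(fit)$tTable
  iv <- tryCatch(nlme::intervals(fit), error = function(e) NULL)
  boundary <- is.null(iv)
  if (boundary) {
    warning("variance parameters near the boundary: Wald intervals unavailable")
  }

  fixed <- data.frame(
    term = rownames(tt),
    estimate = tt[, "Value"],
    lower = if (!boundary) iv$fixed[, "lower"] else NA_real_,
    upper = if (!boundary) iv$fixed[, "upper"] else NA_real_,
    p_value = tt[, "p-value"],
    row.names = NULL
  )

  re_iv <- if (!boundary) iv$reStruct else NULL
  sd_ci <- function(which) {
    if (is.null(re_iv)) return(c(NA_real_, NA_real_))
    as.numeric(re_iv[[which]][1, c("lower", "upper")])
  }
  # VarCorr rows for subject/set nesting: subject intercept first,
  # set-in-subject intercept second, residual last
  vc <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  subj_sd <- sds[which(rownames(vc) == "(Intercept)")[1]]
  set_sd <- sds[which(rownames(vc) == "(Intercept)")[2]]
  if (heteroscedastic) {
    # varIdent fixes one stratum's coefficient at 1 (its reference is
    # data-order dependent); recover the KTT/N-KTT SD ratio from the
    # full coefficient vector and rescale sigma to the N/KTT stratum.
    w <- stats::coef(fit$modelStruct$varStruct,
                     unconstrained = FALSE, allCoef = TRUE)
    sigma_nktt <- fit$sigma * w[["N/KTT"]]
    ratio <- (w[["KTT"]] / w[["N/KTT"]])^2
    ratio_ci <- c(NA_real_, NA_real_)
    if (!boundary && !is.null(iv$varStruct)) {
      free <- rownames(iv$varStruct)[1]
      b <- as.numeric(iv$varStruct[1, c("lower", "upper")])
      ratio_ci <- if (free == "KTT") b^2 else sort(1 / b^2)
    }
  } else {
    sigma_nktt <- fit$sigma
    ratio <- NA_real_
    ratio_ci <- c(NA_real_, NA_real_)
  }

  structure(
    list(
      fixed_effects = fixed,
      within_individual_sd = unname(subj_sd),
      within_individual_sd_ci = sd_ci("subject"),
      within_set_sd = unname(set_sd),
      within_set_sd_ci = sd_ci("set"),
      residual_sd_nktt = sigma_nktt,
      variance_ratio = unname(ratio),
      variance_ratio_ci = ratio_ci,
      heteroscedastic = heteroscedastic,
      log_likelihood = as.numeric(stats::logLik(fit)),
      n_obs = nrow(d),
      converged = TRUE,
      fixed_formula = deparse(args$fixed),
      fit = fit
    ),
    class = "hetero_lmm_fit"
  )
}

#' @export
print.hetero_lmm_fit <- function(x, ...) {
  cat(sprintf("<hetero_lmm_fit> %s model, %d observations\n",
              if (x$heteroscedastic) "heteroscedastic" else "homoscedastic",
              x$n_obs))
  cat("Fixed effects:\n")
  print(x$fixed_effects, digits = 4)
  cat(sprintf("Within-individual SD: %.4f  Within-set SD: %.4f  Residual SD (N/KTT): %.4f\n",
              x$within_individual_sd, x$within_set_sd, x$residual_sd_nktt))
  if (x$heteroscedastic) {
    cat(sprintf("KTT residual variance ratio: %.4f (95%% CI %.4f; %.4f)\n",
                x$variance_ratio, x$variance_ratio_ci[1], x$variance_ratio_ci[2]))
  }
  invisible(x)
}

#' Likelihood-ratio test of residual heteroscedasticity
#'
#' Compares the homoscedastic (ratio fixed at 1) and heteroscedastic
#' fits of the same data with identical fixed effects: the statistic
#' `2 * (logLik_full - logLik_restricted)` is referred to a chi-square
#' distribution with 1 df. REML likelihoods are comparable because only
#' the variance structure differs.
#'
#' @param fit_restricted homoscedastic [fit_hetero_lmm()] fit.
#' @param fit_full heteroscedastic fit of the same data.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lrt_heteroscedasticity <- function(fit_restricted, fit_full) {
  stopifnot(inherits(fit_restricted, "hetero_lmm_fit"),
            inherits(fit_full, "hetero_lmm_fit"))
  if (fit_restricted$n_obs != fit_full$n_obs ||
      fit_restricted$fixed_formula != fit_full$fixed_formula) {
    stop_domain("fits must share the same data and fixed effects")
  }
  if (fit_restricted$heteroscedastic || !fit_full$heteroscedastic) {
    stop_domain("`fit_restricted` must be homoscedastic and `fit_full` heteroscedastic")
  }
  stat <- 2 * (fit_full$log_likelihood - fit_restricted$log_likelihood)
  if (stat < 0 && stat > -1e-6) stat <- 0  # numerical round-off
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Mixed-model ANOVA for per-set windowed autocorrelation means
#'
#' Fits a random-intercept model (subject) to per-set Fisher-Z
#' transformed mean wgamma(1) values with fixed effects for taping case,
#' speed, and their interaction, and returns marginal F-tests with
#' containment denominator degrees of freedom (the `nlme` convention).
#'
#' @param data data.frame with columns `z` (Fisher-Z transformed per-set
#'   mean wgamma(1)), `subject`, `case`, `speed`.
#' @return A data.frame with one row per term (`case`, `speed`,
#'   `case:speed`): `num_df`, `den_df`, `F_value`, `p_value`.
#' @export
fit_wgamma_anova <- function(data) {
  req <- c("z", "subject", "case", "speed")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop_domain(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  d <- data.frame(
    z = as.numeric(data$z),
    subject = factor(data$subject),
    case = .as_case_factor(data$case),
    speed = .as_speed_factor(data$speed)
  )
  if (nlevels(d$subject) < 2L) stop_domain("need at least 2 subjects")
  cells <- table(d$case, d$speed)
  if (any(cells == 0L)) {
    warning("empty case x speed cells: interaction F-test may be unreliable")
  }
  # sum-to-zero contrasts so the marginal F for each factor tests its
  # main effect (classical ANOVA reading), not a simple effect at the
  # other factor's reference level
  d$case <- stats::C(d$case, stats::contr.sum)
  d$speed <- stats::C(d$speed, stats::contr.sum)
  fit <- nlme::lme(z ~ case * speed, random = ~ 1 | subject, data = d,
                   method = "REML",
                   control = nlme::lmeControl(returnObject = TRUE))
  av <- stats::anova(fit, type = "marginal")
  av <- av[rownames(av) != "(Intercept)", ]
  data.frame(
    term = rownames(av),
    num_df = av$numDF,
    den_df = av$denDF,
    F_value = av$`F-value`,
    p_value = av$`p-value`,
    row.names = NULL
  )
}
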