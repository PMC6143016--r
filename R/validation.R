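#' Long-term calibration and discrimination statistics
#'
#' Everything needed to validate an absolute-risk model against observed
#' follow-up: expected events from predicted cumulative risk, exact Poisson
#' O/E ratios, stratum tables, Kaplan-Meier cumulative-risk curves, decile
#' hazard ratios, a time-varying calibration coefficient, likelihood-ratio
#' information beyond age, and risk reclassification.
#'
#' @name validation
NULL

#' Expected events from predicted cumulative risks
#'
#' Each woman's predicted cumulative incidence to the end of her follow-up is
#' converted to a cumulative hazard, `E_i = -log(1 - P_i)`, and summed.
#'
#' @param p Numeric vector of predicted cumulative risks in `[0, 1)`.
#' @return A list with `E` (total expected events) and `e_i` (per-woman
#'   contributions).
#' @export
#' @examples
#' expected_events(c(0.1, 0.2, 0.3))$E
expected_events <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p >= 1)) {
    stop("predicted cumulative risks must lie in [0, 1)", call. = FALSE)
  }
  e_i <- -log1p(-p)
  list(E = sum(e_i), e_i = e_i)
}

#' Exact Poisson observed/expected ratio
#'
#' Treats the observed count as Poisson with rate equal to the expected
#' count under calibration.  The 95% bounds are the Garwood gamma-quantile
#' construction: lower `qgamma(0.025, O) / E` (0 when `O = 0`), upper
#' `qgamma(0.975, O + 1) / E`.
#'
#' @param observed Non-negative event count.
#' @param expected Positive expected count.
#' @param conf Confidence level (default 0.95).
#' @return An `oe_result` tibble: `observed`, `expected`, `ratio`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' oe_ratio(147, 185)
oe_ratio <- function(observed, expected, conf = 0.95) {
  if (any(expected <= 0)) stop("expected must be positive", call. = FALSE)
  if (any(observed < 0)) stop("observed must be non-negative", call. = FALSE)
  a <- (1 - conf) / 2
  out <- tibble::tibble(
    observed = observed, expected = expected,
    ratio = observed / expected,
    ci_low = ifelse(observed == 0, 0,
                    stats::qgamma(a, shape = observed) / expected),
    ci_high = stats::qgamma(1 - a, shape = observed + 1) / expected
  )
  class(out) <- c("oe_result", class(out))
  out
}

# Exact Poisson rate-ratio CI via the conditional binomial method.
rate_ratio_ci <- function(o1, py1, o0, py0, conf = 0.95) {
  if (o1 + o0 == 0 || py1 == 0 || py0 == 0) {
    return(c(NA_real_, NA_real_, NA_real_))
  }
  est <- (o1 / py1) / (o0 / py0)
  ci <- stats::binom.test(o1, o1 + o0, conf.level = conf)$conf.int
  c(est, ci / (1 - ci) * py0 / py1)
}

#' Calibration table by risk stratum
#'
#' Per-stratum counts, person-years, observed and expected events, exact
#' Poisson O/E, incidence rate per 1000 women-years, and the incidence rate
#' ratio against the reference stratum (exact conditional CI).  An overall
#' row labelled `"all"` comes first.
#'
#' @param cohort Cohort tibble with follow-up columns.
#' @param predictions Predictions from [predict_cohort()] (needs `id`, `r`,
#'   `d`, `stratum`).
#' @param rates Baseline rate table used to accumulate expected events over
#'   each woman's observed follow-up.
#' @param reference Reference stratum for the IRR (default the average-risk
#'   band `"2% to <3%"`).
#' @return A tibble with one row per stratum (empty strata kept, `O = 0`).
#' @export
group_table <- function(cohort, predictions,
                        rates = default_baseline_rates(),
                        reference = "2% to <3%") {
  df <- dplyr::inner_join(
    tibble::as_tibble(cohort), predictions, by = "id"
  ) |>
    dplyr::mutate(
      py = .data$exit_age - .data$age_entry,
      e_i = cum_hazard_net(.data$r * .data$d, .data$age_entry,
                           .data$exit_age, rates)
    )
  per <- df |>
    dplyr::group_by(stratum = factor(.data$stratum,
                                     levels = .strata_levels)) |>
    dplyr::summarise(
      n_women = dplyr::n(), person_years = sum(.data$py),
      observed = sum(.data$event), expected = sum(.data$e_i),
      .groups = "drop"
    ) |>
    tidyr::complete(.data$stratum,
                    fill = list(n_women = 0L, person_years = 0,
                                observed = 0L, expected = 0))
  all_row <- dplyr::summarise(
    per, stratum = factor(NA, levels = levels(per$stratum)),
    n_women = sum(.data$n_women), person_years = sum(.data$person_years),
    observed = sum(.data$observed), expected = sum(.data$expected)
  )
  tab <- dplyr::bind_rows(all_row, per) |>
    dplyr::mutate(
      stratum = dplyr::coalesce(as.character(.data$stratum), "all"),
      ratio = ifelse(.data$expected > 0,
                     .data$observed / .data$expected, NA_real_),
      ci_low = ifelse(.data$expected > 0 & .data$observed > 0,
                      stats::qgamma(0.025, .data$observed) / .data$expected,
                      ifelse(.data$expected > 0, 0, NA_real_)),
      ci_high = ifelse(.data$expected > 0,
                       stats::qgamma(0.975, .data$observed + 1) /
                         .data$expected, NA_real_),
      ir = ifelse(.data$person_years > 0,
                  1000 * .data$observed / .data$person_years, 0)
    )
  ref <- tab[tab$stratum == reference, ]
  irr <- purrr::pmap(
    list(tab$observed, tab$person_years, tab$stratum),
    function(o, py, s) {
      if (s == "all" || py == 0) return(c(NA_real_, NA_real_, NA_real_))
      if (s == reference) return(c(1, NA_real_, NA_real_))
      rate_ratio_ci(o, py, ref$observed, ref$person_years)
    }
  )
  tab$irr <- purrr::map_dbl(irr, 1)
  tab$irr_low <- purrr::map_dbl(irr, 2)
  tab$irr_high <- purrr::map_dbl(irr, 3)
  tab
}

#' Kaplan-Meier cumulative-risk curves by group
#'
#' Product-limit estimate of cumulative invasive-cancer risk
#' (`1 - S(t)`) on the follow-up time scale per group, with pointwise 95%
#' confidence bands from the Greenwood variance (log scale).
#'
#' @param cohort Cohort tibble with follow-up columns.
#' @param group Vector of group labels, one per woman (e.g. risk strata).
#' @return A `km_curves` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `cum_risk`, `ci_low`, `ci_high`.
#' @export
km_cumulative_risk <- function(cohort, group) {
  time <- cohort$exit_age - cohort$age_entry
  if (any(time <= 0)) stop("follow-up times must be positive", call. = FALSE)
  df <- data.frame(time = time, event = cohort$event,
                   group = as.character(group))
  fit <- survival::survfit(Surv(time, event) ~ group, data = df,
                           conf.type = "log")
  strata_names <- if (is.null(fit$strata)) {
    rep(unique(df$group), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble::tibble(
    group = strata_names, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, cum_risk = 1 - fit$surv,
    ci_low = 1 - fit$upper, ci_high = 1 - fit$lower
  )
  class(out) <- c("km_curves", class(out))
  out
}

age5_band <- function(age) {
  cut(age, breaks = seq(40, 75, by = 5), right = FALSE,
      include.lowest = TRUE)
}

#' Decile hazard ratios for 10-year risk
#'
#' Proportional-hazards fit of indicator covariates for the top and bottom
#' quantiles of predicted 10-year risk against the middle of the
#' distribution, stratified by 5-year age group at entry.  Ties in predicted
#' risk at a quantile boundary are broken deterministically by id order.
#'
#' @param cohort Cohort tibble with follow-up columns.
#' @param p10 Predicted 10-year risks, aligned with `cohort` rows.
#' @param quantiles Lower and upper cut points (default `c(0.1, 0.9)`; set
#'   e.g. `c(0.1, 0.95)` for a top-5% sensitivity analysis).
#' @return A `decile_hr` tibble: `term` (`"bottom"`, `"top"`), `hr`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
decile_hr <- function(cohort, p10, quantiles = c(0.1, 0.9)) {
  n <- nrow(cohort)
  if (n < 30) stop("need at least 30 women", call. = FALSE)
  rank_pos <- order(order(p10, cohort$id))  # 1 = lowest risk, ties by id
  bottom <- rank_pos <= n * quantiles[1]
  top <- rank_pos > n * quantiles[2]
  df <- data.frame(
    time = cohort$exit_age - cohort$age_entry, event = cohort$event,
    bottom = bottom, top = top, age5 = age5_band(cohort$age_entry)
  )
  fit <- survival::coxph(
    Surv(time, event) ~ bottom + top + strata(age5), data = df
  )
  ci <- stats::confint(fit)
  out <- tibble::tibble(
    term = c("bottom", "top"),
    hr = exp(unname(stats::coef(fit))),
    ci_low = exp(ci[, 1]), ci_high = exp(ci[, 2]),
    n = c(sum(bottom), sum(top))
  )
  class(out) <- c("decile_hr", class(out))
  out
}

# One record per woman-year with the predicted yearly hazard of that year.
expand_person_years <- function(cohort, predictions, rates) {
  df <- dplyr::inner_join(tibble::as_tibble(cohort), predictions,
                          by = "id") |>
    dplyr::mutate(time = .data$exit_age - .data$age_entry,
                  age5 = age5_band(.data$age_entry))
  base <- data.frame(
    id = df$id, time = df$time, event = df$event, rd = df$r * df$d,
    age_entry = df$age_entry, age5 = df$age5
  )
  # keep every episode longer than the survival tie tolerance: times within
  # ~1e-6 of a yearly cut would otherwise leave zero-length records
  near <- abs(base$time - round(base$time)) < 1e-6
  base$time[near] <- round(base$time[near]) + 1e-6
  base$time <- pmax(base$time, 1e-6)
  cuts <- seq_len(ceiling(max(base$time)) - 1)
  if (length(cuts) == 0) {
    split <- base
    split$tstart <- 0
    split$tstop <- base$time
  } else {
    split <- survival::survSplit(Surv(time, event) ~ .,
                                 data = base, cut = cuts,
                                 start = "tstart", end = "tstop")
  }
  h0 <- h0_lookup(rates)
  split$pred_hazard <- split$rd * h0(split$age_entry + split$tstart)
  split
}

#' Calibration coefficient for predicted relative hazards
#'
#' Follow-up is expanded to one record per woman-year and a proportional
#' hazards model is fitted with a time-dependent covariate equal to the
#' predicted yearly hazard for that year, stratified by 5-year age group at
#' entry (so the covariate is age-detrended).  On the default log scale the
#' coefficient beta equals 1 when predicted relative risks are correctly
#' scaled, 0 when they carry no information.
#'
#' @param cohort Cohort tibble with follow-up columns.
#' @param predictions Predictions from [predict_cohort()].
#' @param rates Baseline rate table.
#' @param scale `"log"` (default: covariate is the log predicted hazard) or
#'   `"natural"` (covariate is the hazard itself).
#' @return A `calibration_fit` object: the coxph fit, `beta`, `ci`, the
#'   expanded data dimensions, and the covariate scale.
#' @export
calibration_coefficient <- function(cohort, predictions,
                                    rates = default_baseline_rates(),
                                    scale = c("log", "natural")) {
  scale <- match.arg(scale)
  split <- expand_person_years(cohort, predictions, rates)
  if (any(split$pred_hazard <= 0)) {
    stop("predicted hazards must be positive", call. = FALSE)
  }
  split$z <- if (scale == "log") log(split$pred_hazard) else
    split$pred_hazard
  fit <- survival::coxph(
    Surv(tstart, tstop, event) ~ z + strata(age5), data = split
  )
  ci <- stats::confint(fit)
  structure(
    list(fit = fit, beta = unname(stats::coef(fit)["z"]),
         ci = c(ci[1, 1], ci[1, 2]), scale = scale,
         n_women = nrow(cohort), n_records = nrow(split),
         n_events = sum(split$event)),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration coefficient (%s scale): beta = %.3f (95%% CI %.3f-%.3f)\n",
    x$scale, x$beta, x$ci[1], x$ci[2]))
  cat(sprintf("  %d women, %d woman-year records, %d events\n",
              x$n_women, x$n_records, x$n_events))
  invisible(x)
}

#' Linear trend in the calibration coefficient over follow-up
#'
#' Scaled Schoenfeld residuals from the calibration fit, offset by the
#' overall coefficient, estimate beta at each event time; a linear
#' regression on follow-up year gives the intercept (beta at entry) and the
#' per-year slope with 95% CIs.  A slope of 0 means calibration does not
#' drift with time since risk assessment.
#'
#' @param calfit A `calibration_fit` from [calibration_coefficient()].
#' @return A tibble: `term` (`"intercept"`, `"slope"`), `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
calibration_trend <- function(calfit) {
  stopifnot(inherits(calfit, "calibration_fit"))
  if (calfit$n_events < 2) {
    stop("need at least 2 event times for a trend", call. = FALSE)
  }
  sch <- stats::residuals(calfit$fit, type = "scaledsch")
  times <- as.numeric(rownames(as.matrix(sch)))
  y <- as.numeric(sch) + calfit$beta
  lmfit <- stats::lm(y ~ times)
  ci <- stats::confint(lmfit)
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(stats::coef(lmfit)),
    ci_low = ci[, 1], ci_high = ci[, 2]
  )
}

#' Likelihood-ratio information beyond age
#'
#' The difference in likelihood-ratio statistics between a proportional
#' hazards model with age only (5-year age group at entry) and one that adds
#' the yearly predicted hazard; both models are fitted to the identical
#' woman-year data, so the difference is the chi-square information the risk
#' model adds beyond age.
#'
#' @inheritParams calibration_coefficient
#' @return Non-negative scalar, the LR chi-square difference (1 df).
#' @export
delta_lr <- function(cohort, predictions, rates = default_baseline_rates(),
                     scale = c("log", "natural")) {
  scale <- match.arg(scale)
  split <- expand_person_years(cohort, predictions, rates)
  split$z <- if (scale == "log") log(split$pred_hazard) else
    split$pred_hazard
  split$age5f <- droplevels(split$age5)
  if (nlevels(split$age5f) >= 2) {
    f0 <- survival::coxph(Surv(tstart, tstop, event) ~ age5f,
                          data = split)
    f1 <- survival::coxph(Surv(tstart, tstop, event) ~ age5f + z,
                          data = split)
    ll0 <- f0$loglik[2]
  } else {
    # single age band: the age-only model is the null model
    f1 <- survival::coxph(Surv(tstart, tstop, event) ~ z,
                          data = split)
    ll0 <- f1$loglik[1]
  }
  max(0, 2 * (f1$loglik[2] - ll0))
}

#' Relative information gain between two nested LR statistics
#'
#' Given the beyond-age LR chi-squares of a richer and a simpler risk model,
#' returns the proportion of additional information, e.g. how much density
#' adds to classic factors.
#'
#' @param lr_with,lr_without Beyond-age LR chi-square statistics.
#' @return `(lr_with - lr_without) / lr_without`.
#' @export
lr_gain <- function(lr_with, lr_without) {
  (lr_with - lr_without) / lr_without
}

#' Risk reclassification between two models
#'
#' Cross-classifies women by the risk strata of two models, with observed
#' events, person-years and incidence rate per cell; all 25 cells are kept.
#'
#' @param cohort Cohort tibble with follow-up columns.
#' @param p10_a,p10_b Predicted 10-year risks under models A and B, aligned
#'   with `cohort` rows.
#' @return A `reclass_matrix` tibble: `stratum_a`, `stratum_b`, `n`,
#'   `events`, `person_years`, `ir`.
#' @export
reclassification_matrix <- function(cohort, p10_a, p10_b) {
  df <- tibble::tibble(
    stratum_a = classify_risk_group(p10_a),
    stratum_b = classify_risk_group(p10_b),
    event = cohort$event, py = cohort$exit_age - cohort$age_entry
  )
  out <- df |>
    dplyr::group_by(.data$stratum_a, .data$stratum_b) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event),
                     person_years = sum(.data$py), .groups = "drop") |>
    tidyr::complete(.data$stratum_a, .data$stratum_b,
                    fill = list(n = 0L, events = 0L, person_years = 0)) |>
    dplyr::mutate(ir = ifelse(.data$person_years > 0,
                              1000 * .data$events / .data$person_years,
                              NA_real_))
  class(out) <- c("reclass_matrix", class(out))
  out
}

#' Run the full validation pipeline
#'
#' Overall exact-Poisson O/E, the stratum calibration table, the calibration
#' coefficient and its time trend, the beyond-age LR chi-square, and (when a
#' second model's predictions are supplied) the reclassification matrix.
#'
#' @param cohort Cohort tibble with follow-up columns.
#' @param predictions Predictions from [predict_cohort()].
#' @param rates Baseline rate table.
#' @param predictions_b Optional second model's predictions for
#'   reclassification.
#' @return A `validation_report` list: `oe`, `groups`, `calibration`,
#'   `trend`, `delta_lr`, and optionally `reclassification`.
#' @export
run_validation <- function(cohort, predictions,
                           rates = default_baseline_rates(),
                           predictions_b = NULL) {
  missing_ids <- setdiff(cohort$id, predictions$id)
  if (length(missing_ids) > 0) {
    stop("no predictions for id(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...", call. = FALSE)
  }
  df <- dplyr::inner_join(tibble::as_tibble(cohort), predictions, by = "id")
  e_i <- cum_hazard_net(df$r * df$d, df$age_entry, df$exit_age, rates)
  oe <- oe_ratio(sum(df$event), sum(e_i))
  groups <- group_table(cohort, predictions, rates)
  cal <- calibration_coefficient(cohort, predictions, rates)
  trend <- calibration_trend(cal)
  dlr <- delta_lr(cohort, predictions, rates)
  out <- list(oe = oe, groups = groups, calibration = cal, trend = trend,
              delta_lr = dlr)
  if (!is.null(predictions_b)) {
    pb <- predictions_b[match(cohort$id, predictions_b$id), ]
    pa <- predictions[match(cohort$id, predictions$id), ]
    out$reclassification <- reclassification_matrix(cohort, pa$p10, pb$p10)
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Overall O/E: %d / %.1f = %.2f (95%% CI %.2f-%.2f)\n",
              x$oe$observed, x$oe$expected, x$oe$ratio, x$oe$ci_low,
              x$oe$ci_high))
  print(x$calibration)
  sl <- x$trend[x$trend$term == "slope", ]
  cat(sprintf("  trend slope: %.4f/y (95%% CI %.4f to %.4f)\n",
              sl$estimate, sl$ci_low, sl$ci_high))
  cat(sprintf("  LR chi-square beyond age: %.1f\n", x$delta_lr))
  invisible(x)
}
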