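#' Multiplicative relative-hazard engine with BI-RADS density
#'
#' A woman's hazard of invasive breast cancer is modelled as
#' `r * d * h0(age)`: a product of per-factor relative risks `r` over the
#' classic questionnaire factors, a normalized density multiplier `d`, and a
#' baseline age-specific hazard `h0`.  Both `r` and `d` are normalized
#' against configured population prevalences so that the population-average
#' relative hazard is 1 and `h0` keeps its interpretation as the population
#' incidence.
#'
#' @name risk-engine
NULL

# Map each woman to the category used for a given relative-risk factor.
factor_category <- function(cohort, factor, bmi) {
  switch(factor,
    age_first_birth = cohort$age_first_birth,
    menarche = cohort$menarche,
    n_fdr_bc = cohort$n_fdr_bc,
    menopause = dplyr::case_when(
      cohort$menopause_status %in% c("pre", "peri") ~ cohort$menopause_status,
      cohort$menopause_status == "unknown" ~ "unknown",
      .default = cohort$menopause_age
    ),
    benign_grade = cohort$benign_grade,
    bmi_pre = ifelse(cohort$menopause_status == "post", NA, bmi_band5(bmi)),
    bmi_post = ifelse(cohort$menopause_status == "post", bmi_band5(bmi), NA),
    height = height_band(cohort$height_m),
    fdr_age_cat = cohort$fdr_age_cat,
    sdr_bc = as.character(cohort$sdr_bc),
    fdr_ovarian = as.character(cohort$fdr_ovarian),
    ovarian_personal = as.character(cohort$ovarian_personal),
    stop("unknown factor: ", factor, call. = FALSE)
  )
}

#' Population-average relative risk implied by tables and prevalences
#'
#' The product over factors of the prevalence-weighted mean relative risk,
#' with the pre-/post-menopausal BMI blocks blended by the configured
#' menopausal-status prevalence.  Dividing each woman's factor product by
#' this constant makes the population-average relative hazard 1.
#'
#' @param tables Relative-risk tibble as [default_rr_tables()].
#' @param prevalences Prevalence tibble as [default_prevalences()].
#' @return A positive scalar.
#' @export
population_mean_rr <- function(tables = default_rr_tables(),
                               prevalences = default_prevalences()) {
  joined <- dplyr::inner_join(tables, prevalences,
                              by = c("factor", "category"))
  means <- joined |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(m = sum(.data$prevalence * .data$rr) /
                       sum(.data$prevalence), .groups = "drop")
  post_w <- prevalences |>
    dplyr::filter(.data$factor == "menopause",
                  .data$category %in% cohort_levels("menopause_age")[1:5]) |>
    dplyr::pull("prevalence") |>
    sum()
  m <- function(f) means$m[means$factor == f]
  bmi_mean <- (1 - post_w) * m("bmi_pre") + post_w * m("bmi_post")
  others <- means$m[!means$factor %in% c("bmi_pre", "bmi_post")]
  prod(others) * bmi_mean
}

#' Per-woman relative hazard from classic risk factors
#'
#' The product of per-category relative risks across factors (unknown
#' categories contribute 1.0 — the population risk), optionally divided by
#' [population_mean_rr()] so the cohort average is 1.
#'
#' @param cohort A cohort tibble (follow-up columns not required).
#' @param tables,prevalences Model tables; defaults from
#'   [default_rr_tables()] and [default_prevalences()].
#' @param normalize Divide by the population-mean product?  Default TRUE.
#' @return Numeric vector of positive relative hazards, one per row.
#' @export
relative_hazard <- function(cohort, tables = default_rr_tables(),
                            prevalences = default_prevalences(),
                            normalize = TRUE) {
  bmi <- compute_bmi(cohort$weight_kg, cohort$height_m)
  r <- rep(1, nrow(cohort))
  for (f in unique(tables$factor)) {
    cat_f <- factor_category(cohort, f, bmi)
    tab <- tables[tables$factor == f, ]
    rr <- tab$rr[match(cat_f, tab$category)]
    rr[is.na(rr)] <- 1  # factor not applicable (other BMI block) or unknown
    r <- r * rr
  }
  if (normalize) r <- r / population_mean_rr(tables, prevalences)
  r
}

#' Normalized BI-RADS density multiplier
#'
#' Within the woman's age/BMI band, `d = rr(birads) / sum(prevalence * rr)`,
#' so the prevalence-weighted mean multiplier in every band is exactly 1 and
#' density reshapes relative risk without changing the population incidence.
#' Missing density gives `d = 1`.
#'
#' @param birads Character vector of BI-RADS categories
#'   (`"fatty"`, `"scattered"`, `"heterogeneous"`, `"dense"`, `"missing"`).
#' @param age Age in years (for the band; any age works with the default
#'   band-constant model).
#' @param bmi Body mass index; `NA` uses the unknown-BMI band.
#' @param model Density model tibble as [default_density_model()].
#' @return Numeric vector of positive multipliers.
#' @export
#' @examples
#' density_multiplier("dense", 55, 24)
density_multiplier <- function(birads, age, bmi = NA_real_,
                               model = default_density_model()) {
  bad <- !birads %in% c(.density_levels, "missing")
  if (any(bad)) {
    stop("invalid BI-RADS category '", birads[bad][1], "'", call. = FALSE)
  }
  n <- max(length(birads), length(age), length(bmi))
  x <- tibble::tibble(
    .row = seq_len(n),
    birads = rep_len(birads, n),
    age_band = age_band3(rep_len(age, n)),
    bmi_band = bmi_band4(rep_len(bmi, n))
  )
  denom <- model |>
    dplyr::group_by(.data$age_band, .data$bmi_band) |>
    dplyr::summarise(
      denom = sum(.data$prevalence * .data$rr) / sum(.data$prevalence),
      .groups = "drop"
    )
  out <- x |>
    dplyr::left_join(model, by = c("birads", "age_band", "bmi_band")) |>
    dplyr::left_join(denom, by = c("age_band", "bmi_band")) |>
    dplyr::arrange(.data$.row)
  d <- out$rr / out$denom
  d[out$birads == "missing"] <- 1
  d
}

h0_lookup <- function(rates) {
  function(age) {
    i <- match(pmin(pmax(floor(age), min(rates$age)), max(rates$age)),
               rates$age)
    rates$h0[i]
  }
}

mort_lookup <- function(rates) {
  function(age) {
    i <- match(pmin(pmax(floor(age), min(rates$age)), max(rates$age)),
               rates$age)
    rates$mortality[i]
  }
}

#' Project absolute invasive-cancer risk for one woman
#'
#' Annual discrete cycle with competing mortality: starting from `S(0) = 1`,
#' each year `q_k = 1 - exp(-r d h0(a + k))` converts the relative hazard to
#' an annual cancer probability, cumulative risk gains `S(k) q_k`, and the
#' survivor pool shrinks by both cancer and competing death,
#' `S(k+1) = S(k) (1 - q_k) exp(-m(a + k))`.
#'
#' @param r Relative hazard from [relative_hazard()] (scalar).
#' @param d Density multiplier from [density_multiplier()] (scalar).
#' @param age_entry Age at the start of projection.
#' @param horizon Whole years to project (`age_entry + horizon` must stay
#'   within the rate table).
#' @param rates Baseline rate table as [default_baseline_rates()].
#' @return A `risk_projection` tibble with one row per year: `year`, `age`,
#'   `rel_hazard`, `hazard` (annual cancer hazard `r d h0`), `cum_risk`; the
#'   10-year risk (when `horizon >= 10`) is attached as attribute
#'   `"ten_year_risk"`.
#' @export
project_absolute_risk <- function(r, d, age_entry, horizon = 10,
                                  rates = default_baseline_rates()) {
  stopifnot(length(r) == 1, length(d) == 1, horizon >= 1)
  if (age_entry < min(rates$age) ||
      floor(age_entry) + horizon - 1 > max(rates$age)) {
    stop("projection ages outside the baseline rate table", call. = FALSE)
  }
  h0 <- h0_lookup(rates); m <- mort_lookup(rates)
  rd <- r * d
  ages <- floor(age_entry) + seq_len(horizon) - 1
  q <- 1 - exp(-rd * h0(ages))
  S <- 1; P <- numeric(horizon)
  for (k in seq_len(horizon)) {
    P[k] <- (if (k == 1) 0 else P[k - 1]) + S * q[k]
    S <- S * (1 - q[k]) * exp(-m(ages[k]))
  }
  out <- tibble::tibble(
    year = seq_len(horizon), age = ages, rel_hazard = rd,
    hazard = rd * h0(ages), cum_risk = P
  )
  if (horizon >= 10) attr(out, "ten_year_risk") <- P[10]
  class(out) <- c("risk_projection", class(out))
  out
}

# Vectorized cumulative-risk-at-horizon over many women (same recursion).
cum_risk_at <- function(rd, age_entry, horizon, rates) {
  h0 <- h0_lookup(rates); m <- mort_lookup(rates)
  S <- rep(1, length(rd)); P <- rep(0, length(rd))
  a0 <- floor(age_entry)
  out <- matrix(NA_real_, length(rd), horizon)
  for (k in seq_len(horizon)) {
    a <- a0 + k - 1
    q <- 1 - exp(-rd * h0(a))
    P <- P + S * q
    S <- S * (1 - q) * exp(-m(a))
    out[, k] <- P
  }
  out
}

#' Net cumulative cancer hazard over an observed follow-up window
#'
#' `r d` times the integral of the attained-age step baseline hazard
#' `h0(floor(a))` from `age_entry` to `exit_age`.  This is the quantity whose
#' sum over women is the model-expected number of events given observed
#' follow-up (competing mortality plays no role because death already ends
#' follow-up).
#'
#' @param rd Relative hazard times density multiplier (vector).
#' @param age_entry,exit_age Follow-up window in attained age (vectors).
#' @param rates Baseline rate table.
#' @return Numeric vector of cumulative hazards.
#' @export
cum_hazard_net <- function(rd, age_entry, exit_age,
                           rates = default_baseline_rates()) {
  stopifnot(all(exit_age >= age_entry))
  H <- numeric(length(age_entry))
  for (a in seq(min(rates$age), max(rates$age))) {
    overlap <- pmax(0, pmin(exit_age, a + 1) - pmax(age_entry, a))
    H <- H + overlap * rates$h0[match(a, rates$age)]
  }
  rd * H
}

.strata_levels <- c("<2%", "2% to <3%", "3% to <5%", "5% to <8%", ">=8%")

#' Classify 10-year risk into clinical strata
#'
#' Left-closed, right-open bands following UK clinical guidelines: below
#' average (<2%), average (2% to <3%), above average (3% to <5%), moderately
#' increased (5% to <8%), high (>=8%).
#'
#' @param p10 Numeric vector of 10-year absolute risks in `[0, 1)`.
#' @return Factor with the five stratum levels.
#' @export
#' @examples
#' classify_risk_group(c(0.015, 0.02, 0.085))
classify_risk_group <- function(p10) {
  if (any(is.na(p10)) || any(p10 < 0 | p10 >= 1)) {
    stop("p10 must lie in [0, 1)", call. = FALSE)
  }
  cut(p10, breaks = c(0, 0.02, 0.03, 0.05, 0.08, 1),
      labels = .strata_levels, right = FALSE, include.lowest = TRUE)
}

#' Predict per-woman absolute risk over a cohort
#'
#' Computes the classic-factor relative hazard `r`, the density multiplier
#' `d`, yearly cumulative risks to `horizon`, the 10-year risk and its
#' clinical stratum for every woman.
#'
#' @param cohort A cohort tibble.
#' @param tables,prevalences,density_model,rates Model tables (defaults as
#'   shipped).
#' @param horizon Projection horizon in years (default 10).
#' @param use_density If FALSE, `d` is fixed at 1 (classic-factors-only
#'   model).
#' @return A tibble: `id`, `r`, `d`, `p10`, `stratum`, then `cr1`..
#'   `cr<horizon>` cumulative risks by year.
#' @export
predict_cohort <- function(cohort, tables = default_rr_tables(),
                           prevalences = default_prevalences(),
                           density_model = default_density_model(),
                           rates = default_baseline_rates(),
                           horizon = 10, use_density = TRUE) {
  bmi <- compute_bmi(cohort$weight_kg, cohort$height_m)
  r <- relative_hazard(cohort, tables, prevalences)
  d <- if (use_density) {
    density_multiplier(cohort$birads, cohort$age_entry, bmi, density_model)
  } else {
    rep(1, nrow(cohort))
  }
  P <- cum_risk_at(r * d, cohort$age_entry, max(horizon, 10), rates)
  pred <- tibble::tibble(
    id = cohort$id, r = r, d = d, p10 = P[, 10],
    stratum = classify_risk_group(P[, 10])
  )
  yearly <- tibble::as_tibble(P[, seq_len(horizon), drop = FALSE],
                              .name_repair = ~ paste0("cr", seq_len(horizon)))
  dplyr::bind_cols(pred, yearly)
}
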