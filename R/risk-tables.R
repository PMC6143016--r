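#' Default model tables: relative risks, prevalences, density, baseline rates
#'
#' The engine is a multiplicative relative-risk model.  Its default factor
#' relative risks are the age-adjusted hazard ratios estimated in a large US
#' screening cohort (Kaiser Permanente Washington registry); factors for which
#' no published estimate exists (second-degree family history, ovarian-cancer
#' history, age of the youngest affected relative) default to 1.0 in every
#' category and are configuration points, not fitted quantities.
#'
#' @name model-tables
NULL

#' Default per-factor relative-risk tables
#'
#' @return A tibble with columns `factor`, `category`, `rr`.  Reference
#'   categories carry rr exactly 1.0; unknown categories carry 1.0 (a woman
#'   with a missing answer is assigned the population risk).
#' @export
default_rr_tables <- function() {
  tribble_rr <- function(factor, x) {
    tibble::tibble(factor = factor, category = names(x), rr = unname(x))
  }
  dplyr::bind_rows(
    tribble_rr("age_first_birth", c(
      nulliparous = 1.00, "<20" = 0.83, "20-24" = 0.93, "25-29" = 0.97,
      "30-34" = 1.07, "35-39" = 1.08, ">=40" = 1.27, unknown = 1.00)),
    tribble_rr("menarche", c(
      "<11" = 0.70, "11" = 0.96, "12" = 1.00, "13" = 0.90, "14" = 0.75,
      ">=15" = 0.68, unknown = 1.00)),
    tribble_rr("n_fdr_bc", c("0" = 1.00, "1" = 1.71, ">=2" = 2.04)),
    tribble_rr("menopause", c(
      pre = 1.03, peri = 1.03, "<30" = 0.59, "30-39" = 0.77, "40-49" = 1.00,
      "50-54" = 1.12, ">=55" = 1.24, unknown = 1.00)),
    tribble_rr("benign_grade", c(
      none = 1.00, biopsy = 1.32, usual_hyperplasia = 1.77,
      atypical_hyperplasia = 4.50)),
    tribble_rr("bmi_pre", c(
      "<20" = 1.20, "20-25" = 1.00, "25-30" = 1.08, "30-35" = 0.90,
      ">=35" = 0.81, unknown = 1.00)),
    tribble_rr("bmi_post", c(
      "<20" = 0.79, "20-25" = 1.00, "25-30" = 1.22, "30-35" = 1.14,
      ">=35" = 1.19, unknown = 1.00)),
    tribble_rr("height", c(
      "<1.57" = 1.02, "1.57-1.67" = 1.00, ">=1.67" = 1.18, unknown = 1.00)),
    tribble_rr("fdr_age_cat", c("<50" = 1.00, ">=50" = 1.00, unknown = 1.00)),
    tribble_rr("sdr_bc", c("FALSE" = 1.00, "TRUE" = 1.00)),
    tribble_rr("fdr_ovarian", c("FALSE" = 1.00, "TRUE" = 1.00)),
    tribble_rr("ovarian_personal", c("FALSE" = 1.00, "TRUE" = 1.00))
  )
}

#' Default factor prevalences
#'
#' Category prevalences for the screened population, used both to normalize
#' the relative hazard (so the population-average relative hazard is 1) and
#' as sampling weights for the synthetic-cohort generator.  Family-history
#' extras without published marginals use documented synthetic defaults.
#'
#' @return A tibble with columns `factor`, `category`, `prevalence`
#'   (normalized to sum to 1 within factor).
#' @export
default_prevalences <- function() {
  trib <- function(factor, x) {
    tibble::tibble(factor = factor, category = names(x),
                   prevalence = unname(x) / sum(x))
  }
  dplyr::bind_rows(
    trib("age_first_birth", c(
      nulliparous = .199, "<20" = .153, "20-24" = .285, "25-29" = .184,
      "30-34" = .097, "35-39" = .039, ">=40" = .007, unknown = .036)),
    trib("menarche", c(
      "<11" = .023, "11" = .057, "12" = .113, "13" = .113, "14" = .054,
      ">=15" = .058, unknown = .582)),
    trib("n_fdr_bc", c("0" = .860, "1" = .127, ">=2" = .013)),
    trib("menopause", c(
      pre = .393, "<30" = .025, "30-39" = .082, "40-49" = .198,
      "50-54" = .149, ">=55" = .036, unknown = .118)),
    trib("benign_grade", c(
      none = .934, biopsy = .045, usual_hyperplasia = .017,
      atypical_hyperplasia = .004)),
    trib("bmi_pre", c(
      "<20" = .058, "20-25" = .381, "25-30" = .260, "30-35" = .139,
      ">=35" = .130, unknown = .034)),
    trib("bmi_post", c(
      "<20" = .042, "20-25" = .303, "25-30" = .298, "30-35" = .174,
      ">=35" = .146, unknown = .038)),
    trib("height", c(
      "<1.57" = .135, "1.57-1.67" = .507, ">=1.67" = .331, unknown = .027)),
    # synthetic defaults; relative risks default to 1 so these only shape
    # the simulator's sampled records
    trib("fdr_age_cat", c("<50" = .30, ">=50" = .50, unknown = .20)),
    trib("sdr_bc", c("FALSE" = .88, "TRUE" = .12)),
    trib("fdr_ovarian", c("FALSE" = .98, "TRUE" = .02)),
    trib("ovarian_personal", c("FALSE" = .995, "TRUE" = .005))
  )
}

.density_levels <- c("fatty", "scattered", "heterogeneous", "dense")
.age_bands <- c("<50", "50-59", ">=60")
.bmi_bands4 <- c("<25", "25-30", ">=30", "unknown")

#' Default BI-RADS density model
#'
#' Relative risk and prevalence of the four BI-RADS categories within bands
#' of age (`<50`, `50-59`, `>=60`) and BMI (`<25`, `25-30`, `>=30`,
#' `unknown`).  The default fills every band with the marginal, age- and
#' BMI-adjusted estimates (fatty 0.55, scattered 1.00 reference,
#' heterogeneous 1.69, dense 2.21; prevalences 7.7/35.7/42.3/14.3%): the band
#' structure is a configuration surface for band-specific estimates when
#' available.
#'
#' @return A tibble with columns `birads`, `age_band`, `bmi_band`, `rr`,
#'   `prevalence`.
#' @export
default_density_model <- function() {
  grid <- tidyr::expand_grid(
    age_band = .age_bands, bmi_band = .bmi_bands4,
    birads = .density_levels
  )
  marg_rr <- c(fatty = 0.55, scattered = 1.00, heterogeneous = 1.69,
               dense = 2.21)
  marg_prev <- c(fatty = 0.077, scattered = 0.357, heterogeneous = 0.423,
                 dense = 0.143)
  dplyr::mutate(grid,
    rr = unname(marg_rr[.data$birads]),
    prevalence = unname(marg_prev[.data$birads])
  )[, c("birads", "age_band", "bmi_band", "rr", "prevalence")]
}

#' Default baseline incidence and competing mortality
#'
#' The baseline invasive-cancer hazard `h0` rises log-linearly from
#' 1.3 per 1000 women/year at age 42 to 5.1 per 1000 at age 70 (the observed
#' anchor rates in the validation cohort), held flat outside that range.
#' Competing (non-breast-cancer) mortality is a synthetic Gompertz female
#' all-cause hazard, `m(a) = 0.0013 * exp(0.085 * (a - 40))`, chosen so that
#' death censors roughly 2% of a screening cohort; both columns are
#' replaceable via [read_rates_csv()].
#'
#' @return A tibble with columns `age` (40-90), `h0`, `mortality`.
#' @export
default_baseline_rates <- function() {
  age <- 40:90
  slope <- log(5.1 / 1.3) / (70 - 42)
  h0 <- 0.0013 * exp(slope * (pmin(pmax(age, 42), 70) - 42))
  mortality <- 0.0013 * exp(0.085 * (age - 40))
  tibble::tibble(age = age, h0 = h0, mortality = mortality)
}

#' Read model tables from CSV overrides
#'
#' `read_rr_csv()` expects header `factor,category,rr`;
#' `read_density_csv()` expects `birads,age_band,bmi_band,rr,prevalence`;
#' `read_rates_csv()` expects `age,h0,mortality`.
#'
#' @param path CSV file path.
#' @return The corresponding table as a tibble, checked for required columns
#'   and positivity.
#' @export
read_rr_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(x, c("factor", "category", "rr"), path)
  if (any(x$rr <= 0)) stop("relative risks must be positive", call. = FALSE)
  x
}

#' @rdname read_rr_csv
#' @export
read_density_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(x, c("birads", "age_band", "bmi_band", "rr", "prevalence"), path)
  if (any(x$rr <= 0)) stop("relative risks must be positive", call. = FALSE)
  x
}

#' @rdname read_rr_csv
#' @export
read_rates_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(x, c("age", "h0", "mortality"), path)
  if (any(x$h0 <= 0 | x$h0 >= 0.05)) {
    stop("baseline hazard h0 must lie in (0, 0.05)", call. = FALSE)
  }
  if (any(x$mortality < 0 | x$mortality >= 1)) {
    stop("mortality hazard must lie in [0, 1)", call. = FALSE)
  }
  x
}

check_cols <- function(x, cols, path) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# Band assignment helpers shared by the engine and the simulator.
bmi_band5 <- function(bmi) {
  dplyr::case_when(
    is.na(bmi) ~ "unknown",
    bmi < 20 ~ "<20", bmi < 25 ~ "20-25", bmi < 30 ~ "25-30",
    bmi < 35 ~ "30-35", .default = ">=35"
  )
}

bmi_band4 <- function(bmi) {
  dplyr::case_when(
    is.na(bmi) ~ "unknown",
    bmi < 25 ~ "<25", bmi < 30 ~ "25-30", .default = ">=30"
  )
}

age_band3 <- function(age) {
  dplyr::case_when(age < 50 ~ "<50", age < 60 ~ "50-59", .default = ">=60")
}

height_band <- function(height_m) {
  dplyr::case_when(
    is.na(height_m) ~ "unknown",
    height_m < 1.57 ~ "<1.57", height_m < 1.67 ~ "1.57-1.67",
    .default = ">=1.67"
  )
}
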