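#' Cohort data model: schema, validation, category conversion, eligibility
#'
#' A cohort is an ordinary tibble with one row per woman, holding both the
#' baseline risk-factor questionnaire and the follow-up record.  Unknown
#' categorical answers are kept (coded `"unknown"`), never dropped: downstream
#' they contribute relative risk 1.0, i.e. the population average.
#'
#' @name cohort-model
NULL

# Canonical category levels, used for validation, conversion and simulation.
.levels <- list(
  age_first_birth  = c("nulliparous", "<20", "20-24", "25-29", "30-34",
                       "35-39", ">=40", "unknown"),
  menarche         = c("<11", "11", "12", "13", "14", ">=15", "unknown"),
  menopause_status = c("pre", "peri", "post", "unknown"),
  menopause_age    = c("<30", "30-39", "40-49", "50-54", ">=55", "unknown"),
  n_fdr_bc         = c("0", "1", ">=2"),
  fdr_age_cat      = c("<50", ">=50", "unknown"),
  benign_grade     = c("none", "biopsy", "usual_hyperplasia",
                       "atypical_hyperplasia"),
  birads           = c("fatty", "scattered", "heterogeneous", "dense",
                       "missing"),
  censor_reason    = c("death", "disenrollment", "dcis", "age75",
                       "admin_end", "event")
)

#' Category levels used throughout the package
#'
#' @param field One of the categorical field names
#'   (`"age_first_birth"`, `"menarche"`, `"menopause_status"`,
#'   `"menopause_age"`, `"n_fdr_bc"`, `"fdr_age_cat"`, `"benign_grade"`,
#'   `"birads"`, `"censor_reason"`).
#' @return Character vector of valid categories for `field`.
#' @export
cohort_levels <- function(field) {
  if (!field %in% names(.levels)) {
    stop("unknown categorical field: ", field, call. = FALSE)
  }
  .levels[[field]]
}

# Fixed CSV header, in order.
.cohort_cols <- c(
  "id", "age_entry", "weight_kg", "height_m", "age_first_birth", "menarche",
  "menopause_status", "menopause_age", "n_fdr_bc", "fdr_age_cat", "sdr_bc",
  "fdr_ovarian", "n_biopsies", "benign_grade", "ovarian_personal", "birads",
  "exit_age", "event", "censor_reason"
)

#' Cohort column schema
#'
#' @return A tibble with one row per cohort column: name, type, and a short
#'   description of the coding.
#' @export
cohort_schema <- function() {
  tibble::tibble(
    column = .cohort_cols,
    type = c("character", "double", "double", "double", "category", "category",
             "category", "category", "category", "category", "logical",
             "logical", "integer", "category", "logical", "category (1-4/NA)",
             "double", "integer 0/1", "category"),
    description = c(
      "unique woman identifier",
      "age at cohort entry, years (40-73 after eligibility)",
      "self-reported weight in kg; NA = unknown",
      "self-reported height in m; NA = unknown",
      "age at first live birth category",
      "age at menarche category",
      "menopausal status",
      "age at menopause category (post only)",
      "number of affected first-degree relatives",
      "age of youngest affected first-degree relative",
      "any second-degree relative with breast cancer",
      "any first-degree relative with ovarian cancer",
      "number of previous breast biopsies (0-3)",
      "most severe benign breast disease finding",
      "personal history of ovarian cancer",
      "BI-RADS density: 1 fatty, 2 scattered, 3 heterogeneous, 4 dense",
      "age at end of follow-up, years (<= 75)",
      "1 = invasive breast cancer at exit",
      "why follow-up ended"
    )
  )
}

#' Validate a cohort tibble
#'
#' Checks column presence, category enumerations and record-level invariants:
#' unique ids, `exit_age > age_entry`, `exit_age <= 75`, `event` equivalent to
#' `censor_reason == "event"`, `benign_grade == "none"` implying
#' `n_biopsies == 0`, and `menopause_age` set only for postmenopausal women.
#'
#' @param cohort A data frame with the columns of [cohort_schema()].
#' @return The validated cohort as a tibble (invisibly unchanged).
#' @export
as_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(.cohort_cols, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[.cohort_cols]
  if (anyDuplicated(cohort$id)) {
    stop("cohort ids are not unique", call. = FALSE)
  }
  for (f in c("age_first_birth", "menarche", "menopause_status",
              "menopause_age", "n_fdr_bc", "fdr_age_cat", "benign_grade",
              "birads", "censor_reason")) {
    bad <- !cohort[[f]] %in% .levels[[f]]
    if (any(bad)) {
      stop(sprintf("invalid %s value '%s' (row %d)", f,
                   cohort[[f]][which(bad)[1]], which(bad)[1]), call. = FALSE)
    }
  }
  with(cohort, {
    if (any(exit_age <= age_entry)) {
      stop("exit_age must exceed age_entry (row ",
           which(exit_age <= age_entry)[1], ")", call. = FALSE)
    }
    if (any(exit_age > 75 + 1e-9)) {
      stop("exit_age must be <= 75 (row ", which(exit_age > 75)[1], ")",
           call. = FALSE)
    }
    if (any((event == 1L) != (censor_reason == "event"))) {
      stop("event indicator inconsistent with censor_reason (row ",
           which((event == 1L) != (censor_reason == "event"))[1], ")",
           call. = FALSE)
    }
    if (any(benign_grade == "none" & n_biopsies != 0L)) {
      stop("benign_grade 'none' requires n_biopsies = 0 (row ",
           which(benign_grade == "none" & n_biopsies != 0L)[1], ")",
           call. = FALSE)
    }
    if (any(menopause_status != "post" & menopause_age != "unknown")) {
      stop("menopause_age may only be set for postmenopausal women (row ",
           which(menopause_status != "post" & menopause_age != "unknown")[1],
           ")", call. = FALSE)
    }
  })
  cohort
}

#' Body mass index from self-reported weight and height
#'
#' @param weight_kg Weight in kilograms; `NA` = unknown.
#' @param height_m Height in metres; `NA` = unknown.
#' @return `weight_kg / height_m^2`; `NA` where either input is unknown.
#' @export
#' @examples
#' compute_bmi(70, 1.67)
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.na(weight_kg) & weight_kg <= 0)) {
    stop("weight_kg must be positive", call. = FALSE)
  }
  if (any(!is.na(height_m) & height_m <= 0)) {
    stop("height_m must be positive", call. = FALSE)
  }
  weight_kg / height_m^2
}

# Midpoint dialect for converting age categories to single years.  Closed
# intervals map to their midpoint; open-ended categories use fixed,
# documented values; ages of affected relatives get the coarser rule.
.year_dialect <- list(
  age_first_birth = c("<20" = 18, "20-24" = 22, "25-29" = 27, "30-34" = 32,
                      "35-39" = 37, ">=40" = 41, "nulliparous" = NA,
                      "unknown" = NA),
  menarche = c("<11" = 10, "11" = 11, "12" = 12, "13" = 13, "14" = 14,
               ">=15" = 16, "unknown" = NA),
  menopause_age = c("<30" = 27.5, "30-39" = 34.5, "40-49" = 44.5,
                    "50-54" = 52, ">=55" = 56, "unknown" = NA),
  fdr_age_cat = c("<50" = 45, ">=50" = 60, "unknown" = 50)
)

#' Convert an age category to a single year
#'
#' Closed intervals map to their midpoint (`"20-24"` to 22); open-ended
#' categories use a fixed documented dialect (menarche `"<11"` to 10,
#' `">=15"` to 16; menopause `"<30"` to 27.5, `">=55"` to 56; first birth
#' `">=40"` to 41; affected-relative ages `"<50"` to 45, `">=50"` to 60,
#' unknown to 50).  Unknown (and nulliparous for first birth) maps to `NA`
#' except for relatives' ages, where the model needs a working value.
#'
#' @param category Character vector of categories.
#' @param field One of `"age_first_birth"`, `"menarche"`, `"menopause_age"`,
#'   `"fdr_age_cat"`.
#' @return Numeric vector of years.
#' @export
#' @examples
#' category_to_years("20-24", "age_first_birth")
category_to_years <- function(category, field) {
  if (!field %in% names(.year_dialect)) {
    stop("no year dialect for field: ", field, call. = FALSE)
  }
  map <- .year_dialect[[field]]
  bad <- !category %in% names(map)
  if (any(bad)) {
    stop(sprintf("unrecognized %s category '%s'", field, category[bad][1]),
         call. = FALSE)
  }
  unname(map[category])
}

#' Apply cohort eligibility rules
#'
#' Restricts to women aged 40-73 at entry with no prior invasive breast
#' cancer, DCIS or LCIS (optional logical columns `prior_invasive`,
#' `prior_dcis`, `prior_lcis`; absent columns are treated as all-FALSE), and
#' removes events diagnosed within 6 months of entry so the cohort starts
#' screen-negative.  Filters only; never raises on content.
#'
#' @param cohort A cohort tibble.
#' @return A list with `cohort` (the eligible subset) and `tally`, a tibble of
#'   exclusion reasons and counts.  Reasons are assigned in priority order:
#'   age, prior diagnosis, early event.
#' @export
apply_eligibility <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  flag <- function(col) {
    if (col %in% names(cohort)) isTRUE_vec(cohort[[col]]) else
      rep(FALSE, nrow(cohort))
  }
  bad_age <- cohort$age_entry < 40 | cohort$age_entry > 73
  prior <- flag("prior_invasive") | flag("prior_dcis") | flag("prior_lcis")
  early <- cohort$event == 1L & (cohort$exit_age - cohort$age_entry) < 0.5
  reason <- dplyr::case_when(
    bad_age ~ "age",
    prior ~ "prior_diagnosis",
    early ~ "early_event",
    .default = NA_character_
  )
  tally <- dplyr::count(
    dplyr::filter(tibble::tibble(reason = reason), !is.na(reason)),
    .data$reason, name = "n"
  )
  list(cohort = cohort[is.na(reason), , drop = FALSE], tally = tally)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read / write the cohort CSV
#'
#' One row per woman with the fixed header of [cohort_schema()].  BI-RADS
#' density is coded 1-4 (fatty to dense) with empty/NA meaning not recorded;
#' all other unknowns are empty strings or NA.  The round trip
#' `read_cohort(write_cohort(x))` is the identity on valid cohorts.
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated cohort tibble.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      age_entry = readr::col_double(),
      weight_kg = readr::col_double(),
      height_m = readr::col_double(),
      n_biopsies = readr::col_integer(),
      sdr_bc = readr::col_logical(),
      fdr_ovarian = readr::col_logical(),
      ovarian_personal = readr::col_logical(),
      birads = readr::col_integer(),
      exit_age = readr::col_double(),
      event = readr::col_integer(),
      .default = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(.cohort_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  birads_lab <- .levels$birads[1:4]
  out <- raw |>
    dplyr::mutate(
      dplyr::across(
        c("age_first_birth", "menarche", "menopause_status", "menopause_age",
          "fdr_age_cat", "benign_grade", "n_fdr_bc"),
        ~ dplyr::coalesce(.x, "unknown")
      ),
      benign_grade = dplyr::if_else(.data$benign_grade == "unknown", "none",
                                    .data$benign_grade),
      n_fdr_bc = dplyr::if_else(.data$n_fdr_bc == "unknown", "0",
                                .data$n_fdr_bc),
      birads = dplyr::if_else(is.na(.data$birads), "missing",
                              birads_lab[.data$birads]),
      n_biopsies = dplyr::coalesce(.data$n_biopsies, 0L),
      dplyr::across(c("sdr_bc", "fdr_ovarian", "ovarian_personal"),
                    ~ dplyr::coalesce(.x, FALSE))
    )
  as_cohort(out)
}

#' @rdname read_cohort
#' @param cohort A validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  out <- cohort |>
    dplyr::mutate(
      birads = dplyr::if_else(.data$birads == "missing", NA_integer_,
                              match(.data$birads, .levels$birads[1:4])),
      dplyr::across(
        c("age_first_birth", "menarche", "menopause_status", "menopause_age",
          "fdr_age_cat"),
        ~ dplyr::if_else(.x == "unknown", NA_character_, .x)
      )
    )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
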