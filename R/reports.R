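#' Report writers and run manifests
#'
#' Thin writers turning pipeline outputs into plain-text artifacts: a
#' predictions CSV, a validation report directory (stratum table, calibration
#' JSON with fixed key names, reclassification and curve-point CSVs), and a
#' run manifest recording what produced the outputs.
#'
#' @name reports
NULL

#' Write per-woman predictions to CSV
#'
#' Columns: `id`, `r`, `d`, `p10`, `stratum`, then the yearly cumulative
#' risks `p1..p<horizon>`.  Rerunning with the same inputs yields a
#' byte-identical file.
#'
#' @param predictions Tibble from [predict_cohort()].
#' @param path Output CSV path.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_csv(predictions, path, progress = FALSE)
  invisible(path)
}

#' Read back a predictions CSV
#'
#' @param path CSV path written by [write_predictions()].
#' @return The predictions tibble with `stratum` restored as a factor.
#' @export
read_predictions <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(id = readr::col_character(),
                                               stratum = readr::col_character(),
                                               .default = readr::col_double()))
  x$stratum <- factor(x$stratum, levels = .strata_levels)
  x
}

#' Write a validation report directory
#'
#' Emits `group_table.csv` (the stratum calibration table),
#' `calibration.json` (keys `beta`, `beta_ci`, `intercept`, `slope`,
#' `slope_ci`, `delta_lr`), `km_curves.csv` when curves are supplied,
#' `reclassification.csv` when a two-model report was run, and
#' `manifest.json` describing the run.
#'
#' @param report A `validation_report` from [run_validation()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @param inputs Named character vector/list of input paths for the manifest.
#' @param km Optional `km_curves` tibble from [km_cumulative_risk()].
#' @return The directory path, invisibly.
#' @export
write_validation_report <- function(report, dir, seed = NA, inputs = list(),
                                    km = NULL) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$groups, file.path(dir, "group_table.csv"),
                   progress = FALSE)
  tr <- report$trend
  cal <- list(
    beta = report$calibration$beta,
    beta_ci = unname(report$calibration$ci),
    intercept = tr$estimate[tr$term == "intercept"],
    slope = tr$estimate[tr$term == "slope"],
    slope_ci = c(tr$ci_low[tr$term == "slope"],
                 tr$ci_high[tr$term == "slope"]),
    delta_lr = report$delta_lr
  )
  jsonlite::write_json(cal, file.path(dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$reclassification)) {
    readr::write_csv(report$reclassification,
                     file.path(dir, "reclassification.csv"), progress = FALSE)
  }
  if (!is.null(km)) {
    readr::write_csv(km, file.path(dir, "km_curves.csv"), progress = FALSE)
  }
  manifest <- list(
    command = "run_validation",
    package = "mammorisk",
    version = as.character(utils::packageVersion("mammorisk")),
    seed = seed,
    inputs = inputs,
    outputs = list.files(dir),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
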