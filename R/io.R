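# Plain-text I/O: per-case daily CSVs, fire-event tables, scenario YAML,
# and JSON/CSV report writers.

CASE_COLUMNS <- c("date", "P_mm", "T_C", "Hr_day", "SWE_mm", "Q_mm")

#' Read a per-watershed daily series CSV
#'
#' Expects columns `date, P_mm, T_C, Hr_day, SWE_mm, Q_mm` (extra columns
#' such as `PET_mm` are kept). Dates must be strictly increasing. A missing
#' `SWE_mm` column is tolerated with a warning -- snow-dependent analyses
#' (CEM4) are then unavailable.
#'
#' @param path CSV file path.
#' @return Daily data frame with `date` as `Date`.
#' @export
read_case_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(CASE_COLUMNS, "SWE_mm")
  missing <- setdiff(required, names(d))
  stop_if(length(missing) > 0,
          "missing column(s): ", paste(missing, collapse = ", "))
  if (!"SWE_mm" %in% names(d))
    warning("no SWE_mm column: snow-based elasticity (CEM4) disabled")
  d$date <- as.Date(d$date)
  stop_if(anyNA(d$date), "unparseable dates")
  stop_if(any(diff(as.numeric(d$date)) <= 0), "dates must be increasing")
  d
}

#' Write a per-watershed daily series CSV
#'
#' @param daily Daily data frame (e.g. a cohort case's `daily` element).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case_csv <- function(daily, path) {
  keep <- intersect(c(CASE_COLUMNS, "PET_mm"), names(daily))
  write.csv(daily[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the cohort fire-event table
#'
#' One row per case: `case_id, fire_date, BAR, frac_unburned, frac_low,
#' frac_moderate, frac_high, frac_greenness` (watershed-area fractions).
#'
#' @param cohort List of `synthetic_case` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fire_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(cs) {
    af <- cs$fire$area_fractions
    data.frame(case_id = cs$id, fire_date = as.character(cs$fire$date),
               BAR = cs$fire$bar,
               frac_unburned = af[["unburned"]], frac_low = af[["low"]],
               frac_moderate = af[["moderate"]], frac_high = af[["high"]],
               frac_greenness = af[["greenness"]])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline reports
#'
#' Writes the per-watershed case table as CSV and the full report (cohort
#' summary plus per-case records) as JSON. Files are written to a temporary
#' name and renamed into place so partially written outputs never appear.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "case_reports.csv")
  json <- file.path(dir, "report.json")
  atomically <- function(path, fn) {
    tmp <- paste0(path, ".tmp")
    fn(tmp)
    file.rename(tmp, path)
  }
  atomically(csv, function(p)
    write.csv(result$case_table, p, row.names = FALSE, quote = FALSE))
  atomically(json, function(p)
    jsonlite::write_json(
      list(summary = result$summary, cases = result$case_table),
      p, auto_unbox = TRUE, digits = NA, na = "null"))
  invisible(c(csv = csv, json = json))
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; unknown
#' keys raise an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  stop_if(length(unknown) > 0,
          "unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, cfg)
}
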