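#' Write the implementation workbook
#'
#' Renders the pipeline result as the four-sheet workbook used for
#' downstream statistical analysis:
#'
#' 1. `by monitor` — one row per (patient, monitor, day) with expected,
#'    recorded, added and corrected openings, the monitored flag, and the
#'    daily implementation (nonmonitored days are genuinely empty cells,
#'    not 0 or the text "NA");
#' 2. `by patient` — one row per (patient, day) with the combined
#'    implementation;
#' 3. `summary by monitor` — days, rates, window dates and EM covariables;
#' 4. `summary by patient` — days, rates and patient covariables.
#'
#' Refuses to write while critical errors are outstanding (warnings do not
#' block). Dates are serialised as ISO 8601.
#'
#' @param result An `adh_implementation` object from [clean_adherence()].
#' @param path Output path, conventionally `implementation.xlsx` next to
#'   the auxiliary workbook.
#' @param csv Also write one CSV mirror per sheet (same basename, suffixed
#'   with the sheet name)? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_implementation <- function(result, path, csv = FALSE) {
  stopifnot(inherits(result, "adh_implementation"))
  if (!result$ok || has_errors(result$report)) {
    stop("critical errors outstanding; implementation workbook not written ",
         "(see errors.log / the validation report)", call. = FALSE)
  }
  sheets <- implementation_sheets(result)
  write_xlsx_sheets(sheets, path)
  if (csv) {
    base <- sub("\\.xlsx$", "", path)
    for (nm in names(sheets)) {
      readr::write_csv(sheets[[nm]],
                       paste0(base, "_", gsub(" ", "_", nm), ".csv"),
                       na = "")
    }
  }
  invisible(path)
}

implementation_sheets <- function(result) {
  by_monitor <- result$monitor_daily |>
    dplyr::transmute(
      PatientCode = .data$patient_code,
      Monitor = .data$monitor,
      Date = .data$date,
      ExpectedOpenings = .data$expected,
      RecordedOpenings = .data$recorded,
      AddedOpenings = .data$adjustment,
      CorrectedOpenings = .data$corrected,
      Monitored = as.integer(.data$monitored),
      Implementation = .data$implementation
    )
  by_patient <- result$patient_daily |>
    dplyr::transmute(
      PatientCode = .data$patient_code,
      Date = .data$date,
      Implementation = .data$implementation
    )
  sm <- result$monitor_summary
  summary_monitor <- tibble::tibble(
    PatientCode = sm$patient_code,
    Monitor = sm$monitor,
    StartDate = sm$start_date,
    EndDate = sm$end_date,
    MonitoredDays = sm$monitored_days,
    OptimalDays = sm$optimal_days,
    ImplementationRate = sm$implementation_rate
  )
  extra_m <- setdiff(names(sm), c("patient_code", "monitor", "start_date",
                                  "end_date", "monitored_days", "optimal_days",
                                  "implementation_rate"))
  for (cn in extra_m) summary_monitor[[cn]] <- sm[[cn]]
  sp <- result$patient_summary
  summary_patient <- tibble::tibble(
    PatientCode = sp$patient_code,
    MonitoredDays = sp$monitored_days,
    OptimalDays = sp$optimal_days,
    ImplementationRate = sp$implementation_rate
  )
  extra_p <- setdiff(names(sp), c("patient_code", "monitored_days",
                                  "optimal_days", "implementation_rate"))
  for (cn in extra_p) summary_patient[[cn]] <- sp[[cn]]
  list("by monitor" = by_monitor,
       "by patient" = by_patient,
       "summary by monitor" = summary_monitor,
       "summary by patient" = summary_patient)
}

#' Read back an implementation workbook
#'
#' Inverse of [write_implementation()], used to verify that the written
#' sheets reproduce the in-memory tables (empty cells come back as `NA`).
#'
#' @param path Workbook path.
#' @return Named list of tibbles, one per sheet.
#' @export
read_implementation <- function(path) {
  sheets <- readxl::excel_sheets(path)
  out <- lapply(sheets, function(s) {
    df <- suppressMessages(readxl::read_excel(path, sheet = s, col_types = "list"))
    tibble::as_tibble(lapply(df, simplify_cell_col))
  })
  names(out) <- sheets
  out
}

#' Write the error and warning log files
#'
#' Writes `errors.log` and `warnings.log` (always both, possibly empty)
#' into `folder` — conventionally the folder of the Auxiliary Data
#' workbook. One finding per line, tab-separated:
#' `CODE<TAB>sheet/file<TAB>row<TAB>message`, deterministically ordered by
#' (sheet, row, code), so identical runs produce byte-identical logs.
#'
#' @param report A validation report tibble.
#' @param folder Output directory.
#' @return Character vector of the two paths, invisibly.
#' @export
write_logs <- function(report, folder) {
  if (!dir.exists(folder)) dir.create(folder, recursive = TRUE)
  fmt <- function(df) {
    if (nrow(df) == 0) return(character())
    df <- df[order(ifelse(is.na(df$sheet), "", df$sheet),
                   ifelse(is.na(df$row), .Machine$integer.max, df$row),
                   df$code), ]
    paste(df$code,
          ifelse(is.na(df$sheet), "-", df$sheet),
          ifelse(is.na(df$row), "-", as.character(df$row)),
          df$message, sep = "\t")
  }
  err_path <- file.path(folder, "errors.log")
  warn_path <- file.path(folder, "warnings.log")
  writeLines(fmt(report_errors(report)), err_path, useBytes = TRUE)
  writeLines(fmt(report_warnings(report)), warn_path, useBytes = TRUE)
  invisible(c(err_path, warn_path))
}
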