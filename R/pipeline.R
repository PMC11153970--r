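#' Clean EM adherence data and compute implementation
#'
#' End-to-end pipeline: load the Auxiliary Data workbook and the raw EM
#' files, validate them against each other, build the expected-openings
#' schedule for every monitoring window, apply the documented corrections
#' (pocket doses, extra openings) and the nonmonitored-period censoring,
#' and compute the daily binary implementation statistic per monitor, per
#' patient, and as summary rates.
#'
#' When any critical error is found the result carries the validation
#' report and no implementation tables (`ok = FALSE`); warnings alone never
#' block the calculation. With `corrections = FALSE` the same calculus runs
#' with adjustments and censoring disabled (schedule and window truncation
#' still apply) — the "raw" implementation used for before/after-cleaning
#' comparisons.
#'
#' @param aux Path to the Auxiliary Data workbook, or an `adh_aux` object
#'   from [read_auxiliary()] / [as_auxiliary()].
#' @param raw Path to the raw EM data folder, or a pre-aggregated daily
#'   openings tibble (`patient_code`, `monitor`, `date`, `recorded`).
#' @param corrections Apply adjustments and censoring? Default `TRUE`.
#' @return An object of class `adh_implementation` with components
#'   `monitor_daily` (per monitor-day ledger: expected, recorded,
#'   adjustment, corrected, monitored, implementation), `patient_daily`,
#'   `monitor_summary`, `patient_summary`, `report`, `ok`, `corrections`.
#'   Use [generics::tidy()] / [generics::glance()] to extract tidy tables,
#'   [ggplot2::autoplot()] to visualise, and [write_implementation()] /
#'   [write_logs()] to render files.
#' @examples
#' \donttest{
#' sim <- simulate_adherence(simulation_config(n_patients = 2, seed = 1))
#' res <- clean_adherence(sim$aux, sim$daily)
#' glance(res)
#' }
#' @export
clean_adherence <- function(aux, raw, corrections = TRUE) {
  if (is.character(aux)) aux <- read_auxiliary(aux)
  stopifnot(inherits(aux, "adh_aux"))
  if (is.character(raw)) {
    raw <- read_raw_folder(raw)
  } else if (is.data.frame(raw)) {
    raw <- list(daily = raw, report = empty_report())
  }
  stopifnot(is.list(raw), !is.null(raw$daily))
  daily <- raw$daily

  monitors_seen <- dplyr::distinct(daily, .data$patient_code, .data$monitor)
  report <- bind_reports(aux$report, raw$report,
                         validate_cross_references(aux, monitors_seen))

  empty_result <- function(report) {
    structure(list(
      monitor_daily = NULL, patient_daily = NULL,
      monitor_summary = NULL, patient_summary = NULL,
      report = report, ok = FALSE, corrections = corrections,
      aux = aux
    ), class = "adh_implementation")
  }
  if (has_errors(report)) return(empty_result(report))

  # drop events for undeclared monitors (warned above)
  em_key <- paste(aux$em_info$patient_code, aux$em_info$monitor, sep = "\r")
  daily <- daily[paste(daily$patient_code, daily$monitor, sep = "\r") %in% em_key, ]

  ledger <- build_schedules(aux$em_info, aux$regimen)

  adjustments <- if (corrections) aux$added_openings else
    aux$added_openings[0, , drop = FALSE]
  adj <- apply_adjustments(ledger, daily, adjustments)
  report <- bind_reports(report, if (corrections) adj$report)

  nmp <- if (corrections) aux$nonmonitored_periods else
    aux$nonmonitored_periods[0, , drop = FALSE]
  cen <- apply_censoring(adj$ledger, nmp)
  report <- bind_reports(report, if (corrections) cen$report)

  monitor_daily <- cen$ledger |>
    dplyr::mutate(implementation = daily_implementation(
      .data$corrected, .data$expected, .data$monitored))

  pdays <- patient_daily(monitor_daily)
  ms <- summarize_monitors(monitor_daily, aux$em_info, aux$em_covariables)
  ps <- summarize_patients(pdays, aux$patient_covariables)
  report <- bind_reports(report, ms$report, ps$report)

  structure(list(
    monitor_daily = monitor_daily,
    patient_daily = pdays,
    monitor_summary = ms$summary,
    patient_summary = ps$summary,
    report = report,
    ok = TRUE,
    corrections = corrections,
    aux = aux
  ), class = "adh_implementation")
}

#' @export
print.adh_implementation <- function(x, ...) {
  cat("<EM adherence implementation>\n")
  if (!x$ok) {
    cat("  BLOCKED by ", nrow(report_errors(x$report)),
        " critical error(s); no implementation computed.\n", sep = "")
    cat("  First errors:\n")
    errs <- utils::head(report_errors(x$report), 5)
    for (i in seq_len(nrow(errs))) {
      cat("    [", errs$code[i], "] ", errs$sheet[i],
          if (!is.na(errs$row[i])) paste0(" row ", errs$row[i]), ": ",
          errs$message[i], "\n", sep = "")
    }
    return(invisible(x))
  }
  g <- glance(x)
  cat("  corrections:        ", if (x$corrections) "applied" else "disabled (raw)", "\n", sep = "")
  cat("  patients / monitors: ", g$n_patients, " / ", g$n_monitors, "\n", sep = "")
  cat("  monitor-days:        ", g$monitor_days, " (", g$censored_days,
      " censored)\n", sep = "")
  cat("  median implementation by patient: ",
      sprintf("%.1f%%", 100 * g$median_patient_rate), "\n", sep = "")
  cat("  findings:            ", g$n_errors, " error(s), ", g$n_warnings,
      " warning(s)\n", sep = "")
  invisible(x)
}
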