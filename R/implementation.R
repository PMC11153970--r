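#' Daily binary implementation for a monitor
#'
#' Implementation on a given day is *optimal* (1) when the corrected number
#' of EM openings is at least equal to the number of expected openings, and
#' *suboptimal* (0) otherwise. Two consequences of the "at least equal"
#' rule are worth spelling out: overconsumption is not penalised
#' (`corrected = 3, expected = 1` is optimal), and Off-cycle days with
#' `expected = 0` are trivially optimal (`0 >= 0`), so they stay in the
#' denominator of cyclic-regimen rates. On nonmonitored (censored) days
#' implementation is not calculated (`NA`).
#'
#' @param corrected Integer vector of corrected opening counts.
#' @param expected Integer vector of expected opening counts.
#' @param monitored Logical vector; `FALSE` forces `NA`.
#' @return Integer vector in `{0, 1, NA}`.
#' @examples
#' daily_implementation(c(1, 0, 3, 0), c(1, 1, 1, 0))
#' @export
daily_implementation <- function(corrected, expected, monitored = TRUE) {
  value <- ifelse(corrected >= expected, 1L, 0L)
  ifelse(rep_len(monitored, length(value)), value, NA_integer_)
}

#' Combine per-monitor daily implementation at patient level
#'
#' On each day, the patient's implementation is the product of the
#' implementation of every EM in scope (monitors whose monitoring window
#' covers that day): suboptimal (0) on at least one monitor makes the
#' patient day suboptimal; a nonmonitored day on at least one monitor makes
#' the patient day nonmonitored (`NA`).
#'
#' @param monitor_daily Monitor-day tibble with `patient_code`, `monitor`,
#'   `date`, `implementation`.
#' @return Tibble `patient_code`, `date`, `implementation`,
#'   `n_monitors_in_scope`.
#' @export
patient_daily <- function(monitor_daily) {
  monitor_daily |>
    dplyr::group_by(.data$patient_code, .data$date) |>
    dplyr::summarise(
      implementation = if (anyNA(.data$implementation)) NA_integer_ else
        as.integer(prod(.data$implementation)),
      n_monitors_in_scope = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_code, .data$date)
}

#' Summarise implementation by monitor
#'
#' The implementation rate of a monitor is the number of days with optimal
#' implementation over the number of monitored days (nonmonitored days are
#' excluded from both numerator and denominator). EM-level covariables are
#' joined by (patient, monitor) key.
#'
#' @param monitor_daily Monitor-day tibble with `implementation` values.
#' @param em_info `EMInfo` tibble (for window start/end columns).
#' @param em_covariables Optional EM covariables tibble.
#' @return List with `summary` (tibble `patient_code`, `monitor`,
#'   `start_date`, `end_date`, `monitored_days`, `optimal_days`,
#'   `implementation_rate`, joined covariables) and `report` (warning
#'   `ZERO_DENOMINATOR` for fully censored monitors, whose rate is `NA`).
#' @export
summarize_monitors <- function(monitor_daily, em_info = NULL,
                               em_covariables = NULL) {
  smry <- monitor_daily |>
    dplyr::group_by(.data$patient_code, .data$monitor) |>
    dplyr::summarise(
      monitored_days = sum(!is.na(.data$implementation)),
      optimal_days = sum(.data$implementation == 1L, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(implementation_rate = ifelse(
      .data$monitored_days > 0,
      .data$optimal_days / .data$monitored_days, NA_real_))
  report <- empty_report()
  zero <- dplyr::filter(smry, .data$monitored_days == 0)
  for (i in seq_len(nrow(zero))) {
    report <- bind_reports(report, report_entry(
      "warning", "ZERO_DENOMINATOR", "summary by monitor", NA,
      paste0("monitor ", zero$patient_code[i], "/", zero$monitor[i],
             " has no monitored days; implementation rate undefined")))
  }
  if (!is.null(em_info)) {
    smry <- smry |>
      dplyr::left_join(
        dplyr::select(em_info, "patient_code", "monitor", "start_date", "end_date"),
        by = c("patient_code", "monitor")) |>
      dplyr::relocate("start_date", "end_date", .after = "monitor")
  }
  if (!is.null(em_covariables) && nrow(em_covariables) > 0) {
    smry <- dplyr::left_join(
      smry, em_covariables[setdiff(names(em_covariables), "row")],
      by = c("patient_code", "monitor"))
  }
  list(summary = smry, report = report)
}

#' Summarise implementation by patient
#'
#' Patient-level analogue of [summarize_monitors()]: optimal patient-days
#' over monitored patient-days, with patient covariables joined by
#' `patient_code`.
#'
#' @param patient_days Patient-day tibble from [patient_daily()].
#' @param patient_covariables Optional patient covariables tibble.
#' @return List with `summary` and `report` (see [summarize_monitors()]).
#' @export
summarize_patients <- function(patient_days, patient_covariables = NULL) {
  smry <- patient_days |>
    dplyr::group_by(.data$patient_code) |>
    dplyr::summarise(
      monitored_days = sum(!is.na(.data$implementation)),
      optimal_days = sum(.data$implementation == 1L, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(implementation_rate = ifelse(
      .data$monitored_days > 0,
      .data$optimal_days / .data$monitored_days, NA_real_))
  report <- empty_report()
  zero <- dplyr::filter(smry, .data$monitored_days == 0)
  for (i in seq_len(nrow(zero))) {
    report <- bind_reports(report, report_entry(
      "warning", "ZERO_DENOMINATOR", "summary by patient", NA,
      paste0("patient ", zero$patient_code[i],
             " has no monitored days; implementation rate undefined")))
  }
  if (!is.null(patient_covariables) && nrow(patient_covariables) > 0) {
    smry <- dplyr::left_join(
      smry, patient_covariables[setdiff(names(patient_covariables), "row")],
      by = "patient_code")
  }
  list(summary = smry, report = report)
}
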