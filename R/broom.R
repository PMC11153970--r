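#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the implementation result
#'
#' Returns one of the result's tables as a tibble.
#'
#' @param x An `adh_implementation` object.
#' @param level Which table: `"monitor"` / `"patient"` (the summaries) or
#'   `"monitor_day"` / `"patient_day"` (the daily ledgers).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy adh_implementation
#' @export
tidy.adh_implementation <- function(x, level = c("monitor", "patient",
                                                 "monitor_day", "patient_day"),
                                    ...) {
  level <- match.arg(level)
  if (!x$ok) stop("pipeline blocked by critical errors; nothing to tidy",
                  call. = FALSE)
  switch(level,
    monitor = x$monitor_summary,
    patient = x$patient_summary,
    monitor_day = x$monitor_daily,
    patient_day = x$patient_daily
  )
}

#' One-row overview of an implementation result
#'
#' @param x An `adh_implementation` object.
#' @param ... Unused.
#' @return A one-row tibble with counts of patients, monitors, monitor-days
#'   (total and censored), the median monitor and patient implementation
#'   rates, and the numbers of errors and warnings.
#' @method glance adh_implementation
#' @export
glance.adh_implementation <- function(x, ...) {
  if (!x$ok) {
    return(tibble::tibble(
      n_patients = NA_integer_, n_monitors = NA_integer_,
      monitor_days = NA_integer_, censored_days = NA_integer_,
      median_monitor_rate = NA_real_, median_patient_rate = NA_real_,
      n_errors = nrow(report_errors(x$report)),
      n_warnings = nrow(report_warnings(x$report))
    ))
  }
  tibble::tibble(
    n_patients = dplyr::n_distinct(x$patient_summary$patient_code),
    n_monitors = nrow(x$monitor_summary),
    monitor_days = nrow(x$monitor_daily),
    censored_days = sum(!x$monitor_daily$monitored),
    median_monitor_rate = stats::median(x$monitor_summary$implementation_rate,
                                        na.rm = TRUE),
    median_patient_rate = stats::median(x$patient_summary$implementation_rate,
                                        na.rm = TRUE),
    n_errors = nrow(report_errors(x$report)),
    n_warnings = nrow(report_warnings(x$report))
  )
}
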