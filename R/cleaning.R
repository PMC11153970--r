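#' Apply documented opening adjustments to the daily ledger
#'
#' Adds the investigator-documented corrections to the recorded counts:
#' positive deltas insert pocket doses (doses taken without opening the EM),
#' negative deltas remove documented extra openings (e.g. a pharmacist
#' checking pills left). The corrected count is
#' `corrected = max(0, recorded + adjustment)`; days the ledger does not
#' list are treated as `recorded = 0`. Adjustments dated outside the
#' monitor's window are ignored with warning `ADJUST_OUT_OF_WINDOW`; a
#' clamp at zero (over-deletion) yields warning `NEGATIVE_CLAMP` rather
#' than an error, so the investigator sees the mistake without the run
#' being blocked.
#'
#' @param ledger Tibble with one row per monitor-day (`patient_code`,
#'   `monitor`, `date`, `expected`) covering exactly the monitoring
#'   windows, e.g. from [build_schedules()].
#' @param daily Recorded openings per day (`patient_code`, `monitor`,
#'   `date`, `recorded`), e.g. from [read_raw_folder()].
#' @param adjustments `AddedOpenings` tibble (`patient_code`, `monitor`,
#'   `date`, `openings_delta`).
#' @return List with `ledger` (input plus `recorded`, `adjustment`,
#'   `corrected` columns) and `report`.
#' @export
apply_adjustments <- function(ledger, daily, adjustments) {
  report <- empty_report()
  out <- ledger |>
    dplyr::left_join(daily, by = c("patient_code", "monitor", "date")) |>
    dplyr::mutate(recorded = as.integer(dplyr::coalesce(.data$recorded, 0L)))

  adj <- adjustments
  if (nrow(adj) > 0) {
    key_ledger <- paste(out$patient_code, out$monitor, out$date, sep = "\r")
    key_adj <- paste(adj$patient_code, adj$monitor, adj$date, sep = "\r")
    in_window <- key_adj %in% key_ledger
    for (i in which(!in_window)) {
      report <- bind_reports(report, report_entry(
        "warning", "ADJUST_OUT_OF_WINDOW", "AddedOpenings",
        adj$row[i] %||% NA_integer_,
        paste0("adjustment for ", adj$patient_code[i], "/", adj$monitor[i],
               " on ", format(adj$date[i]),
               " falls outside the monitoring window; ignored")))
    }
    adj <- adj[in_window, , drop = FALSE]
  }
  adj_sum <- adj |>
    dplyr::group_by(.data$patient_code, .data$monitor, .data$date) |>
    dplyr::summarise(adjustment = as.integer(sum(.data$openings_delta)),
                     .groups = "drop")
  out <- out |>
    dplyr::left_join(adj_sum, by = c("patient_code", "monitor", "date")) |>
    dplyr::mutate(
      adjustment = as.integer(dplyr::coalesce(.data$adjustment, 0L)),
      corrected = pmax(0L, .data$recorded + .data$adjustment)
    )
  clamped <- out |>
    dplyr::filter(.data$recorded + .data$adjustment < 0L)
  for (i in seq_len(nrow(clamped))) {
    report <- bind_reports(report, report_entry(
      "warning", "NEGATIVE_CLAMP", "AddedOpenings", NA,
      paste0("corrected openings for ", clamped$patient_code[i], "/",
             clamped$monitor[i], " on ", format(clamped$date[i]),
             " would be negative (", clamped$recorded[i], " recorded ",
             sprintf("%+d", clamped$adjustment[i]), "); clamped to 0")))
  }
  list(ledger = out, report = report)
}

#' Censor nonmonitored periods in the daily ledger
#'
#' Marks every ledger day that falls inside a declared nonmonitored period
#' (holiday, hospitalisation, documented EM nonuse) as `monitored = FALSE`.
#' Implementation is never calculated on censored days: they are excluded
#' from both numerator and denominator of every rate. Intervals are clipped
#' to the monitoring window (warning `NMP_CLIPPED` when clipping occurred);
#' an interval with no overlap at all yields warning `NMP_OUT_OF_WINDOW`
#' and has no effect. Overlapping intervals censor their union.
#'
#' @param ledger Monitor-day tibble (as produced by [apply_adjustments()]).
#' @param nmp `NonMonitoredPeriods` tibble (`patient_code`, `monitor`,
#'   `start_date`, `end_date`).
#' @return List with `ledger` (input plus logical `monitored` column) and
#'   `report`.
#' @export
apply_censoring <- function(ledger, nmp) {
  report <- empty_report()
  monitored <- rep(TRUE, nrow(ledger))
  if (nrow(nmp) > 0) {
    for (i in seq_len(nrow(nmp))) {
      sel <- ledger$patient_code == nmp$patient_code[i] &
        ledger$monitor == nmp$monitor[i] &
        ledger$date >= nmp$start_date[i] & ledger$date <= nmp$end_date[i]
      n_hit <- sum(sel)
      n_days <- as.integer(nmp$end_date[i] - nmp$start_date[i]) + 1L
      if (n_hit == 0) {
        report <- bind_reports(report, report_entry(
          "warning", "NMP_OUT_OF_WINDOW", "NonMonitoredPeriods",
          nmp$row[i] %||% NA_integer_,
          paste0("nonmonitored period ", format(nmp$start_date[i]), " .. ",
                 format(nmp$end_date[i]), " for ", nmp$patient_code[i], "/",
                 nmp$monitor[i], " lies outside the monitoring window; no effect")))
      } else if (n_hit < n_days) {
        report <- bind_reports(report, report_entry(
          "warning", "NMP_CLIPPED", "NonMonitoredPeriods",
          nmp$row[i] %||% NA_integer_,
          paste0("nonmonitored period ", format(nmp$start_date[i]), " .. ",
                 format(nmp$end_date[i]), " for ", nmp$patient_code[i], "/",
                 nmp$monitor[i], " extends beyond the monitoring window; clipped")))
      }
      monitored[sel] <- FALSE
    }
  }
  ledger$monitored <- monitored
  list(ledger = ledger, report = report)
}
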