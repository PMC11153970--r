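#' Expand one regimen period to per-day expected openings
#'
#' A regimen period prescribes `expected_openings` EM openings per day over
#' `[start_date, end_date]` (both ends inclusive). When `on_days`/`off_days`
#' are set the regimen is cyclic: the cycle starts on the period's
#' `start_date` with `on_days` consecutive days at `expected_openings`,
#' followed by `off_days` days at 0, and repeats. The palbociclib scheme
#' "21 days of treatment, 7 days of interruption" is `on_days = 21`,
#' `off_days = 7`; an alternate-day scheme is `on_days = 1`, `off_days = 1`.
#' The cycle phase is anchored at the period's own `start_date`, so a new
#' regimen row restarts the cycle.
#'
#' @param period One-row tibble (or list) with `start_date`, `end_date`,
#'   `expected_openings`, and optional `on_days`, `off_days`.
#' @return Tibble with columns `date`, `expected` covering every day of the
#'   period.
#' @examples
#' expand_regimen(list(start_date = as.Date("2021-01-01"),
#'                     end_date = as.Date("2021-01-08"),
#'                     expected_openings = 1L, on_days = 1L, off_days = 1L))
#' @export
expand_regimen <- function(period) {
  period <- as.list(period)
  on <- period$on_days %||% NA_integer_
  off <- period$off_days %||% NA_integer_
  if (xor(is.na(on), is.na(off))) {
    stop("regimen period has exactly one of On/Off filled (should have been ",
         "caught by workbook validation)", call. = FALSE)
  }
  dates <- seq(period$start_date, period$end_date, by = "day")
  if (is.na(on)) {
    expected <- rep(as.integer(period$expected_openings), length(dates))
  } else {
    k <- as.integer(dates - period$start_date) %% (on + off)
    expected <- ifelse(k < on, as.integer(period$expected_openings), 0L)
  }
  tibble::tibble(date = dates, expected = as.integer(expected))
}

#' Build the expected-openings schedule for one monitoring window
#'
#' Concatenates the covering regimen periods into a per-day expected count
#' and truncates the result to the monitoring window (`[start_date,
#' end_date]` of the `EMInfo` row): dates outside the window are dropped
#' even when a regimen period extends beyond it, and the cycle phase of a
#' cyclic period that starts before the window is preserved (anchored at
#' the period's `StartDate`, not the window's).
#'
#' @param window One-row tibble (or list) with `patient_code`, `monitor`,
#'   `start_date`, `end_date`.
#' @param periods Tibble of regimen periods for this (patient, monitor),
#'   validated non-overlapping and gap-free over the window.
#' @return Tibble `patient_code`, `monitor`, `date`, `expected` with exactly
#'   one row per window day.
#' @export
build_schedule <- function(window, periods) {
  window <- as.list(window)
  win_dates <- seq(window$start_date, window$end_date, by = "day")
  expected <- rep(NA_integer_, length(win_dates))
  for (j in seq_len(nrow(periods))) {
    ex <- expand_regimen(periods[j, ])
    ex <- ex[ex$date >= window$start_date & ex$date <= window$end_date, ]
    idx <- match(as.integer(ex$date), as.integer(win_dates))
    if (any(!is.na(expected[idx]))) {
      stop("REGIMEN_OVERLAP: regimen periods overlap inside the window for ",
           window$patient_code, "/", window$monitor, call. = FALSE)
    }
    expected[idx] <- ex$expected
  }
  if (anyNA(expected)) {
    stop("REGIMEN_GAP: window days without regimen coverage for ",
         window$patient_code, "/", window$monitor, call. = FALSE)
  }
  tibble::tibble(patient_code = window$patient_code, monitor = window$monitor,
                 date = win_dates, expected = expected)
}

#' Build schedules for every declared monitor
#'
#' @param em_info `EMInfo` tibble (`patient_code`, `monitor`, `start_date`,
#'   `end_date`).
#' @param regimen Regimen periods tibble.
#' @return Tibble `patient_code`, `monitor`, `date`, `expected`, one row per
#'   monitor-day.
#' @export
build_schedules <- function(em_info, regimen) {
  purrr::map_dfr(seq_len(nrow(em_info)), function(i) {
    w <- em_info[i, ]
    per <- regimen[regimen$patient_code == w$patient_code &
                     regimen$monitor == w$monitor, , drop = FALSE]
    build_schedule(w, per)
  })
}
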