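# Fixture builders: minimal valid auxiliary sheet sets and raw event tables,
# built in code so every test constructs exactly the situation it checks.

aux_sheets_minimal <- function(patient = "A", monitor = "EM01",
                               start = as.Date("2021-05-01"),
                               end = as.Date("2021-05-30"),
                               expected = 1L, on = NA_integer_,
                               off = NA_integer_) {
  list(
    EMInfo = data.frame(PatientCode = patient, Monitor = monitor,
                        StartDate = start, EndDate = end,
                        stringsAsFactors = FALSE),
    Regimen = data.frame(PatientCode = patient, Monitor = monitor,
                         ExpectedOpenings = expected,
                         StartDate = start, EndDate = end,
                         On = on, Off = off, stringsAsFactors = FALSE)
  )
}

write_temp_aux <- function(sheets, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "auxiliary_data.xlsx")
  write_xlsx_sheets(sheets, path)
  path
}

write_events_csv <- function(df, dir, name = "p_eventslist.csv") {
  path <- file.path(dir, name)
  readr::write_csv(df, path)
  path
}

events_table <- function(patient, monitor, timestamps) {
  data.frame(PatientCode = patient, Monitor = monitor, Date = timestamps,
             stringsAsFactors = FALSE)
}

daily_table <- function(patient, monitor, dates, recorded) {
  tibble::tibble(patient_code = patient, monitor = monitor,
                 date = as.Date(dates), recorded = as.integer(recorded))
}

# Random small but always-valid fixture: ≤ n_patients patients, ≤ 3 monitors
# overall per patient, ≤ max_days day windows, mixed continuous/cyclic
# regimens with a possible mid-window change, random recorded counts,
# random in-window adjustments and nonmonitored intervals.
random_fixture <- function(n_patients = NULL, max_days = 60) {
  if (is.null(n_patients)) n_patients <- sample(1:5, 1)
  origin <- as.Date("2021-01-01")
  em_info <- NULL; regimen <- NULL; added <- NULL; nmp <- NULL; daily <- NULL
  em_id <- 0L
  for (i in seq_len(n_patients)) {
    pc <- LETTERS[i]
    for (m in seq_len(sample(1:3, 1))) {
      em_id <- em_id + 1L
      mon <- sprintf("EM%02d", em_id)
      len <- sample(5:max_days, 1)
      s <- origin + sample(0:60, 1)
      e <- s + len - 1L
      em_info <- rbind(em_info, data.frame(
        PatientCode = pc, Monitor = mon, StartDate = s, EndDate = e,
        stringsAsFactors = FALSE))
      # split the window into 1 or 2 regimen periods
      cuts <- if (len >= 10 && stats::runif(1) < 0.5) {
        mid <- s + sample(2:(len - 3), 1)
        list(c(s, mid), c(mid + 1L, e))
      } else list(c(s, e))
      for (cut in cuts) {
        cyclic <- stats::runif(1) < 0.4
        regimen <- rbind(regimen, data.frame(
          PatientCode = pc, Monitor = mon,
          ExpectedOpenings = sample(0:2, 1),
          StartDate = cut[1], EndDate = cut[2],
          On = if (cyclic) sample(1:21, 1) else NA_integer_,
          Off = if (cyclic) sample(1:7, 1) else NA_integer_,
          stringsAsFactors = FALSE))
      }
      dates <- seq(s, e, by = "day")
      rec_days <- dates[stats::runif(len) < 0.8]
      if (length(rec_days) > 0) {
        daily <- rbind(daily, data.frame(
          patient_code = pc, monitor = mon, date = rec_days,
          recorded = sample(0:3, length(rec_days), replace = TRUE),
          stringsAsFactors = FALSE))
      }
      n_adj <- stats::rpois(1, 1.5)
      if (n_adj > 0) {
        added <- rbind(added, data.frame(
          PatientCode = pc, Monitor = mon,
          Date = sample(dates, n_adj, replace = TRUE),
          Openings = sample(c(-2L, -1L, 1L, 1L, 2L), n_adj, replace = TRUE),
          stringsAsFactors = FALSE))
      }
      if (stats::runif(1) < 0.5 && len >= 6) {
        a <- sample(seq_len(len - 2), 1)
        b <- min(len, a + sample(1:6, 1))
        nmp <- rbind(nmp, data.frame(
          PatientCode = pc, Monitor = mon,
          StartDate = dates[a], EndDate = dates[b], stringsAsFactors = FALSE))
      }
    }
  }
  sheets <- list(EMInfo = em_info, Regimen = regimen)
  if (!is.null(added)) sheets$AddedOpenings <- added
  if (!is.null(nmp)) sheets$NonMonitoredPeriods <- nmp
  daily <- if (is.null(daily)) {
    daily_table(character(), character(), as.Date(character()), integer())
  } else {
    tibble::as_tibble(daily)
  }
  list(sheets = sheets, daily = daily)
}
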