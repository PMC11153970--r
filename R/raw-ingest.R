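#' Discover EM raw data files in a folder
#'
#' Raw EM exports are dropped together in one folder; the pipeline picks up
#' every file whose name contains the `"eventslist"` substring (the export
#' convention of the monitoring software) and ignores the rest with a
#' warning. One file may contain the events of several patients.
#'
#' @param folder Directory containing the exports.
#' @param pattern Substring a usable filename must contain. Default
#'   `"eventslist"`.
#' @param ignore_case Match the substring case-insensitively? Default
#'   `FALSE`.
#' @return A list with `files` (matched paths) and `report` (warning
#'   `IGNORED_FILE` per skipped file; critical error `NO_RAW_FILES` when
#'   nothing matches).
#' @export
discover_raw_files <- function(folder, pattern = "eventslist", ignore_case = FALSE) {
  if (!dir.exists(folder)) {
    stop("raw data folder not found: ", folder, call. = FALSE)
  }
  all_files <- list.files(folder, full.names = TRUE)
  all_files <- all_files[!dir.exists(all_files) | !file.info(all_files)$isdir]
  all_files <- all_files[!file.info(all_files)$isdir]
  hit <- stringr::str_detect(
    basename(all_files),
    stringr::fixed(pattern, ignore_case = ignore_case))
  report <- empty_report()
  for (f in all_files[!hit]) {
    report <- bind_reports(report, report_entry(
      "warning", "IGNORED_FILE", basename(f), NA,
      paste0("filename does not contain '", pattern, "'; file ignored")))
  }
  if (!any(hit)) {
    report <- bind_reports(report, report_entry(
      "error", "NO_RAW_FILES", folder, NA,
      paste0("no raw EM data file matching '", pattern, "' found")))
  }
  list(files = all_files[hit], report = report)
}

#' Read one EM raw data file
#'
#' Accepts the two export formats:
#'
#' * **events list** — one row per EM opening, columns `PatientCode`,
#'   `Monitor`, `Date` (a date-time or a well-formatted date string);
#' * **daily adherence** — one row per day, with an additional
#'   `RecordedOpenings` count column.
#'
#' The format is auto-detected from the presence of `RecordedOpenings`.
#' Delimited text is sniffed for comma, semicolon or tab; `.xlsx` is read
#' natively. Duplicate identical event rows are kept as distinct openings
#' (rapid successive openings are legitimate) but flagged with warning
#' `DUPLICATE_EVENT`.
#'
#' @param path File path (`.csv`, `.txt`, `.tsv` or `.xlsx`).
#' @return A list with `events` (tibble `patient_code`, `monitor`, `date`
#'   for the events format; `NULL` otherwise), `daily` (tibble
#'   `patient_code`, `monitor`, `date`, `recorded` for the daily format),
#'   `format` (`"events"` or `"daily"`), and `report`.
#' @export
read_em_events <- function(path) {
  fname <- basename(path)
  report <- empty_report()
  df <- read_raw_table(path)
  if (is.null(df)) {
    return(list(events = NULL, daily = NULL, format = NA_character_,
                report = report_entry("error", "BAD_FORMAT", fname, NA,
                                      "cannot detect delimiter or read file")))
  }
  required <- c("PatientCode", "Monitor", "Date")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    for (mc in missing) {
      report <- bind_reports(report, report_entry(
        "error", "MISSING_COLUMN", fname, 1,
        paste0("mandatory column '", mc, "' is missing (column names are case-sensitive)")))
    }
    return(list(events = NULL, daily = NULL, format = NA_character_, report = report))
  }
  daily_format <- "RecordedOpenings" %in% names(df)

  n <- nrow(df)
  patient <- character(n); monitor <- character(n)
  date <- as.Date(rep(NA, n)); ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    p1 <- parse_cell_chr(cell_at(df$PatientCode, i))
    p2 <- parse_cell_chr(cell_at(df$Monitor, i))
    p3 <- parse_cell_timestamp(cell_at(df$Date, i))
    if (p1$status != "ok" || p2$status != "ok") {
      ok[i] <- FALSE
      report <- bind_reports(report, report_entry(
        "error", "MISSING_VALUE", fname, i + 1L,
        "missing PatientCode or Monitor"))
      next
    }
    if (p3$status != "ok") {
      ok[i] <- FALSE
      report <- bind_reports(report, report_entry(
        "error", "BAD_DATE", fname, i + 1L,
        "cannot interpret Date as a date or date-time"))
      next
    }
    patient[i] <- p1$value; monitor[i] <- p2$value; date[i] <- p3$value
  }

  if (daily_format) {
    rec <- integer(n)
    for (i in seq_len(n)) {
      if (!ok[i]) next
      p <- parse_cell_int(cell_at(df$RecordedOpenings, i))
      if (p$status != "ok" || p$value < 0) {
        ok[i] <- FALSE
        report <- bind_reports(report, report_entry(
          "error", "BAD_VALUE", fname, i + 1L,
          "RecordedOpenings must be a nonnegative integer"))
        next
      }
      rec[i] <- p$value
    }
    daily <- tibble::tibble(patient_code = patient, monitor = monitor,
                            date = date, recorded = rec)[ok, ]
    return(list(events = NULL, daily = daily, format = "daily", report = report))
  }

  events <- tibble::tibble(patient_code = patient, monitor = monitor,
                           date = date)[ok, ]
  # flag exact duplicates (same patient, monitor, raw Date cell)
  raw_date_chr <- vapply(seq_len(n), function(i) {
    v <- cell_at(df$Date, i)
    if (is_blank_cell(v)) NA_character_ else paste(format(v), collapse = " ")
  }, character(1))
  key <- paste(patient, monitor, raw_date_chr, sep = "\r")[ok]
  for (i in which(duplicated(key))) {
    report <- bind_reports(report, report_entry(
      "warning", "DUPLICATE_EVENT", fname, which(ok)[i] + 1L,
      "identical event row seen before in this file; both kept as openings"))
  }
  list(events = events, daily = NULL, format = "events", report = report)
}

# Timestamps: native date/datetime cells, Excel serials, ISO dates, or ISO
# date-times ("YYYY-MM-DD HH:MM[:SS]"); reduced to the calendar date of the
# EM clock (no timezone arithmetic).
parse_cell_timestamp <- function(v) {
  if (is_blank_cell(v)) return(list(value = as.Date(NA), status = "missing"))
  if (is.character(v)) {
    s <- trimws(v)
    if (grepl("^\\d{4}-\\d{2}-\\d{2}[ T]\\d{2}:\\d{2}(:\\d{2})?$", s)) {
      d <- suppressWarnings(as.Date(substr(s, 1, 10), format = "%Y-%m-%d"))
      if (!is.na(d)) return(list(value = d, status = "ok"))
      return(list(value = as.Date(NA), status = "bad"))
    }
  }
  if (is.numeric(v)) {
    # Excel serial date-times carry a fractional day
    if (v > 0) {
      return(list(value = as.Date(floor(v), origin = "1899-12-30"), status = "ok"))
    }
    return(list(value = as.Date(NA), status = "bad"))
  }
  parse_cell_date(v)
}

read_raw_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    return(suppressMessages(readxl::read_excel(path, col_types = "list")))
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) return(NULL)
  delim <- NULL
  for (d in c(",", ";", "\t")) {
    fields <- strsplit(header, d, fixed = TRUE)[[1]]
    if ("PatientCode" %in% trimws(fields)) { delim <- d; break }
  }
  if (is.null(delim)) {
    # single-column header (no delimiter found); fall back to comma so the
    # missing-column check can report precisely
    delim <- ","
  }
  suppressWarnings(suppressMessages(
    readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                      trim_ws = TRUE, progress = FALSE)
  ))
}

#' Aggregate opening events to daily counts
#'
#' Reduces one-row-per-opening events to one row per (patient, monitor,
#' calendar day) with the number of recorded openings. Days with no events
#' yield no row (they are treated as zero openings downstream). The total
#' number of events is conserved.
#'
#' @param events Tibble with columns `patient_code`, `monitor`, `date`.
#' @return Tibble `patient_code`, `monitor`, `date`, `recorded`.
#' @export
aggregate_daily <- function(events) {
  if (is.null(events) || nrow(events) == 0) {
    return(tibble::tibble(patient_code = character(), monitor = character(),
                          date = as.Date(character()), recorded = integer()))
  }
  events |>
    dplyr::count(.data$patient_code, .data$monitor, .data$date,
                 name = "recorded") |>
    dplyr::mutate(recorded = as.integer(.data$recorded)) |>
    dplyr::arrange(.data$patient_code, .data$monitor, .data$date)
}

#' Read a whole raw data folder into daily opening counts
#'
#' Discovers the `"eventslist"` files, reads each (events or daily format),
#' aggregates events to days, and merges everything into one daily ledger.
#' Counts for the same (patient, monitor, day) arriving from several files
#' are summed.
#'
#' @inheritParams discover_raw_files
#' @return A list with `daily` (tibble `patient_code`, `monitor`, `date`,
#'   `recorded`) and `report`.
#' @export
read_raw_folder <- function(folder, pattern = "eventslist", ignore_case = FALSE) {
  disc <- discover_raw_files(folder, pattern = pattern, ignore_case = ignore_case)
  report <- disc$report
  if (has_errors(report)) {
    return(list(daily = aggregate_daily(NULL), report = report))
  }
  parts <- list()
  for (f in disc$files) {
    res <- read_em_events(f)
    report <- bind_reports(report, res$report)
    if (!is.null(res$events)) parts[[length(parts) + 1L]] <- aggregate_daily(res$events)
    if (!is.null(res$daily)) parts[[length(parts) + 1L]] <- res$daily
  }
  daily <- dplyr::bind_rows(parts)
  if (nrow(daily) > 0) {
    daily <- daily |>
      dplyr::group_by(.data$patient_code, .data$monitor, .data$date) |>
      dplyr::summarise(recorded = as.integer(sum(.data$recorded)), .groups = "drop") |>
      dplyr::arrange(.data$patient_code, .data$monitor, .data$date)
  } else {
    daily <- aggregate_daily(NULL)
  }
  list(daily = daily, report = report)
}
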