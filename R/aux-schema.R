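#' Load and validate an Auxiliary Data workbook
#'
#' The Auxiliary Data workbook is the investigator-curated companion to the
#' raw EM event files. Two sheets are mandatory and drive the whole
#' calculation:
#'
#' * `EMInfo` — one row per electronic monitor with `PatientCode`,
#'   `Monitor`, `StartDate`, `EndDate`: the monitoring window. The cleaned
#'   data set is truncated to this window.
#' * `Regimen` — one row per (monitor, regimen period) with
#'   `ExpectedOpenings` per day over `StartDate`..`EndDate`, plus optional
#'   `On`/`Off` day counts describing a cyclic regimen (e.g. 21 days on, 7
#'   days off). A regimen change is a new row. Exactly one of `On`/`Off`
#'   filled is a critical error.
#'
#' Five sheets are optional: `PatientCovariables` and `EMCovariables`
#' (arbitrary columns carried verbatim into the summaries), `AddedOpenings`
#' (signed per-day corrections: positive deltas insert documented pocket
#' doses, negative deltas remove documented extra openings such as pharmacist
#' pill-count checks), `NonMonitoredPeriods` (intervals to censor), and
#' `AdverseEvents` (descriptive enrichment only).
#'
#' Sheet and column names are matched case-sensitively. Unknown columns are
#' ignored except in the two covariable sheets, where they are the payload.
#' Dates may be workbook-native date cells, Excel serial numbers, or ISO
#' 8601 text; ambiguous text dates (e.g. `03/04/2021`) are a critical error
#' rather than a guess. All findings land in the attached validation report
#' (see [report_entry()]); any `"error"` finding blocks implementation
#' output downstream.
#'
#' @param path Path to the workbook (`.xlsx`).
#' @return An object of class `adh_aux`: a list with typed tibbles
#'   `em_info`, `regimen`, `added_openings`, `nonmonitored_periods`,
#'   `patient_covariables`, `em_covariables`, `adverse_events`, and the
#'   validation `report`. Each typed tibble carries the originating workbook
#'   `row` (header = row 1).
#' @seealso [as_auxiliary()] for in-memory input, [write_auxiliary()] for
#'   the reverse direction, [validate_cross_references()] for checks against
#'   the raw data.
#' @export
read_auxiliary <- function(path) {
  if (!file.exists(path)) {
    stop("auxiliary workbook not found: ", path, call. = FALSE)
  }
  sheets <- read_xlsx_cells(path)
  parse_auxiliary(sheets)
}

#' Build an auxiliary object from in-memory sheets
#'
#' Applies the same schema validation as [read_auxiliary()] to a named list
#' of data frames (names are the sheet names, e.g. `EMInfo`). Used by the
#' synthetic generator and in tests.
#'
#' @param sheets Named list of data frames.
#' @return An `adh_aux` object.
#' @export
as_auxiliary <- function(sheets) {
  stopifnot(is.list(sheets))
  parse_auxiliary(sheets)
}

AUX_OPTIONAL_SHEETS <- c("PatientCovariables", "EMCovariables", "AddedOpenings",
                         "NonMonitoredPeriods", "AdverseEvents")

parse_auxiliary <- function(sheets) {
  report <- empty_report()
  for (s in c("EMInfo", "Regimen")) {
    if (!s %in% names(sheets)) {
      report <- bind_reports(report, report_entry(
        "error", "MISSING_SHEET", s, NA,
        paste0("mandatory sheet '", s, "' is missing")))
    }
  }

  em <- parse_em_info(sheets[["EMInfo"]])
  rg <- parse_regimen(sheets[["Regimen"]])
  ao <- parse_added_openings(sheets[["AddedOpenings"]])
  np <- parse_nonmonitored(sheets[["NonMonitoredPeriods"]])
  ae <- parse_adverse_events(sheets[["AdverseEvents"]])
  pc <- parse_covariables(sheets[["PatientCovariables"]], "PatientCovariables",
                          keys = c(PatientCode = "patient_code"))
  ec <- parse_covariables(sheets[["EMCovariables"]], "EMCovariables",
                          keys = c(PatientCode = "patient_code", Monitor = "monitor"))

  report <- bind_reports(report, em$report, rg$report, ao$report, np$report,
                         ae$report, pc$report, ec$report)

  structure(list(
    em_info = em$data,
    regimen = rg$data,
    added_openings = ao$data,
    nonmonitored_periods = np$data,
    patient_covariables = pc$data,
    em_covariables = ec$data,
    adverse_events = ae$data,
    report = report
  ), class = "adh_aux")
}

#' @export
print.adh_aux <- function(x, ...) {
  cat("<Auxiliary Data>\n")
  cat("  EMInfo:              ", nrow(x$em_info), " monitor window(s)\n", sep = "")
  cat("  Regimen:             ", nrow(x$regimen), " period(s)\n", sep = "")
  cat("  AddedOpenings:       ", nrow(x$added_openings), " adjustment(s)\n", sep = "")
  cat("  NonMonitoredPeriods: ", nrow(x$nonmonitored_periods), " interval(s)\n", sep = "")
  cat("  covariables:         ", nrow(x$patient_covariables), " patient row(s), ",
      nrow(x$em_covariables), " monitor row(s)\n", sep = "")
  cat("  AdverseEvents:       ", nrow(x$adverse_events), " record(s)\n", sep = "")
  cat("  findings:            ", nrow(report_errors(x$report)), " error(s), ",
      nrow(report_warnings(x$report)), " warning(s)\n", sep = "")
  invisible(x)
}

# -- per-sheet parsers --------------------------------------------------------

# Generic row scanner: `cols` is a named list col_name -> list(parse, required).
# Returns typed tibble (only fully parseable rows) + findings.
scan_sheet <- function(df, sheet, cols) {
  report <- empty_report()
  missing_cols <- setdiff(names(cols)[vapply(cols, `[[`, logical(1), "required")],
                          names(df))
  if (length(missing_cols) > 0) {
    for (mc in missing_cols) {
      report <- bind_reports(report, report_entry(
        "error", "MISSING_COLUMN", sheet, 1,
        paste0("mandatory column '", mc, "' is missing (column names are case-sensitive)")))
    }
    return(list(data = NULL, report = report, ok_rows = integer(0)))
  }
  n <- nrow(df)
  out <- vector("list", length(cols))
  names(out) <- names(cols)
  ok <- rep(TRUE, n)
  for (cn in names(cols)) {
    spec <- cols[[cn]]
    col <- if (cn %in% names(df)) df[[cn]] else NULL
    vals <- vector("list", n)
    for (i in seq_len(n)) {
      v <- if (is.null(col)) NULL else cell_at(col, i)
      p <- spec$parse(v)
      if (p$status == "missing" && isTRUE(spec$required)) {
        ok[i] <- FALSE
        report <- bind_reports(report, report_entry(
          "error", "MISSING_VALUE", sheet, i + 1L,
          paste0("missing value in mandatory column '", cn, "'")))
      } else if (p$status == "bad") {
        ok[i] <- FALSE
        code <- if (identical(spec$kind, "date")) "BAD_DATE" else "BAD_VALUE"
        report <- bind_reports(report, report_entry(
          "error", code, sheet, i + 1L,
          paste0("cannot interpret value in column '", cn, "'",
                 if (identical(spec$kind, "date")) " as a date (expected ISO 8601 or a native date cell)" else "")))
      }
      vals[[i]] <- p$value
    }
    out[[cn]] <- vals
  }
  simplify <- function(vals, proto) {
    if (n == 0) return(proto)
    do.call(c, vals)
  }
  typed <- tibble::tibble(.rows = n)
  for (cn in names(cols)) {
    proto <- cols[[cn]]$proto
    typed[[cols[[cn]]$as %||% cn]] <- simplify(out[[cn]], proto)
  }
  typed$row <- seq_len(n) + 1L
  list(data = typed[ok, , drop = FALSE], report = report, ok_rows = which(ok))
}

col_chr <- function(as, required = TRUE) {
  list(parse = parse_cell_chr, required = required, kind = "chr",
       proto = character(), as = as)
}
col_date <- function(as, required = TRUE) {
  list(parse = parse_cell_date, required = required, kind = "date",
       proto = as.Date(character()), as = as)
}
col_int <- function(as, required = TRUE) {
  list(parse = parse_cell_int, required = required, kind = "int",
       proto = integer(), as = as)
}

check_interval <- function(data, sheet, start = "start_date", end = "end_date") {
  report <- empty_report()
  if (is.null(data) || nrow(data) == 0) return(list(data = data, report = report))
  bad <- which(data[[start]] > data[[end]])
  for (i in bad) {
    report <- bind_reports(report, report_entry(
      "error", "BAD_INTERVAL", sheet, data$row[i],
      "StartDate is after EndDate"))
  }
  if (length(bad) > 0) data <- data[-bad, , drop = FALSE]
  list(data = data, report = report)
}

parse_em_info <- function(df) {
  empty <- tibble::tibble(patient_code = character(), monitor = character(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character()), row = integer())
  if (is.null(df)) return(list(data = empty, report = empty_report()))
  sc <- scan_sheet(df, "EMInfo", list(
    PatientCode = col_chr("patient_code"),
    Monitor = col_chr("monitor"),
    StartDate = col_date("start_date"),
    EndDate = col_date("end_date")
  ))
  if (is.null(sc$data)) return(list(data = empty, report = sc$report))
  iv <- check_interval(sc$data, "EMInfo")
  data <- iv$data
  report <- bind_reports(sc$report, iv$report)
  dup <- duplicated(data[c("patient_code", "monitor")])
  for (i in which(dup)) {
    report <- bind_reports(report, report_entry(
      "error", "DUP_WINDOW", "EMInfo", data$row[i],
      paste0("duplicate (PatientCode, Monitor) pair: ", data$patient_code[i],
             "/", data$monitor[i])))
  }
  list(data = data[!dup, , drop = FALSE], report = report)
}

parse_regimen <- function(df) {
  empty <- tibble::tibble(patient_code = character(), monitor = character(),
                          expected_openings = integer(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character()),
                          on_days = integer(), off_days = integer(),
                          row = integer())
  if (is.null(df)) return(list(data = empty, report = empty_report()))
  sc <- scan_sheet(df, "Regimen", list(
    PatientCode = col_chr("patient_code"),
    Monitor = col_chr("monitor"),
    ExpectedOpenings = col_int("expected_openings"),
    StartDate = col_date("start_date"),
    EndDate = col_date("end_date"),
    On = col_int("on_days", required = FALSE),
    Off = col_int("off_days", required = FALSE)
  ))
  if (is.null(sc$data)) return(list(data = empty, report = sc$report))
  iv <- check_interval(sc$data, "Regimen")
  data <- iv$data
  report <- bind_reports(sc$report, iv$report)
  drop <- logical(nrow(data))
  for (i in seq_len(nrow(data))) {
    on_na <- is.na(data$on_days[i]); off_na <- is.na(data$off_days[i])
    if (xor(on_na, off_na)) {
      drop[i] <- TRUE
      report <- bind_reports(report, report_entry(
        "error", "ON_OFF_PAIR", "Regimen", data$row[i],
        "cyclic regimen requires both On and Off (or neither for a continuous regimen)"))
    } else if (!on_na && (data$on_days[i] < 1 || data$off_days[i] < 1)) {
      drop[i] <- TRUE
      report <- bind_reports(report, report_entry(
        "error", "BAD_VALUE", "Regimen", data$row[i],
        "On and Off must be positive day counts"))
    }
    if (!is.na(data$expected_openings[i]) && data$expected_openings[i] < 0) {
      drop[i] <- TRUE
      report <- bind_reports(report, report_entry(
        "error", "BAD_VALUE", "Regimen", data$row[i],
        "ExpectedOpenings must be a nonnegative integer"))
    }
  }
  list(data = data[!drop, , drop = FALSE], report = report)
}

parse_added_openings <- function(df) {
  empty <- tibble::tibble(patient_code = character(), monitor = character(),
                          date = as.Date(character()),
                          openings_delta = integer(), row = integer())
  if (is.null(df)) return(list(data = empty, report = empty_report()))
  sc <- scan_sheet(df, "AddedOpenings", list(
    PatientCode = col_chr("patient_code"),
    Monitor = col_chr("monitor"),
    Date = col_date("date"),
    Openings = col_int("openings_delta")
  ))
  if (is.null(sc$data)) return(list(data = empty, report = sc$report))
  data <- sc$data
  report <- sc$report
  zero <- which(data$openings_delta == 0L)
  for (i in zero) {
    report <- bind_reports(report, report_entry(
      "warning", "ZERO_DELTA", "AddedOpenings", data$row[i],
      "adjustment of 0 openings has no effect and is ignored"))
  }
  if (length(zero) > 0) data <- data[-zero, , drop = FALSE]
  list(data = data, report = report)
}

parse_nonmonitored <- function(df) {
  empty <- tibble::tibble(patient_code = character(), monitor = character(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character()), row = integer())
  if (is.null(df)) return(list(data = empty, report = empty_report()))
  sc <- scan_sheet(df, "NonMonitoredPeriods", list(
    PatientCode = col_chr("patient_code"),
    Monitor = col_chr("monitor"),
    StartDate = col_date("start_date"),
    EndDate = col_date("end_date")
  ))
  if (is.null(sc$data)) return(list(data = empty, report = sc$report))
  iv <- check_interval(sc$data, "NonMonitoredPeriods")
  list(data = iv$data, report = bind_reports(sc$report, iv$report))
}

parse_adverse_events <- function(df) {
  empty <- tibble::tibble(patient_code = character(), date = as.Date(character()),
                          event = character(), grade = character(), row = integer())
  if (is.null(df)) return(list(data = empty, report = empty_report()))
  sc <- scan_sheet(df, "AdverseEvents", list(
    PatientCode = col_chr("patient_code"),
    Date = col_date("date"),
    Event = col_chr("event", required = FALSE),
    Grade = col_chr("grade", required = FALSE)
  ))
  if (is.null(sc$data)) return(list(data = empty, report = sc$report))
  list(data = sc$data, report = sc$report)
}

parse_covariables <- function(df, sheet, keys) {
  key_out <- unname(keys)
  empty <- tibble::tibble(!!!stats::setNames(
    rep(list(character()), length(key_out)), key_out), row = integer())
  if (is.null(df)) return(list(data = empty, report = empty_report()))
  report <- empty_report()
  missing_keys <- setdiff(names(keys), names(df))
  if (length(missing_keys) > 0) {
    for (mc in missing_keys) {
      report <- bind_reports(report, report_entry(
        "error", "MISSING_COLUMN", sheet, 1,
        paste0("mandatory column '", mc, "' is missing (column names are case-sensitive)")))
    }
    return(list(data = empty, report = report))
  }
  n <- nrow(df)
  out <- tibble::tibble(.rows = n)
  ok <- rep(TRUE, n)
  for (kc in names(keys)) {
    vals <- character(n)
    for (i in seq_len(n)) {
      p <- parse_cell_chr(cell_at(df[[kc]], i))
      if (p$status == "missing") {
        ok[i] <- FALSE
        report <- bind_reports(report, report_entry(
          "error", "MISSING_VALUE", sheet, i + 1L,
          paste0("missing value in mandatory column '", kc, "'")))
      }
      vals[i] <- p$value
    }
    out[[keys[[kc]]]] <- vals
  }
  for (cn in setdiff(names(df), names(keys))) {
    out[[cn]] <- simplify_cell_col(df[[cn]])
  }
  out$row <- seq_len(n) + 1L
  list(data = out[ok, , drop = FALSE], report = report)
}

# -- cross-reference validation ----------------------------------------------

#' Validate auxiliary collections against the monitors seen in the raw data
#'
#' Cross-checks that the loaded auxiliary workbook and the raw EM files tell
#' the same story:
#'
#' * a declared monitor (`EMInfo` row) with no raw events yields warning
#'   `NO_RAW_DATA`;
#' * raw events for a (patient, monitor) absent from `EMInfo` yield warning
#'   `UNDECLARED_MONITOR` (the pipeline excludes those events);
#' * `Regimen`, `AddedOpenings` or `NonMonitoredPeriods` rows referencing a
#'   monitor absent from `EMInfo` are critical `ORPHAN_ROW` errors;
#' * covariable or adverse-event rows with unresolvable keys yield warning
#'   `UNKNOWN_KEY`;
#' * every date of every monitoring window must be covered by exactly one
#'   regimen period, otherwise critical `REGIMEN_GAP` / `REGIMEN_OVERLAP`.
#'
#' @param aux An `adh_aux` object.
#' @param monitors_seen Tibble with columns `patient_code`, `monitor`: the
#'   distinct monitors present in the raw data. `NULL` skips the raw/aux
#'   presence checks (pure workbook validation).
#' @return A validation report tibble (new findings only).
#' @export
validate_cross_references <- function(aux, monitors_seen = NULL) {
  stopifnot(inherits(aux, "adh_aux"))
  report <- empty_report()
  em <- aux$em_info
  em_key <- paste(em$patient_code, em$monitor, sep = "\r")

  if (!is.null(monitors_seen) && nrow(em) > 0) {
    seen_key <- paste(monitors_seen$patient_code, monitors_seen$monitor, sep = "\r")
    for (i in which(!(em_key %in% seen_key))) {
      report <- bind_reports(report, report_entry(
        "warning", "NO_RAW_DATA", "EMInfo", em$row[i],
        paste0("no raw EM data found for declared monitor ",
               em$patient_code[i], "/", em$monitor[i])))
    }
    undeclared <- monitors_seen[!(seen_key %in% em_key), , drop = FALSE]
    for (i in seq_len(nrow(undeclared))) {
      report <- bind_reports(report, report_entry(
        "warning", "UNDECLARED_MONITOR", "raw data", NA,
        paste0("raw events found for monitor ", undeclared$patient_code[i], "/",
               undeclared$monitor[i], " not declared in EMInfo; events excluded")))
    }
  }

  orphan_check <- function(tbl, sheet) {
    rep_ <- empty_report()
    if (nrow(tbl) == 0) return(rep_)
    key <- paste(tbl$patient_code, tbl$monitor, sep = "\r")
    for (i in which(!(key %in% em_key))) {
      rep_ <- bind_reports(rep_, report_entry(
        "error", "ORPHAN_ROW", sheet, tbl$row[i],
        paste0("references monitor ", tbl$patient_code[i], "/", tbl$monitor[i],
               " which has no EMInfo entry")))
    }
    rep_
  }
  report <- bind_reports(report,
    orphan_check(aux$regimen, "Regimen"),
    orphan_check(aux$added_openings, "AddedOpenings"),
    orphan_check(aux$nonmonitored_periods, "NonMonitoredPeriods"))

  if (nrow(aux$patient_covariables) > 0) {
    for (i in which(!(aux$patient_covariables$patient_code %in% em$patient_code))) {
      report <- bind_reports(report, report_entry(
        "warning", "UNKNOWN_KEY", "PatientCovariables",
        aux$patient_covariables$row[i],
        paste0("PatientCode ", aux$patient_covariables$patient_code[i],
               " has no EMInfo entry")))
    }
  }
  if (nrow(aux$em_covariables) > 0) {
    ec_key <- paste(aux$em_covariables$patient_code, aux$em_covariables$monitor,
                    sep = "\r")
    for (i in which(!(ec_key %in% em_key))) {
      report <- bind_reports(report, report_entry(
        "warning", "UNKNOWN_KEY", "EMCovariables", aux$em_covariables$row[i],
        paste0("monitor ", aux$em_covariables$patient_code[i], "/",
               aux$em_covariables$monitor[i], " has no EMInfo entry")))
    }
  }
  if (nrow(aux$adverse_events) > 0) {
    for (i in which(!(aux$adverse_events$patient_code %in% em$patient_code))) {
      report <- bind_reports(report, report_entry(
        "warning", "UNKNOWN_KEY", "AdverseEvents", aux$adverse_events$row[i],
        paste0("PatientCode ", aux$adverse_events$patient_code[i],
               " has no EMInfo entry")))
    }
  }

  # regimen coverage: every window date covered by exactly one period
  for (i in seq_len(nrow(em))) {
    win_dates <- seq(em$start_date[i], em$end_date[i], by = "day")
    cover <- rep(0L, length(win_dates))
    per <- aux$regimen[aux$regimen$patient_code == em$patient_code[i] &
                         aux$regimen$monitor == em$monitor[i], , drop = FALSE]
    for (j in seq_len(nrow(per))) {
      hit <- win_dates >= per$start_date[j] & win_dates <= per$end_date[j]
      cover[hit] <- cover[hit] + 1L
    }
    if (any(cover == 0L)) {
      gap <- win_dates[cover == 0L]
      report <- bind_reports(report, report_entry(
        "error", "REGIMEN_GAP", "Regimen", em$row[i],
        paste0("monitor ", em$patient_code[i], "/", em$monitor[i], ": ",
               length(gap), " window day(s) not covered by any regimen period (",
               format(min(gap)), " .. ", format(max(gap)), ")")))
    }
    if (any(cover > 1L)) {
      ov <- win_dates[cover > 1L]
      report <- bind_reports(report, report_entry(
        "error", "REGIMEN_OVERLAP", "Regimen", em$row[i],
        paste0("monitor ", em$patient_code[i], "/", em$monitor[i], ": ",
               length(ov), " window day(s) covered by more than one regimen period (",
               format(min(ov)), " .. ", format(max(ov)), ")")))
    }
  }

  report
}

# -- writing back -------------------------------------------------------------

#' Write an auxiliary object back to a workbook
#'
#' Serialises the typed collections to the sheet-native column layout, so
#' that `read_auxiliary(write_auxiliary(aux, path))` round-trips
#' field-by-field. All seven sheets are always written (empty sheets keep
#' their header row).
#'
#' @param aux An `adh_aux` object.
#' @param path Output path (`.xlsx`).
#' @return `path`, invisibly.
#' @export
write_auxiliary <- function(aux, path) {
  stopifnot(inherits(aux, "adh_aux"))
  strip <- function(df) df[setdiff(names(df), "row")]
  rename_back <- function(df, map) {
    df <- strip(df)
    names(df)[match(unname(map), names(df))] <- names(map)
    df
  }
  sheets <- list(
    EMInfo = rename_back(aux$em_info, c(PatientCode = "patient_code",
                                        Monitor = "monitor",
                                        StartDate = "start_date",
                                        EndDate = "end_date")),
    Regimen = rename_back(aux$regimen, c(PatientCode = "patient_code",
                                         Monitor = "monitor",
                                         ExpectedOpenings = "expected_openings",
                                         StartDate = "start_date",
                                         EndDate = "end_date",
                                         On = "on_days", Off = "off_days")),
    PatientCovariables = rename_back(aux$patient_covariables,
                                     c(PatientCode = "patient_code")),
    EMCovariables = rename_back(aux$em_covariables,
                                c(PatientCode = "patient_code", Monitor = "monitor")),
    AddedOpenings = rename_back(aux$added_openings,
                                c(PatientCode = "patient_code", Monitor = "monitor",
                                  Date = "date", Openings = "openings_delta")),
    NonMonitoredPeriods = rename_back(aux$nonmonitored_periods,
                                      c(PatientCode = "patient_code",
                                        Monitor = "monitor",
                                        StartDate = "start_date",
                                        EndDate = "end_date")),
    AdverseEvents = rename_back(aux$adverse_events,
                                c(PatientCode = "patient_code", Date = "date",
                                  Event = "event", Grade = "grade"))
  )
  write_xlsx_sheets(sheets, path)
}
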