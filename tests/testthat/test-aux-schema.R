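test_that("a minimal well-formed workbook loads with no findings", {
  path <- write_temp_aux(aux_sheets_minimal())
  aux <- read_auxiliary(path)
  expect_s3_class(aux, "adh_aux")
  expect_identical(nrow(aux$report), 0L)
  expect_identical(nrow(aux$em_info), 1L)
  expect_identical(nrow(aux$regimen), 1L)
  expect_identical(nrow(aux$added_openings), 0L)
  expect_identical(nrow(aux$nonmonitored_periods), 0L)
  expect_identical(aux$em_info$patient_code, "A")
  expect_identical(aux$em_info$start_date, as.Date("2021-05-01"))
})

test_that("structural defects are critical errors naming sheet and row", {
  # only one of On/Off filled
  sheets <- aux_sheets_minimal()
  sheets$Regimen$On <- 21L
  aux <- as_auxiliary(sheets)
  errs <- report_errors(aux$report)
  expect_true("ON_OFF_PAIR" %in% errs$code)
  expect_identical(errs$sheet[errs$code == "ON_OFF_PAIR"], "Regimen")
  expect_identical(errs$row[errs$code == "ON_OFF_PAIR"], 2L)

  # unparseable date cell, via a real workbook
  sheets <- aux_sheets_minimal()
  sheets$EMInfo$StartDate <- "notadate"
  aux <- read_auxiliary(write_temp_aux(sheets))
  errs <- report_errors(aux$report)
  expect_true("BAD_DATE" %in% errs$code)
  expect_identical(errs$sheet[errs$code == "BAD_DATE"], "EMInfo")
  expect_identical(errs$row[errs$code == "BAD_DATE"], 2L)

  # ambiguous day/month text dates are rejected, not guessed
  sheets <- aux_sheets_minimal()
  sheets$EMInfo$StartDate <- "03/04/2021"
  aux <- as_auxiliary(sheets)
  expect_true("BAD_DATE" %in% report_errors(aux$report)$code)

  # missing mandatory sheet and column
  aux <- as_auxiliary(list(EMInfo = aux_sheets_minimal()$EMInfo))
  expect_true("MISSING_SHEET" %in% report_errors(aux$report)$code)
  sheets <- aux_sheets_minimal()
  sheets$EMInfo$StartDate <- NULL
  aux <- as_auxiliary(sheets)
  errs <- report_errors(aux$report)
  expect_true("MISSING_COLUMN" %in% errs$code)

  # column names are case-sensitive
  sheets <- aux_sheets_minimal()
  names(sheets$EMInfo)[1] <- "patientcode"
  aux <- as_auxiliary(sheets)
  expect_true("MISSING_COLUMN" %in% report_errors(aux$report)$code)
})

test_that("interval and uniqueness invariants are enforced", {
  sheets <- aux_sheets_minimal()
  sheets$EMInfo <- rbind(sheets$EMInfo, sheets$EMInfo)
  aux <- as_auxiliary(sheets)
  expect_true("DUP_WINDOW" %in% report_errors(aux$report)$code)

  sheets <- aux_sheets_minimal(start = as.Date("2021-05-30"),
                               end = as.Date("2021-05-01"))
  aux <- as_auxiliary(sheets)
  expect_true("BAD_INTERVAL" %in% report_errors(aux$report)$code)
})

test_that("native date cells, serial numbers and ISO text all parse to the same date", {
  expect_identical(parse_cell_date(as.Date("2021-05-02"))$value, as.Date("2021-05-02"))
  expect_identical(parse_cell_date("2021-05-02")$value, as.Date("2021-05-02"))
  serial <- as.numeric(as.Date("2021-05-02") - as.Date("1899-12-30"))
  expect_identical(parse_cell_date(serial)$value, as.Date("2021-05-02"))
  expect_identical(parse_cell_date("2021-13-45")$status, "bad")
})

test_that("auxiliary collections round-trip through a workbook field by field", {
  sim <- simulate_adherence(simulation_config(n_patients = 4,
                                              two_monitor_patients = 2,
                                              seed = 3))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "aux.xlsx")
  write_auxiliary(sim$aux, path)
  back <- read_auxiliary(path)
  for (part in c("em_info", "regimen", "added_openings",
                 "nonmonitored_periods", "patient_covariables",
                 "em_covariables", "adverse_events")) {
    expect_equal(as.data.frame(back[[part]]), as.data.frame(sim$aux[[part]]),
                 info = part)
  }
  expect_identical(nrow(back$report), 0L)
})

test_that("adding a malformed row never removes existing findings", {
  sheets <- aux_sheets_minimal()
  sheets$AddedOpenings <- data.frame(
    PatientCode = "A", Monitor = "EM01", Date = as.Date("2021-05-10"),
    Openings = 0L, stringsAsFactors = FALSE)   # ZERO_DELTA warning
  before <- as_auxiliary(sheets)$report
  expect_identical(nrow(before), 1L)
  sheets$Regimen <- rbind(sheets$Regimen, data.frame(
    PatientCode = "A", Monitor = "EM01", ExpectedOpenings = 1L,
    StartDate = as.Date("2021-06-01"), EndDate = as.Date("2021-06-10"),
    On = 5L, Off = NA_integer_, stringsAsFactors = FALSE))
  after <- as_auxiliary(sheets)$report
  key <- function(r) paste(r$severity, r$code, r$sheet, r$row)
  expect_true(all(key(before) %in% key(after)))
  expect_true("ON_OFF_PAIR" %in% after$code)
})

test_that("cross-reference validation flags the raw/aux mismatches", {
  sheets <- aux_sheets_minimal()
  aux <- as_auxiliary(sheets)

  # declared monitor without raw data -> warning, not error
  rep1 <- validate_cross_references(aux, monitors_seen = tibble::tibble(
    patient_code = character(), monitor = character()))
  expect_identical(rep1$code[rep1$severity == "warning"], "NO_RAW_DATA")
  expect_false(has_errors(rep1))

  # raw events for an undeclared monitor -> warning
  seen <- tibble::tibble(patient_code = c("A", "B"), monitor = c("EM01", "EM99"))
  rep2 <- validate_cross_references(aux, seen)
  expect_true("UNDECLARED_MONITOR" %in% rep2$code)
  expect_false(has_errors(rep2))

  # orphan auxiliary rows -> critical error
  sheets$AddedOpenings <- data.frame(
    PatientCode = "Z", Monitor = "EM77", Date = as.Date("2021-05-05"),
    Openings = 1L, stringsAsFactors = FALSE)
  rep3 <- validate_cross_references(as_auxiliary(sheets),
                                    tibble::tibble(patient_code = "A",
                                                   monitor = "EM01"))
  expect_true("ORPHAN_ROW" %in% report_errors(rep3)$code)
})

test_that("every window day must be covered by exactly one regimen period", {
  # overlap: two periods covering the same mid-window days
  sheets <- aux_sheets_minimal(start = as.Date("2021-01-01"),
                               end = as.Date("2021-02-10"))
  sheets$Regimen <- data.frame(
    PatientCode = "A", Monitor = "EM01", ExpectedOpenings = 1L,
    StartDate = as.Date(c("2021-01-01", "2021-01-15")),
    EndDate = as.Date(c("2021-01-31", "2021-02-10")),
    On = NA_integer_, Off = NA_integer_, stringsAsFactors = FALSE)
  rep <- validate_cross_references(as_auxiliary(sheets))
  expect_true("REGIMEN_OVERLAP" %in% report_errors(rep)$code)

  # gap: window day not covered at all
  sheets$Regimen$EndDate <- as.Date(c("2021-01-10", "2021-02-10"))
  sheets$Regimen$StartDate <- as.Date(c("2021-01-01", "2021-01-20"))
  rep <- validate_cross_references(as_auxiliary(sheets))
  expect_true("REGIMEN_GAP" %in% report_errors(rep)$code)
})
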