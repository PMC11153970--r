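sim_result <- function(seed = 21, n = 4) {
  sim <- simulate_adherence(simulation_config(n_patients = n,
                                              two_monitor_patients = 2,
                                              seed = seed))
  list(sim = sim, res = clean_adherence(sim$aux, sim$daily))
}

test_that("the workbook has the four sheets with censored days as empty cells", {
  x <- sim_result()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "implementation.xlsx")
  write_implementation(x$res, path)
  expect_identical(readxl::excel_sheets(path),
                   c("by monitor", "by patient", "summary by monitor",
                     "summary by patient"))
  back <- read_implementation(path)
  bm <- back[["by monitor"]]
  md <- x$res$monitor_daily
  expect_identical(nrow(bm), nrow(md))
  # censored day -> genuinely empty cell, read back as NA; never 0 or "NA"
  expect_true(any(!md$monitored))
  expect_true(all(is.na(bm$Implementation[!md$monitored])))
  expect_false(any(bm$Implementation[!md$monitored] %in% c(0, 1)))
  expect_type(bm$Implementation, "double")
  expect_equal(as.integer(bm$Implementation[md$monitored]),
               md$implementation[md$monitored])
})

test_that("row counts follow the monitoring windows", {
  x <- sim_result(seed = 22)
  md <- x$res$monitor_daily
  em <- x$res$aux$em_info
  expect_identical(nrow(md),
                   sum(as.integer(em$end_date - em$start_date) + 1L))
  pd <- x$res$patient_daily
  union_len <- md |>
    dplyr::distinct(patient_code, date) |>
    nrow()
  expect_identical(nrow(pd), union_len)
})

test_that("recomputing the summaries from the written by-monitor sheet reproduces them", {
  x <- sim_result(seed = 23)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "implementation.xlsx")
  write_implementation(x$res, path)
  bm <- read_implementation(path)[["by monitor"]]
  redo <- bm |>
    dplyr::group_by(PatientCode, Monitor) |>
    dplyr::summarise(monitored_days = sum(!is.na(Implementation)),
                     optimal_days = sum(Implementation == 1, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(rate = optimal_days / monitored_days)
  sm <- x$res$monitor_summary
  expect_identical(as.integer(redo$monitored_days), sm$monitored_days)
  expect_identical(as.integer(redo$optimal_days), sm$optimal_days)
  expect_equal(redo$rate, sm$implementation_rate)
  sm_back <- read_implementation(path)[["summary by monitor"]]
  expect_equal(sm_back$ImplementationRate, sm$implementation_rate)
})

test_that("both log files are always written, deterministically ordered", {
  dir <- withr::local_tempdir()
  write_logs(empty_report(), dir)
  expect_identical(readLines(file.path(dir, "errors.log")), character(0))
  expect_identical(readLines(file.path(dir, "warnings.log")), character(0))

  rep <- bind_reports(
    report_entry("warning", "NO_RAW_DATA", "EMInfo", 3, "w1"),
    report_entry("error", "BAD_DATE", "EMInfo", 2, "e1"),
    report_entry("warning", "IGNORED_FILE", "readme.txt", NA, "w2"))
  write_logs(rep, dir)
  errs <- readLines(file.path(dir, "errors.log"))
  warns <- readLines(file.path(dir, "warnings.log"))
  expect_length(errs, 1)
  expect_length(warns, 2)
  expect_match(errs, "^BAD_DATE\tEMInfo\t2\te1$")

  # identical rerun -> byte-identical logs
  dir2 <- withr::local_tempdir()
  write_logs(rep, dir2)
  expect_identical(readBin(file.path(dir, "warnings.log"), "raw", 1e5),
                   readBin(file.path(dir2, "warnings.log"), "raw", 1e5))
})

test_that("critical errors block the workbook; warnings alone do not", {
  sheets <- aux_sheets_minimal()
  sheets$Regimen$On <- 21L   # ON_OFF_PAIR
  daily <- daily_table("A", "EM01", as.Date("2021-05-02"), 1L)
  res <- clean_adherence(as_auxiliary(sheets), daily)
  expect_false(res$ok)
  dir <- withr::local_tempdir()
  expect_error(write_implementation(res, file.path(dir, "implementation.xlsx")),
               "critical errors")
  expect_false(file.exists(file.path(dir, "implementation.xlsx")))
  write_logs(res$report, dir)
  expect_gt(length(readLines(file.path(dir, "errors.log"))), 0)

  # warnings only: undeclared monitor in the raw data
  sheets2 <- aux_sheets_minimal()
  daily2 <- dplyr::bind_rows(daily,
                             daily_table("B", "EM99", as.Date("2021-05-02"), 1L))
  res2 <- clean_adherence(as_auxiliary(sheets2), daily2)
  expect_true(res2$ok)
  expect_true("UNDECLARED_MONITOR" %in% res2$report$code)
  path2 <- file.path(dir, "impl2.xlsx")
  write_implementation(res2, path2)
  expect_true(file.exists(path2))
})

test_that("the CSV mirror reproduces each sheet", {
  x <- sim_result(seed = 24, n = 2)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "implementation.xlsx")
  write_implementation(x$res, path, csv = TRUE)
  csvs <- list.files(dir, pattern = "\\.csv$")
  expect_length(csvs, 4)
  bp <- readr::read_csv(file.path(dir, "implementation_by_patient.csv"),
                        show_col_types = FALSE)
  expect_identical(nrow(bp), nrow(x$res$patient_daily))
})
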