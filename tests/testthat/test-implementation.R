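test_that("the daily rule reproduces the forced truth table over {0,1,2}^2", {
  for (corrected in 0:2) {
    for (expected in 0:2) {
      want <- if (corrected >= expected) 1L else 0L   # incl. 0 >= 0 -> optimal
      expect_identical(daily_implementation(corrected, expected), want)
    }
  }
  expect_identical(daily_implementation(3L, 1L), 1L)  # overconsumption not penalized
  expect_identical(daily_implementation(1L, 1L, monitored = FALSE), NA_integer_)
})

test_that("patient-day value is the product across in-scope monitors, NA-propagating", {
  mk <- function(vals) {
    tibble::tibble(patient_code = "A", monitor = paste0("EM", seq_along(vals)),
                   date = as.Date("2021-05-02"), implementation = vals)
  }
  expect_identical(patient_daily(mk(c(1L, 1L)))$implementation, 1L)
  expect_identical(patient_daily(mk(c(1L, 0L)))$implementation, 0L)
  expect_identical(patient_daily(mk(c(1L, NA)))$implementation, NA_integer_)
  expect_identical(patient_daily(mk(0L))$implementation, 0L)
  expect_identical(patient_daily(mk(c(1L, 1L)))$n_monitors_in_scope, 2L)
})

test_that("summary rates are optimal days over monitored days", {
  md <- tibble::tibble(
    patient_code = "A", monitor = "EM01",
    date = as.Date("2021-05-01") + 0:9,
    implementation = c(rep(1L, 9), 0L))
  ms <- summarize_monitors(md)
  expect_identical(ms$summary$monitored_days, 10L)
  expect_identical(ms$summary$optimal_days, 9L)
  expect_equal(ms$summary$implementation_rate, 0.9)

  # fully censored monitor: undefined rate, warning, not an error
  md_na <- dplyr::mutate(md, implementation = NA_integer_)
  ms_na <- summarize_monitors(md_na)
  expect_true(is.na(ms_na$summary$implementation_rate))
  expect_identical(ms_na$report$code, "ZERO_DENOMINATOR")
  expect_identical(ms_na$report$severity, "warning")
})

test_that("a 21/7 cycle with doses on every On day scores a perfect rate", {
  start <- as.Date("2021-03-01")
  sheets <- aux_sheets_minimal(start = start, end = start + 55,
                               expected = 1L, on = 21L, off = 7L)
  sched <- expand_regimen(list(start_date = start, end_date = start + 55,
                               expected_openings = 1L, on_days = 21L, off_days = 7L))
  on_days <- sched$date[sched$expected == 1L]
  daily <- daily_table("A", "EM01", on_days, 1L)
  res <- clean_adherence(as_auxiliary(sheets), daily)
  expect_true(res$ok)
  expect_identical(res$monitor_summary$monitored_days, 56L)
  expect_equal(res$monitor_summary$implementation_rate, 1.0)  # Off days: 0 >= 0
  # and taking nothing at all still scores the 14 Off days as optimal
  res0 <- clean_adherence(as_auxiliary(sheets),
                          daily_table(character(), character(),
                                      as.Date(character()), integer()))
  expect_identical(res0$monitor_summary$optimal_days, 14L)
})

test_that("a censored stretch on one of two monitors shrinks the patient denominator", {
  start <- as.Date("2021-06-01")
  sheets <- list(
    EMInfo = data.frame(PatientCode = "A", Monitor = c("EM01", "EM02"),
                        StartDate = start, EndDate = start + 29,
                        stringsAsFactors = FALSE),
    Regimen = data.frame(PatientCode = "A", Monitor = c("EM01", "EM02"),
                         ExpectedOpenings = 1L, StartDate = start,
                         EndDate = start + 29, On = NA_integer_,
                         Off = NA_integer_, stringsAsFactors = FALSE),
    NonMonitoredPeriods = data.frame(PatientCode = "A", Monitor = "EM02",
                                     StartDate = start + 10, EndDate = start + 19,
                                     stringsAsFactors = FALSE))
  dates <- start + 0:29
  daily <- dplyr::bind_rows(daily_table("A", "EM01", dates, 1L),
                            daily_table("A", "EM02", dates, 1L))
  res <- clean_adherence(as_auxiliary(sheets), daily)
  expect_identical(res$patient_summary$monitored_days, 20L)
  expect_identical(res$patient_summary$optimal_days, 20L)
})

test_that("patient rate never exceeds any shared-window monitor rate", {
  set.seed(31)
  start <- as.Date("2021-02-01")
  for (i in 1:20) {
    n <- 30
    impl1 <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(0.2, 0.7, 0.1))
    impl2 <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(0.2, 0.7, 0.1))
    md <- dplyr::bind_rows(
      tibble::tibble(patient_code = "A", monitor = "EM01", date = start + 0:(n - 1),
                     implementation = impl1),
      tibble::tibble(patient_code = "A", monitor = "EM02", date = start + 0:(n - 1),
                     implementation = impl2))
    pd <- patient_daily(md)
    ps <- summarize_patients(pd)$summary
    # per-monitor rates over the common monitored days (patient non-NA days)
    ok_days <- pd$date[!is.na(pd$implementation)]
    if (length(ok_days) == 0) next
    r1 <- mean(impl1[match(ok_days, start + 0:(n - 1))])
    r2 <- mean(impl2[match(ok_days, start + 0:(n - 1))])
    expect_lte(ps$implementation_rate, min(r1, r2) + 1e-12)
  }
})

test_that("covariables join onto the summaries by their keys", {
  sim <- simulate_adherence(simulation_config(n_patients = 3,
                                              two_monitor_patients = 1, seed = 5))
  res <- clean_adherence(sim$aux, sim$daily)
  expect_true(all(c("Age", "Sex") %in% names(res$patient_summary)))
  expect_true(all(c("Drug", "RegimenType") %in% names(res$monitor_summary)))
  expect_false(anyNA(res$monitor_summary$Drug))
})
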