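# Brute-force day-by-day recomputation of the implementation calculus,
# written with plain loops over sheet-native data frames so it shares no
# code with the package's vectorised pipeline. Used as the independent
# oracle in equivalence tests.

oracle_expected_on <- function(regimen, pc, mon, date) {
  for (j in seq_len(nrow(regimen))) {
    r <- regimen[j, ]
    if (r$PatientCode != pc || r$Monitor != mon) next
    if (date < r$StartDate || date > r$EndDate) next
    if (is.na(r$On) || is.na(r$Off)) return(r$ExpectedOpenings)
    pos <- as.integer(date - r$StartDate) %% (r$On + r$Off)
    return(if (pos < r$On) r$ExpectedOpenings else 0L)
  }
  NA_integer_
}

oracle_monitor_daily <- function(sheets, daily, corrections = TRUE) {
  em <- sheets$EMInfo
  ao <- if (corrections) sheets$AddedOpenings else NULL
  np <- if (corrections) sheets$NonMonitoredPeriods else NULL
  parts <- list()
  for (i in seq_len(nrow(em))) {
    pc <- em$PatientCode[i]; mon <- em$Monitor[i]
    win_dates <- seq(em$StartDate[i], em$EndDate[i], by = "day")
    n <- length(win_dates)
    expected <- integer(n); recorded <- integer(n); adjustment <- integer(n)
    monitored <- rep(TRUE, n)
    dsub <- daily[daily$patient_code == pc & daily$monitor == mon, , drop = FALSE]
    asub <- if (!is.null(ao)) ao[ao$PatientCode == pc & ao$Monitor == mon, , drop = FALSE]
    nsub <- if (!is.null(np)) np[np$PatientCode == pc & np$Monitor == mon, , drop = FALSE]
    for (di in seq_len(n)) {
      d <- win_dates[di]
      expected[di] <- oracle_expected_on(sheets$Regimen, pc, mon, d)
      recorded[di] <- sum(dsub$recorded[dsub$date == d])
      if (!is.null(asub) && nrow(asub) > 0) {
        adjustment[di] <- sum(asub$Openings[asub$Date == d])
      }
      if (!is.null(nsub) && nrow(nsub) > 0 &&
          any(d >= nsub$StartDate & d <= nsub$EndDate)) {
        monitored[di] <- FALSE
      }
    }
    corrected <- pmax(0L, recorded + adjustment)
    impl <- ifelse(monitored, ifelse(corrected >= expected, 1L, 0L), NA_integer_)
    parts[[i]] <- data.frame(
      patient_code = pc, monitor = mon, date = win_dates, expected = expected,
      recorded = as.integer(recorded), adjustment = as.integer(adjustment),
      corrected = as.integer(corrected), monitored = monitored,
      implementation = as.integer(impl), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  out[order(out$patient_code, out$monitor, out$date), ]
}

oracle_patient_daily <- function(monitor_daily) {
  out <- NULL
  for (pc in sort(unique(monitor_daily$patient_code))) {
    sub <- monitor_daily[monitor_daily$patient_code == pc, ]
    pd_dates <- sort(unique(sub$date))
    for (di in seq_along(pd_dates)) {
      d <- pd_dates[di]
      vals <- sub$implementation[sub$date == d]
      impl <- if (any(is.na(vals))) NA_integer_ else as.integer(prod(vals))
      out <- rbind(out, data.frame(patient_code = pc, date = d,
                                   implementation = impl,
                                   n_monitors_in_scope = length(vals),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

oracle_rate <- function(impl) {
  monitored <- sum(!is.na(impl))
  if (monitored == 0) return(NA_real_)
  sum(impl == 1L, na.rm = TRUE) / monitored
}

oracle_monitor_summary <- function(monitor_daily) {
  out <- NULL
  keys <- unique(monitor_daily[c("patient_code", "monitor")])
  for (i in seq_len(nrow(keys))) {
    sub <- monitor_daily[monitor_daily$patient_code == keys$patient_code[i] &
                           monitor_daily$monitor == keys$monitor[i], ]
    out <- rbind(out, data.frame(
      patient_code = keys$patient_code[i], monitor = keys$monitor[i],
      monitored_days = sum(!is.na(sub$implementation)),
      optimal_days = sum(sub$implementation == 1L, na.rm = TRUE),
      implementation_rate = oracle_rate(sub$implementation),
      stringsAsFactors = FALSE))
  }
  out[order(out$patient_code, out$monitor), ]
}

oracle_patient_summary <- function(patient_days) {
  out <- NULL
  for (pc in sort(unique(patient_days$patient_code))) {
    sub <- patient_days[patient_days$patient_code == pc, ]
    out <- rbind(out, data.frame(
      patient_code = pc,
      monitored_days = sum(!is.na(sub$implementation)),
      optimal_days = sum(sub$implementation == 1L, na.rm = TRUE),
      implementation_rate = oracle_rate(sub$implementation),
      stringsAsFactors = FALSE))
  }
  out
}

expect_pipeline_matches_oracle <- function(fix, corrections = TRUE) {
  res <- clean_adherence(as_auxiliary(fix$sheets), fix$daily,
                         corrections = corrections)
  expect_true(res$ok)
  ora <- oracle_monitor_daily(fix$sheets, fix$daily, corrections = corrections)
  got <- as.data.frame(res$monitor_daily[names(ora)])
  rownames(ora) <- NULL; rownames(got) <- NULL
  expect_equal(got, ora)
  ora_pd <- oracle_patient_daily(ora)
  got_pd <- as.data.frame(res$patient_daily)
  rownames(ora_pd) <- NULL; rownames(got_pd) <- NULL
  expect_equal(got_pd, ora_pd)
  ms <- oracle_monitor_summary(ora)
  got_ms <- as.data.frame(res$monitor_summary[names(ms)])
  rownames(got_ms) <- NULL
  expect_equal(got_ms, ms)
  ps <- oracle_patient_summary(ora_pd)
  got_ps <- as.data.frame(res$patient_summary[names(ps)])
  rownames(got_ps) <- NULL
  expect_equal(got_ps, ps)
  invisible(res)
}
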