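#' Configuration for the synthetic EM study generator
#'
#' Bundles the parameters of a simulated electronic-monitoring study with
#' known ground truth. The defaults describe a small oncology-style cohort:
#' 10 patients of whom 5 use two EMs (15 monitors), monitoring durations
#' log-normal around a median of 187 days, mostly continuous once-daily
#' regimens plus one 21-days-on / 7-days-off cyclic monitor and one
#' two-monitor alternate-day pair, high per-patient intake probability
#' (Beta(60, 2.5), mean 0.96), and realistic deviation rates: 4% of taken
#' doses are pocket doses, a 2% chance per day of an extra (curiosity /
#' pill-count) opening, and about 0.8 nonmonitored intervals per 100
#' monitored days of 3–14 days each.
#'
#' @param n_patients Number of patients.
#' @param two_monitor_patients How many patients use two EMs.
#' @param window_days Fixed monitoring length in days, or `NULL` to draw
#'   log-normal lengths.
#' @param window_days_meanlog,window_days_sdlog Log-normal parameters of
#'   the monitoring length when `window_days` is `NULL`.
#' @param prob_twice_daily Probability that a continuous monitor expects 2
#'   openings/day instead of 1.
#' @param cyclic Include one 21/7 cyclic monitor?
#' @param alternating Give one two-monitor patient an alternate-day
#'   (`On = 1, Off = 1`) pair of EMs with offset phases?
#' @param regimen_change Give one monitor a mid-window regimen change
#'   (second regimen row)?
#' @param intake_prob Fixed per-dose intake probability for every patient,
#'   or `NULL` to draw per-patient probabilities from
#'   `Beta(intake_shape1, intake_shape2)`.
#' @param intake_shape1,intake_shape2 Beta parameters of the per-patient
#'   intake probability.
#' @param pocket_dose_rate Probability that a taken dose bypasses the EM
#'   (documented pocket dose, corrected by `AddedOpenings` +1).
#' @param extra_opening_rate Daily probability of one documented extra EM
#'   opening without intake (corrected by `AddedOpenings` -1).
#' @param nmp_rate Expected number of nonmonitored intervals per 100
#'   window days.
#' @param nmp_len Length-2 integer vector: min/max length (days) of a
#'   nonmonitored interval.
#' @param start_date Earliest possible monitoring start.
#' @param seed Integer seed; a fixed seed makes every output (including
#'   files) byte-identical across runs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 10,
                              two_monitor_patients = 5,
                              window_days = NULL,
                              window_days_meanlog = log(187),
                              window_days_sdlog = 0.6,
                              prob_twice_daily = 0.2,
                              cyclic = TRUE,
                              alternating = TRUE,
                              regimen_change = TRUE,
                              intake_prob = NULL,
                              intake_shape1 = 60,
                              intake_shape2 = 2.5,
                              pocket_dose_rate = 0.04,
                              extra_opening_rate = 0.02,
                              nmp_rate = 0.8,
                              nmp_len = c(3L, 14L),
                              start_date = as.Date("2021-01-01"),
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    two_monitor_patients = as.integer(two_monitor_patients),
    window_days = if (!is.null(window_days)) as.integer(window_days),
    window_days_meanlog = window_days_meanlog,
    window_days_sdlog = window_days_sdlog,
    prob_twice_daily = prob_twice_daily,
    cyclic = isTRUE(cyclic),
    alternating = isTRUE(alternating),
    regimen_change = isTRUE(regimen_change),
    intake_prob = intake_prob,
    intake_shape1 = intake_shape1,
    intake_shape2 = intake_shape2,
    pocket_dose_rate = pocket_dose_rate,
    extra_opening_rate = extra_opening_rate,
    nmp_rate = nmp_rate,
    nmp_len = as.integer(nmp_len),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (!is.null(cfg$window_days) && cfg$window_days < 1) {
    stop("window_days must be >= 1", call. = FALSE)
  }
  if (cfg$two_monitor_patients > cfg$n_patients) {
    stop("two_monitor_patients cannot exceed n_patients", call. = FALSE)
  }
  probs <- c(cfg$prob_twice_daily, cfg$pocket_dose_rate,
             cfg$extra_opening_rate, cfg$intake_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Read a generator configuration from a YAML file
#'
#' @param path YAML file whose keys are [simulation_config()] arguments.
#' @return A `simulation_config` object.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$start_date)) vals$start_date <- as.Date(vals$start_date)
  do.call(simulation_config, vals)
}

#' Simulate a ground-truthed EM adherence study
#'
#' Generates raw EM event files, a matching Auxiliary Data workbook, and
#' the true per-day implementation. Every injected deviation is recorded
#' *both* as a perturbation of the raw events *and* as the corresponding
#' auxiliary row — a pocket dose removes the opening from the events and
#' adds an `AddedOpenings` +1 row; an extra opening adds an event and an
#' `AddedOpenings` -1 row; a nonmonitored interval removes all activity
#' and adds a `NonMonitoredPeriods` row — so running the full cleaning
#' pipeline on the generated inputs recovers the truth exactly.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory. When given, writes `raw/` (event CSVs whose
#'   names contain `"eventslist"`), `auxiliary_data.xlsx`, and the truth
#'   tables as CSVs. `NULL` keeps everything in memory.
#' @return A list with `aux` (an `adh_aux` object), `daily` (per-day
#'   recorded openings), `events` (the raw event rows), truth tables
#'   (`truth_monitor_daily`, `truth_patient_daily`,
#'   `truth_patient_summary`), the per-patient intake probabilities
#'   (`patients`), `config`, and file `paths` when `dir` was given.
#' @export
simulate_adherence <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  sim <- withr::with_seed(config$seed, simulate_adherence_impl(config))
  if (!is.null(dir)) {
    sim$paths <- write_simulation(sim, dir)
  }
  sim
}

simulate_adherence_impl <- function(cfg) {
  n <- cfg$n_patients
  patient_codes <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("P%03d", seq_len(n))
  two_em <- if (cfg$two_monitor_patients > 0) {
    sort(sample(n, cfg$two_monitor_patients))
  } else integer(0)
  p_intake <- if (!is.null(cfg$intake_prob)) {
    rep(cfg$intake_prob, n)
  } else {
    stats::rbeta(n, cfg$intake_shape1, cfg$intake_shape2)
  }

  drugs <- c("pazopanib", "trametinib", "dabrafenib", "palbociclib",
             "everolimus", "alectinib", "imatinib", "erlotinib")

  em_info <- list(); regimen <- list(); monitors <- list()
  em_cov <- list()
  em_counter <- 0L
  alternating_patient <- if (cfg$alternating && length(two_em) > 0) two_em[1] else 0L
  cyclic_patient <- if (cfg$cyclic) setdiff(seq_len(n), alternating_patient)[1] else 0L
  change_patient <- if (cfg$regimen_change) {
    cand <- setdiff(seq_len(n), c(alternating_patient, cyclic_patient))
    if (length(cand) > 0) cand[length(cand)] else 0L
  } else 0L

  for (i in seq_len(n)) {
    n_days <- if (!is.null(cfg$window_days)) cfg$window_days else {
      max(14L, as.integer(round(stats::rlnorm(1, cfg$window_days_meanlog,
                                              cfg$window_days_sdlog))))
    }
    w_start <- cfg$start_date + sample.int(120L, 1) - 1L
    w_end <- w_start + n_days - 1L
    n_em <- if (i %in% two_em) 2L else 1L
    for (m in seq_len(n_em)) {
      em_counter <- em_counter + 1L
      mon <- sprintf("EM%02d", em_counter)
      s <- w_start; e <- w_end
      reg_rows <- NULL
      if (i == alternating_patient) {
        # alternate-day pair: second EM starts (and cycles) one day later
        if (m == 2L) s <- s + 1L
        reg_rows <- tibble::tibble(
          patient_code = patient_codes[i], monitor = mon,
          expected_openings = 1L, start_date = s, end_date = e,
          on_days = 1L, off_days = 1L)
        drug <- "imatinib"; rtype <- "cyclic"
      } else if (i == cyclic_patient && m == 1L) {
        reg_rows <- tibble::tibble(
          patient_code = patient_codes[i], monitor = mon,
          expected_openings = 1L, start_date = s, end_date = e,
          on_days = 21L, off_days = 7L)
        drug <- "palbociclib"; rtype <- "cyclic"
      } else if (i == change_patient && m == 1L && (e - s) >= 13) {
        mid <- s + as.integer(e - s) %/% 2L
        reg_rows <- tibble::tibble(
          patient_code = patient_codes[i], monitor = mon,
          expected_openings = c(1L, 2L),
          start_date = c(s, mid + 1L), end_date = c(mid, e),
          on_days = NA_integer_, off_days = NA_integer_)
        drug <- sample(drugs, 1); rtype <- "continuous"
      } else {
        eo <- if (stats::runif(1) < cfg$prob_twice_daily) 2L else 1L
        reg_rows <- tibble::tibble(
          patient_code = patient_codes[i], monitor = mon,
          expected_openings = eo, start_date = s, end_date = e,
          on_days = NA_integer_, off_days = NA_integer_)
        drug <- sample(drugs, 1); rtype <- "continuous"
      }
      em_info[[length(em_info) + 1L]] <- tibble::tibble(
        patient_code = patient_codes[i], monitor = mon,
        start_date = s, end_date = e)
      regimen[[length(regimen) + 1L]] <- reg_rows
      em_cov[[length(em_cov) + 1L]] <- tibble::tibble(
        patient_code = patient_codes[i], monitor = mon,
        Drug = drug, RegimenType = rtype)
      monitors[[length(monitors) + 1L]] <- list(
        patient = i, patient_code = patient_codes[i], monitor = mon,
        start = s, end = e, regimen = reg_rows)
    }
  }
  em_info <- dplyr::bind_rows(em_info)
  regimen <- dplyr::bind_rows(regimen)
  em_cov <- dplyr::bind_rows(em_cov)

  events <- list(); added <- list(); nmps <- list(); truth <- list()
  for (mo in monitors) {
    sched <- build_schedule(
      list(patient_code = mo$patient_code, monitor = mo$monitor,
           start_date = mo$start, end_date = mo$end),
      mo$regimen)
    n_days <- nrow(sched)
    # nonmonitored intervals (union; deviations never generated inside)
    in_nmp <- rep(FALSE, n_days)
    n_int <- stats::rpois(1, cfg$nmp_rate * n_days / 100)
    for (k in seq_len(n_int)) {
      len <- sample(seq(cfg$nmp_len[1], cfg$nmp_len[2]), 1)
      if (len >= n_days) len <- max(1L, n_days - 1L)
      at <- sample.int(n_days - len + 1L, 1)
      in_nmp[at:(at + len - 1L)] <- TRUE
      nmps[[length(nmps) + 1L]] <- tibble::tibble(
        patient_code = mo$patient_code, monitor = mo$monitor,
        start_date = sched$date[at], end_date = sched$date[at + len - 1L])
    }
    p <- p_intake[mo$patient]
    taken <- integer(n_days); openings <- integer(n_days)
    pockets <- integer(n_days); extras <- integer(n_days)
    for (d in seq_len(n_days)) {
      if (in_nmp[d]) next
      taken[d] <- stats::rbinom(1, sched$expected[d], p)
      pockets[d] <- if (cfg$pocket_dose_rate > 0 && taken[d] > 0) {
        stats::rbinom(1, taken[d], cfg$pocket_dose_rate)
      } else 0L
      extras[d] <- stats::rbinom(1, 1, cfg$extra_opening_rate)
      openings[d] <- taken[d] - pockets[d] + extras[d]
    }
    for (d in which(openings > 0)) {
      secs <- sort(sample.int(86400L, openings[d]))
      events[[length(events) + 1L]] <- tibble::tibble(
        patient_code = mo$patient_code, monitor = mo$monitor,
        timestamp = paste(format(sched$date[d]),
                          format(as.POSIXct(secs, tz = "UTC",
                                            origin = "1970-01-01"), "%H:%M:%S")),
        date = sched$date[d])
    }
    for (d in which(pockets > 0)) {
      added[[length(added) + 1L]] <- tibble::tibble(
        patient_code = mo$patient_code, monitor = mo$monitor,
        date = sched$date[d], openings_delta = pockets[d])
    }
    for (d in which(extras > 0)) {
      added[[length(added) + 1L]] <- tibble::tibble(
        patient_code = mo$patient_code, monitor = mo$monitor,
        date = sched$date[d], openings_delta = -extras[d])
    }
    truth[[length(truth) + 1L]] <- tibble::tibble(
      patient_code = mo$patient_code, monitor = mo$monitor,
      date = sched$date, expected = sched$expected,
      doses_taken = taken, monitored = !in_nmp,
      implementation = ifelse(in_nmp, NA_integer_,
                              as.integer(taken >= sched$expected)))
  }
  events <- dplyr::bind_rows(events)
  added <- dplyr::bind_rows(added)
  nmp_tbl <- dplyr::bind_rows(nmps)
  truth_monitor <- dplyr::bind_rows(truth) |>
    dplyr::arrange(.data$patient_code, .data$monitor, .data$date)

  truth_patient <- truth_monitor |>
    dplyr::group_by(.data$patient_code, .data$date) |>
    dplyr::summarise(
      implementation = if (anyNA(.data$implementation)) NA_integer_ else
        as.integer(prod(.data$implementation)),
      .groups = "drop")
  truth_patient_summary <- truth_patient |>
    dplyr::group_by(.data$patient_code) |>
    dplyr::summarise(
      monitored_days = sum(!is.na(.data$implementation)),
      optimal_days = sum(.data$implementation == 1L, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(implementation_rate = ifelse(
      .data$monitored_days > 0,
      .data$optimal_days / .data$monitored_days, NA_real_)) |>
    dplyr::left_join(tibble::tibble(patient_code = patient_codes,
                                    true_intake_prob = p_intake),
                     by = "patient_code")

  # descriptive enrichment sheets
  patient_cov <- tibble::tibble(
    patient_code = patient_codes,
    Age = pmax(25, pmin(90, round(stats::rnorm(n, 63, 12)))),
    Sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.4, 0.6)))
  ae_n <- stats::rpois(1, max(1, n %/% 3))
  adverse <- if (ae_n > 0) {
    idx <- sample.int(n, ae_n, replace = TRUE)
    tibble::tibble(
      patient_code = patient_codes[idx],
      date = cfg$start_date + sample.int(200L, ae_n, replace = TRUE),
      event = sample(c("Fatigue", "Nausea", "Rash", "Diarrhea"), ae_n,
                     replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.15)),
      grade = as.character(sample(1:3, ae_n, replace = TRUE,
                                  prob = c(0.6, 0.3, 0.1))))
  } else {
    tibble::tibble(patient_code = character(), date = as.Date(character()),
                   event = character(), grade = character())
  }
  # adverse events must reference monitored patients only (schema contract)
  adverse <- adverse[adverse$patient_code %in% em_info$patient_code, ]

  aux <- as_auxiliary(list(
    EMInfo = setNames(em_info, c("PatientCode", "Monitor", "StartDate", "EndDate")),
    Regimen = setNames(regimen, c("PatientCode", "Monitor", "ExpectedOpenings",
                                  "StartDate", "EndDate", "On", "Off")),
    PatientCovariables = setNames(patient_cov, c("PatientCode", "Age", "Sex")),
    EMCovariables = setNames(em_cov, c("PatientCode", "Monitor", "Drug",
                                       "RegimenType")),
    AddedOpenings = if (nrow(added) > 0) {
      setNames(added, c("PatientCode", "Monitor", "Date", "Openings"))
    } else {
      tibble::tibble(PatientCode = character(), Monitor = character(),
                     Date = as.Date(character()), Openings = integer())
    },
    NonMonitoredPeriods = if (nrow(nmp_tbl) > 0) {
      setNames(nmp_tbl, c("PatientCode", "Monitor", "StartDate", "EndDate"))
    } else {
      tibble::tibble(PatientCode = character(), Monitor = character(),
                     StartDate = as.Date(character()),
                     EndDate = as.Date(character()))
    },
    AdverseEvents = setNames(adverse, c("PatientCode", "Date", "Event", "Grade"))
  ))

  daily <- aggregate_daily(
    if (nrow(events) > 0) events[c("patient_code", "monitor", "date")] else NULL)

  list(aux = aux, daily = daily, events = events,
       truth_monitor_daily = truth_monitor,
       truth_patient_daily = truth_patient,
       truth_patient_summary = truth_patient_summary,
       patients = tibble::tibble(patient_code = patient_codes,
                                 true_intake_prob = p_intake),
       config = cfg)
}

write_simulation <- function(sim, dir) {
  raw_dir <- file.path(dir, "raw")
  if (!dir.exists(raw_dir)) dir.create(raw_dir, recursive = TRUE)
  ev <- sim$events
  paths <- list(raw_dir = raw_dir)
  codes <- unique(ev$patient_code)
  half <- if (length(codes) > 1) codes[seq_len(ceiling(length(codes) / 2))] else codes
  chunks <- list(`1` = ev[ev$patient_code %in% half, ],
                 `2` = ev[!ev$patient_code %in% half, ])
  paths$raw_files <- character(0)
  for (k in names(chunks)) {
    if (nrow(chunks[[k]]) == 0) next
    f <- file.path(raw_dir, sprintf("em_raw_%s_eventslist.csv", k))
    readr::write_csv(
      tibble::tibble(PatientCode = chunks[[k]]$patient_code,
                     Monitor = chunks[[k]]$monitor,
                     Date = chunks[[k]]$timestamp), f)
    paths$raw_files <- c(paths$raw_files, f)
  }
  paths$aux = file.path(dir, "auxiliary_data.xlsx")
  write_auxiliary(sim$aux, paths$aux)
  paths$truth_monitor_daily <- file.path(dir, "truth_monitor_daily.csv")
  readr::write_csv(sim$truth_monitor_daily, paths$truth_monitor_daily, na = "")
  paths$truth_patient_summary <- file.path(dir, "truth_patient_summary.csv")
  readr::write_csv(sim$truth_patient_summary, paths$truth_patient_summary, na = "")
  paths
}
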