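test_that("a fixed seed makes every generated file byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- simulation_config(n_patients = 3, two_monitor_patients = 1, seed = 17)
  simulate_adherence(cfg, dir = d1)
  simulate_adherence(cfg, dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 3)
  expect_identical(sort(files), sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
})

test_that("perfect adherence with no deviations yields rate 1 end to end", {
  cfg <- simulation_config(n_patients = 2, two_monitor_patients = 0,
                           window_days = 30, intake_prob = 1,
                           pocket_dose_rate = 0, extra_opening_rate = 0,
                           nmp_rate = 0, cyclic = FALSE, alternating = FALSE,
                           regimen_change = FALSE, prob_twice_daily = 0,
                           seed = 2)
  sim <- simulate_adherence(cfg)
  expect_true(all(sim$truth_patient_summary$implementation_rate == 1))
  res <- clean_adherence(sim$aux, sim$daily)
  expect_true(all(res$patient_summary$implementation_rate == 1))
})

test_that("every injected deviation appears in both the raw and the auxiliary data", {
  sim <- simulate_adherence(simulation_config(n_patients = 5,
                                              two_monitor_patients = 2,
                                              seed = 8))
  added <- sim$aux$added_openings
  expect_gt(nrow(added), 0)
  expect_gt(nrow(sim$aux$nonmonitored_periods), 0)
  # recorded openings plus the net documented delta reconstruct the doses
  # actually taken, on every monitored day
  tm <- sim$truth_monitor_daily
  key <- paste(tm$patient_code, tm$monitor, tm$date)
  daily_key <- paste(sim$daily$patient_code, sim$daily$monitor, sim$daily$date)
  added_key <- paste(added$patient_code, added$monitor, added$date)
  rec <- sim$daily$recorded[match(key, daily_key)]
  rec[is.na(rec)] <- 0L
  net <- vapply(key, function(k) {
    sum(added$openings_delta[added_key == k])
  }, numeric(1))
  expect_identical(tm$doses_taken[tm$monitored],
                   as.integer(rec + net)[tm$monitored])
  # no deviation or recorded opening falls on a censored day
  cen_key <- key[!tm$monitored]
  expect_length(intersect(cen_key, daily_key), 0)
  expect_length(intersect(cen_key, paste(added$patient_code, added$monitor,
                                         added$date)), 0)
})

test_that("cleaning recovers the generator truth exactly, raw does not", {
  sim <- simulate_adherence(simulation_config(n_patients = 6,
                                              two_monitor_patients = 3,
                                              seed = 14))
  res <- clean_adherence(sim$aux, sim$daily)
  expect_true(res$ok)
  got <- res$monitor_daily[c("patient_code", "monitor", "date", "implementation")]
  want <- sim$truth_monitor_daily[c("patient_code", "monitor", "date",
                                    "implementation")]
  expect_equal(as.data.frame(got), as.data.frame(want))
  raw <- clean_adherence(sim$aux, sim$daily, corrections = FALSE)
  expect_false(isTRUE(all.equal(
    raw$patient_summary$implementation_rate,
    res$patient_summary$implementation_rate)))
})

test_that("the raw-vs-clean gap grows with the injected deviation rates", {
  gap_at <- function(pocket, nmp, seed) {
    cfg <- simulation_config(n_patients = 5, two_monitor_patients = 1,
                             window_days = 60, pocket_dose_rate = pocket,
                             extra_opening_rate = 0.02, nmp_rate = nmp,
                             seed = seed)
    sim <- simulate_adherence(cfg)
    clean <- clean_adherence(sim$aux, sim$daily)
    raw <- clean_adherence(sim$aux, sim$daily, corrections = FALSE)
    mean(clean$patient_summary$implementation_rate) -
      mean(raw$patient_summary$implementation_rate)
  }
  seeds <- 1:5
  g0 <- mean(vapply(seeds, function(s) gap_at(0, 0, s), numeric(1)))
  g1 <- mean(vapply(seeds, function(s) gap_at(0.05, 0.8, s), numeric(1)))
  g2 <- mean(vapply(seeds, function(s) gap_at(0.15, 2.5, s), numeric(1)))
  expect_identical(g0, 0)          # nothing to correct
  expect_gt(g1, 0)
  expect_gt(g2, g1)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(window_days = 0), "window_days")
  expect_error(simulation_config(two_monitor_patients = 3, n_patients = 2),
               "two_monitor_patients")
  expect_error(simulation_config(pocket_dose_rate = 1.4), "probabilities")
})

test_that("configurations load from YAML", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "config.yaml")
  writeLines(c("n_patients: 3", "two_monitor_patients: 1", "seed: 9",
               "window_days: 20", "intake_prob: 0.9"), path)
  cfg <- read_simulation_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_identical(cfg$n_patients, 3L)
  sim <- simulate_adherence(cfg)
  expect_identical(nrow(sim$truth_patient_summary), 3L)
})
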