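test_that("the default cohort has the expected shape and reloads through the CSV contract", {
  sim <- simulate_cohort(seed = 101)
  expect_equal(nrow(sim$participants), 230)
  for (nm in c("dispensing", "eamd_events", "pill_returns", "self_report",
               "efv_concentrations", "labs", "genotypes")) {
    expect_gt(nrow(sim[[nm]]), 0)
  }
  expect_equal(nrow(sim$truth), 230 * 336)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$issues), 0)
  expect_equal(nrow(back$participants), 230)
  expect_equal(back$eamd_events$timestamp, sim$eamd_events$timestamp)
})

test_that("regeneration with the same seed is identical; different seeds differ", {
  a <- simulate_cohort(seed = 5, include_events = FALSE)
  b <- simulate_cohort(seed = 5, include_events = FALSE)
  expect_identical(a$labs, b$labs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$pill_returns, b$pill_returns)
  c <- simulate_cohort(seed = 6, include_events = FALSE)
  expect_false(identical(a$truth, c$truth))
  # and the written form is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  f <- "labs.csv"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("with measurement noise off, estimators recover the ground truth", {
  cfg <- default_sim_config(
    measurement = list(p_pocket_dose = 0, dead_battery_start = 0,
                       sr_yes_bias = 0, pill_dump_prob = 0,
                       study_visit_attend = 1, folder_vl_prob = 1),
    attrition = c(in_care = 1, transferred = 0, died = 0, ltfu = 0,
                  withdrew = 0)
  )
  sim <- simulate_cohort(cfg, seed = 77)
  m <- measured_landmark_summary(sim, "week48")
  # EAMD with no pocket doses and no dead batteries equals truth exactly
  expect_lt(max(abs(m$eamd - m$truth), na.rm = TRUE), 1)
  # unbiased SR is 100 exactly when the last three days were all dosed
  sel <- dplyr::inner_join(
    sim$self_report, sim$participants[c("participant_id", "randomisation_date")],
    by = "participant_id")
  idx <- match(sel$participant_id, sim$internal$ids)
  vday <- as.integer(sel$visit_date - sel$randomisation_date)
  last3 <- vapply(seq_along(idx), function(k) {
    sum(sim$internal$dose[idx[k], (vday[k] - 2):vday[k]])
  }, numeric(1))
  expect_equal(sr_adherence(sel$took_day1, sel$took_day2, sel$took_day3),
               100 * last3 / 3)
  # CPC without dumping tracks interval adherence to rounding
  pr <- sim$pill_returns
  cpc <- cpc_adherence(pr$tablets_dispensed_since_last, pr$tablets_returned,
                       pr$count_date, pr$last_dispense_date)$value
  expect_true(all(cpc <= 100 + 1e-9))
})

test_that("the two-state chain attains its closed-form stationary adherence", {
  expect_equal(markov_stationary_adherence(0.99, 0.65),
               0.35 / (0.01 + 0.35))
  cfg <- default_sim_config(
    n_participants = 400L,
    adherence_mix = list(p_class = c(high = 0, medium = 1, low = 0),
                         stay_dosing = c(high = 0.99, medium = 0.97, low = 0.93),
                         stay_gap = c(high = 0.65, medium = 0.85, low = 0.93))
  )
  sim <- simulate_cohort(cfg, seed = 11, include_events = FALSE)
  target <- 100 * markov_stationary_adherence(0.97, 0.85)
  observed <- 100 * mean(sim$internal$dose)
  expect_lt(abs(observed - target), 2)
})

test_that("ground-truth adherence summarises the dosing record", {
  truth <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 6),
    day = rep(0:5, 2),
    dose_taken = c(rep(1L, 6), rep(c(1L, 0L), 3)))
  upto <- tibble::tibble(participant_id = c("A", "B"), days_in_care = 6L)
  ta <- truth_adherence(truth, upto)
  expect_equal(ta$truth_adherence[ta$participant_id == "A"], 100)
  expect_equal(ta$truth_adherence[ta$participant_id == "B"], 50)
})

test_that("day-level summaries equal the full event-level estimator pipeline", {
  sim <- simulate_cohort(seed = 29)
  fast <- measured_landmark_summary(sim, "week48")
  est <- compute_adherence(sim, "week48")
  wide <- est |>
    dplyr::select("participant_id", "method", "value") |>
    tidyr::pivot_wider(names_from = "method", values_from = "value")
  j <- dplyr::inner_join(fast, wide, by = "participant_id")
  expect_equal(nrow(j), nrow(fast))
  expect_equal(j$eamd, j$EAMD)
  expect_equal(j$sr, j$SR)
  expect_equal(j$cpc, j$CPC)
  expect_equal(j$pr_average, j$PR_AVERAGE)
  expect_equal(j$pr_gaps, j$PR_GAPS)
})
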