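# Independent oracles, deliberately using different algorithms from the
# implementation they check.

# Interval/event-based possession oracle for medication-free days: tracks
# the supply-exhaustion date across dispensings (carryover uncapped) instead
# of simulating day by day.
oracle_free_days <- function(dispense_days, days_supplied, period_days) {
  keep <- dispense_days >= 0 & dispense_days < period_days
  dispense_days <- dispense_days[keep]
  days_supplied <- days_supplied[keep]
  o <- order(dispense_days)
  dispense_days <- dispense_days[o]
  days_supplied <- days_supplied[o]
  exhaust <- 0
  free <- 0
  for (k in seq_along(dispense_days)) {
    d <- dispense_days[k]
    if (d > exhaust) free <- free + (d - exhaust)
    exhaust <- max(exhaust, d) + days_supplied[k]
  }
  if (exhaust < period_days) free <- free + (period_days - exhaust)
  as.integer(free)
}

# Brute-force pairwise concordance AUC over all (event, non-event) pairs.
oracle_auc_pairs <- function(scores, y) {
  y <- as.logical(y)
  cases <- scores[y]
  controls <- scores[!y]
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(cases) * length(controls))
}

random_schedule <- function(period_max = 400) {
  period <- sample(10:period_max, 1)
  k <- sample(0:8, 1)
  list(
    days = if (k) sort(sample(0:(period - 1), k, replace = TRUE)) else integer(),
    supply = if (k) sample(c(7L, 14L, 28L, 56L), k, replace = TRUE) else integer(),
    period = period
  )
}

# Event-stream builder for monitor-day tests.
eamd_events_tbl <- function(timestamps, types, voltages = 3900) {
  tibble::tibble(
    participant_id = "P1",
    timestamp = as.POSIXct(timestamps, format = "%Y-%m-%dT%H:%M:%S",
                           tz = "UTC"),
    event_type = types,
    battery_voltage = as.integer(rep_len(voltages, length(timestamps)))
  )
}

# Minimal in-memory cohort for estimator plumbing tests: one participant,
# deterministic streams.
tiny_cohort <- function() {
  epoch <- as.Date("2013-01-01")
  participants <- tibble::tibble(
    participant_id = "P1", sex = "female", age_years = 30,
    baseline_cd4 = 200, baseline_log10_vl = 4.5,
    randomisation_date = epoch, end_of_care_date = as.Date(NA),
    care_status = "in_care"
  )
  hb_days <- 0:111
  hb <- tibble::tibble(
    participant_id = "P1",
    timestamp = as.POSIXct(epoch, tz = "UTC") + hb_days * 86400 + 12 * 3600,
    event_type = "heartbeat", battery_voltage = 3900L
  )
  open_days <- setdiff(0:111, c(10, 20, 30))
  op <- tibble::tibble(
    participant_id = "P1",
    timestamp = as.POSIXct(epoch, tz = "UTC") + open_days * 86400 + 20 * 3600,
    event_type = "opening", battery_voltage = 3900L
  )
  structure(list(
    participants = participants,
    dispensing = tibble::tibble(
      participant_id = "P1", dispense_date = epoch + c(0, 28, 56, 84),
      drug = "efavirenz", days_supplied = 28L),
    eamd_events = dplyr::arrange(dplyr::bind_rows(hb, op), timestamp),
    pill_returns = tibble::tibble(
      participant_id = "P1", count_date = epoch + 112, drug = "efavirenz",
      tablets_dispensed_since_last = 28L, tablets_returned = 3L,
      last_dispense_date = epoch + 84, doses_per_day = 1),
    self_report = tibble::tibble(
      participant_id = "P1", visit_date = epoch + 112,
      took_day1 = TRUE, took_day2 = FALSE, took_day3 = TRUE),
    efv_concentrations = tibble::tibble(
      participant_id = "P1", sample_date = epoch + 112,
      efv_mg_per_l = 2.3, reported_last_dose_time = "20:00"),
    labs = tibble::tibble(
      participant_id = "P1", sample_date = epoch + c(0, 112),
      hiv_rna_copies_per_ml = c(80000, 60), cd4 = c(200, 350)),
    genotypes = tibble::tibble(
      participant_id = character(), sample_date = as.Date(character()),
      mutations = list(), amplified = logical()),
    issues = tibble::tibble(file = character(), row = integer(),
                            problem = character()),
    config = adherekit::default_config()
  ), class = "cohort")
}
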