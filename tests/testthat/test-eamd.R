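d0 <- as.Date("2013-03-10")

test_that("a day is credited by any opening in its 06:00-to-05:59 window", {
  ev <- eamd_events_tbl(
    c("2013-03-10T12:00:00", "2013-03-10T20:15:00",  # heartbeat + evening opening
      "2013-03-11T12:00:00",
      "2013-03-12T04:30:00",                         # late-night opening -> day 11
      "2013-03-12T12:00:00"),
    c("heartbeat", "opening", "heartbeat", "opening", "heartbeat"))
  days <- eamd_day_classification(ev, d0, d0 + 3)
  expect_equal(days$status, c("adherent", "adherent", "nonadherent"))
})

test_that("window boundary is exact: 05:59:59 credits the previous day, 06:00:00 the current", {
  hb <- eamd_events_tbl(
    sprintf("2013-03-%02dT12:00:00", 10:12), rep("heartbeat", 3))
  before <- dplyr::bind_rows(hb, eamd_events_tbl("2013-03-11T05:59:59", "opening"))
  after <- dplyr::bind_rows(hb, eamd_events_tbl("2013-03-11T06:00:00", "opening"))
  expect_equal(eamd_day_classification(before, d0, d0 + 2)$status,
               c("adherent", "nonadherent"))
  expect_equal(eamd_day_classification(after, d0, d0 + 2)$status,
               c("nonadherent", "adherent"))
})

test_that("days without heartbeat or with low battery voltage are censored", {
  ev <- eamd_events_tbl(
    c("2013-03-10T12:00:00", "2013-03-10T20:00:00",
      # no events on 2013-03-11 at all
      "2013-03-12T12:00:00", "2013-03-12T20:00:00"),
    c("heartbeat", "opening", "heartbeat", "opening"),
    voltages = c(3900, 3900, 3500, 3900))  # low heartbeat voltage on day 12
  days <- eamd_day_classification(ev, d0, d0 + 3)
  expect_equal(days$status, c("adherent", "censored", "censored"))
  # raising the threshold config resurrects the low-voltage day
  days2 <- eamd_day_classification(ev, d0, d0 + 3, battery_threshold = 3400)
  expect_equal(days2$status, c("adherent", "censored", "adherent"))
  # an opening alone does not prove the device alive: still censored
  op_only <- eamd_events_tbl("2013-03-10T20:00:00", "opening")
  expect_equal(eamd_day_classification(op_only, d0, d0 + 1)$status, "censored")
})

test_that("an empty event stream censors every day", {
  empty <- eamd_events_tbl(character(), character())
  days <- eamd_day_classification(empty, d0, d0 + 5)
  expect_equal(nrow(days), 5)
  expect_true(all(days$status == "censored"))
})

test_that("shifting all events by 24 hours shifts day labels by exactly one day", {
  set.seed(5)
  n_days <- 20
  hb_ts <- as.POSIXct(d0, tz = "UTC") + (0:(n_days - 1)) * 86400 + 12 * 3600
  open_days <- sort(sample(0:(n_days - 1), 8))
  open_ts <- as.POSIXct(d0, tz = "UTC") + open_days * 86400 + 6 * 3600 +
    round(runif(8, 0, 86399))
  ev <- tibble::tibble(
    participant_id = "P1",
    timestamp = c(hb_ts, open_ts),
    event_type = c(rep("heartbeat", n_days), rep("opening", 8)),
    battery_voltage = 3900L)
  base <- eamd_day_classification(ev, d0, d0 + n_days)
  shifted <- eamd_day_classification(
    dplyr::mutate(ev, timestamp = timestamp + 86400), d0 + 1, d0 + 1 + n_days)
  expect_equal(shifted$status, base$status)
  expect_equal(shifted$day, base$day + 1)
})

test_that("adding an opening event never decreases monitor adherence", {
  set.seed(17)
  n_days <- 30
  hb_ts <- as.POSIXct(d0, tz = "UTC") + (0:(n_days - 1)) * 86400 + 12 * 3600
  ev <- tibble::tibble(participant_id = "P1", timestamp = hb_ts,
                       event_type = "heartbeat", battery_voltage = 3900L)
  for (k in 1:20) {
    ts <- as.POSIXct(d0, tz = "UTC") +
      sample(0:(n_days - 1), 1) * 86400 + round(runif(1, 6, 29.9) * 3600)
    before <- eamd_day_classification(ev, d0, d0 + n_days)
    v1 <- eamd_adherence(sum(before$status == "adherent"),
                         sum(before$status == "censored"), n_days)$value
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      participant_id = "P1", timestamp = ts, event_type = "opening",
      battery_voltage = 3900L)) |> dplyr::arrange(timestamp)
    after <- eamd_day_classification(ev, d0, d0 + n_days)
    v2 <- eamd_adherence(sum(after$status == "adherent"),
                         sum(after$status == "censored"), n_days)$value
    expect_gte(v2, v1)
  }
})
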