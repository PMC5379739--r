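test_that("3-day self-recall maps yes-counts to percent and propagates missing answers", {
  expect_equal(sr_adherence(TRUE, TRUE, TRUE), 100)
  expect_equal(sr_adherence(FALSE, FALSE, FALSE), 0)
  expect_equal(round(sr_adherence(TRUE, FALSE, TRUE), 1), 66.7)
  expect_true(is.na(sr_adherence(TRUE, NA, TRUE)))
})

test_that("clinic pill count divides unreturned tablets by expected doses", {
  d0 <- as.Date("2013-01-01")
  expect_equal(cpc_adherence(30L, 0L, d0 + 30, d0)$value, 100)
  expect_equal(cpc_adherence(60L, 6L, d0 + 60, d0)$value, 90)
  expect_equal(round(cpc_adherence(30L, 0L, d0 + 28, d0)$value, 1), 107.1)
  # twice-daily: 60 tablets over 30 days at 2 doses/day
  expect_equal(cpc_adherence(60L, 0L, d0 + 30, d0, doses_per_day = 2)$value, 100)
  # empty interval -> absent; surplus returns -> flagged but computed
  expect_true(is.na(cpc_adherence(30L, 0L, d0, d0)$value))
  r <- cpc_adherence(30L, 40L, d0 + 30, d0)
  expect_equal(r$flag, "returned_exceeds_dispensed")
  expect_lt(r$value, 0)
})

test_that("pharmacy-refill average is supplied days over days in care and can exceed 100", {
  expect_equal(pr_average_adherence(c(0, 28, 56, 84), rep(28, 4), 112), 100)
  expect_equal(round(pr_average_adherence(c(0, 28, 56, 84), c(28, 28, 28, 36), 112), 1),
               107.1)
  expect_equal(pr_average_adherence(c(0, 28, 56), rep(28, 3), 112), 75)
  # dispensings outside [0, days_in_care) do not count
  expect_equal(pr_average_adherence(c(-5, 0, 120), rep(28, 3), 112), 25)
  expect_true(is.na(pr_average_adherence(numeric(), numeric(), 112)))
  expect_true(is.na(pr_average_adherence(0, 28, 0)))
})

test_that("stock ledger counts medication-free days with uncapped carryover", {
  expect_equal(build_stock_ledger(0, 28, 28)$medication_free_days, 0L)
  # late refill: days 28..34 uncovered
  late <- build_stock_ledger(c(0, 35), c(28, 28), 56)
  expect_equal(late$medication_free_days, 7L)
  # early refill (day 23, 5 days before exhaustion): carryover absorbs it,
  # so no free days; 56 days of supply are exactly consumed by day 56
  early <- build_stock_ledger(c(0, 23), c(28, 28), 56)
  expect_equal(early$medication_free_days,
               oracle_free_days(c(0, 23), c(28, 28), 56))
  expect_equal(early$medication_free_days, 0L)
  expect_equal(early$stock[56], 0L)
  # the same early refill over a 51-day period leaves 5 days of surplus
  short <- build_stock_ledger(c(0, 23), c(28, 28), 51)
  expect_equal(short$medication_free_days, 0L)
  expect_equal(short$stock[51], 5L)
  expect_equal(build_stock_ledger(integer(), integer(), 30)$medication_free_days,
               30L)
})

test_that("gaps adherence is bounded in [0, 100]", {
  expect_equal(pr_gaps_adherence(0, 112), 100)
  expect_equal(pr_gaps_adherence(112, 112), 0)
  expect_equal(pr_gaps_adherence(7, 140), 95)
  expect_true(is.na(pr_gaps_adherence(0, 0)))
})

test_that("average and gaps methods agree when refills are never early and never oversupply", {
  set.seed(42)
  for (rep in 1:50) {
    period <- sample(60:200, 1)
    # refills arrive exactly at (or after) stock exhaustion; last one trimmed
    days <- 0
    supply <- integer()
    while (TRUE) {
      s <- sample(c(14L, 28L), 1)
      last <- days[length(days)]
      if (last + s >= period) {
        supply <- c(supply, period - last - sample(0:5, 1))
        break
      }
      supply <- c(supply, s)
      days <- c(days, last + s + sample(0:6, 1))
    }
    supply[length(supply)] <- max(supply[length(supply)], 1L)
    days <- days[seq_along(supply)]
    led <- build_stock_ledger(days, supply, period)
    expect_equal(pr_average_adherence(days, supply, period),
                 pr_gaps_adherence(led$medication_free_days, period))
  }
})

test_that("adding a dispensing never decreases either pharmacy-refill measure", {
  set.seed(99)
  for (rep in 1:100) {
    sc <- random_schedule(200)
    extra_day <- sample(0:(sc$period - 1), 1)
    days2 <- c(sc$days, extra_day)
    supply2 <- c(sc$supply, 28L)
    if (length(sc$days)) {
      a1 <- pr_average_adherence(sc$days, sc$supply, sc$period)
      a2 <- pr_average_adherence(days2, supply2, sc$period)
      expect_gte(a2, a1)
    }
    g1 <- pr_gaps_adherence(
      build_stock_ledger(sc$days, sc$supply, sc$period)$medication_free_days,
      sc$period)
    g2 <- pr_gaps_adherence(
      build_stock_ledger(days2, supply2, sc$period)$medication_free_days,
      sc$period)
    expect_gte(g2, g1)
  }
})

test_that("monitor adherence removes censored days from the denominator", {
  r <- eamd_adherence(100, 0, 112)
  expect_equal(round(r$value, 1), 89.3)
  expect_equal(eamd_adherence(50, 12, 112)$value, 50)
  expect_equal(eamd_adherence(112, 0, 112)$value, 100)
  all_cens <- eamd_adherence(0, 112, 112)
  expect_true(is.na(all_cens$value))
  expect_equal(all_cens$censored_fraction, 1)
  # full-denominator variant is recoverable
  expect_equal(eamd_adherence(50, 12, 112)$value_full_denominator,
               100 * 50 / 112)
})

test_that("efavirenz features log-transform with a detection floor and flag the 1-4 mg/L range", {
  f <- tdm_features(c(2.3, 1.0, 0.5, 0, 4.0, 4.5))
  expect_equal(round(f$log10_value[1], 4), 0.3617)
  expect_equal(f$log10_value[2], 0)
  expect_equal(f$therapeutic_flag, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(f$log10_value[4], log10(0.05))
  expect_equal(tdm_features(0, floor_mg_per_l = 0.1)$log10_value, -1)
  expect_error(tdm_features(-1), "negative")
})
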