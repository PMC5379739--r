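#' Three-day self-recall adherence
#'
#' Percentage of the last three days on which the participant reports having
#' swallowed their pills ("Did you swallow your pills yesterday / 2 days ago
#' / 3 days ago?"). A "yes" day counts as fully dosed, so once-daily and
#' twice-daily regimens are treated identically at per-day granularity.
#' Vectorised; any missing answer yields `NA` (estimate absent, not zero).
#'
#' @param took_day1,took_day2,took_day3 logical answers for yesterday, two
#'   and three days ago.
#' @return percent in `{0, 100/3, 200/3, 100}` (full precision; round only
#'   for presentation).
#' @export
sr_adherence <- function(took_day1, took_day2, took_day3) {
  out <- 100 * (took_day1 + took_day2 + took_day3) / 3
  out[is.na(took_day1) | is.na(took_day2) | is.na(took_day3)] <- NA_real_
  out
}

#' Clinic-based pill-count adherence
#'
#' Tablets dispensed minus tablets returned, divided by the expected number
#' of doses over the interval between the last dispensing date and the count
#' date. Only the anchor drug's tablets are counted by the caller. The value
#' can exceed 100% (extra tablets unaccounted for) and is flagged when more
#' tablets come back than went out (undisclosed stock at home).
#'
#' @param tablets_dispensed_since_last,tablets_returned integer counts.
#' @param count_date,last_dispense_date `Date`s; the interval is the integer
#'   day difference (half-open convention).
#' @param doses_per_day dosing frequency (default 1).
#' @return tibble with `value` (percent, `NA` when the interval is empty) and
#'   `flag` (`"returned_exceeds_dispensed"` or `NA`).
#' @export
cpc_adherence <- function(tablets_dispensed_since_last, tablets_returned,
                          count_date, last_dispense_date, doses_per_day = 1) {
  days_between <- as.integer(count_date - last_dispense_date)
  value <- 100 * (tablets_dispensed_since_last - tablets_returned) /
    (days_between * doses_per_day)
  value[days_between <= 0] <- NA_real_
  flag <- ifelse(tablets_returned > tablets_dispensed_since_last,
                 "returned_exceeds_dispensed", NA_character_)
  tibble::tibble(value = value, denominator_days = days_between, flag = flag)
}

#' Pharmacy-refill average adherence
#'
#' Days of anchor-drug supply dispensed between randomisation and the
#' landmark viral-load date, divided by the days in care over the same
#' period. Early refills accumulate supply, so the value may exceed 100%.
#'
#' @param dispense_days integer day offsets (days since randomisation) of the
#'   anchor-drug dispensings; only offsets in `[0, days_in_care)` count.
#' @param days_supplied days of supply per dispensing.
#' @param days_in_care integer length of the adherence period.
#' @return percent, or `NA` when there is no in-period dispensing or no time
#'   in care.
#' @export
pr_average_adherence <- function(dispense_days, days_supplied, days_in_care) {
  if (is.na(days_in_care) || days_in_care <= 0) return(NA_real_)
  keep <- dispense_days >= 0 & dispense_days < days_in_care
  if (!any(keep)) return(NA_real_)
  100 * sum(days_supplied[keep]) / days_in_care
}

#' Daily medication stock ledger
#'
#' Day-by-day possession model behind the pharmacy-refill gaps method: on
#' each dispensing day the days of supply are added to the stock on hand;
#' every day one day of supply is consumed if any stock is available,
#' otherwise the day is a medication-free day (the participant could not
#' have had medication in hand). Surplus from early refills carries forward
#' without cap.
#'
#' @inheritParams pr_average_adherence
#' @return list with `stock` (integer stock on hand at the end of each day of
#'   the period) and `medication_free_days`.
#' @export
build_stock_ledger <- function(dispense_days, days_supplied, days_in_care) {
  stopifnot(days_in_care >= 0)
  supply <- integer(days_in_care)
  keep <- dispense_days >= 0 & dispense_days < days_in_care
  for (i in which(keep)) {
    d <- dispense_days[i] + 1L
    supply[d] <- supply[d] + as.integer(days_supplied[i])
  }
  stock <- integer(days_in_care)
  free <- 0L
  s <- 0L
  for (d in seq_len(days_in_care)) {
    s <- s + supply[d]
    if (s > 0L) s <- s - 1L else free <- free + 1L
    stock[d] <- s
  }
  list(stock = stock, medication_free_days = free)
}

#' Pharmacy-refill gaps adherence
#'
#' Medication-free days are subtracted from the days in the period and the
#' result divided by the days in the period. Bounded in `[0, 100]`.
#'
#' @param medication_free_days integer count from [build_stock_ledger()].
#' @param period_days length of the adherence period in days.
#' @return percent, `NA` for an empty period.
#' @export
pr_gaps_adherence <- function(medication_free_days, period_days) {
  ifelse(period_days > 0,
         100 * (period_days - medication_free_days) / period_days,
         NA_real_)
}

#' Classify electronic-monitor days
#'
#' A monitor day runs from 06:00 local time to 05:59 the next morning, so a
#' late-night opening at 03:00 credits the previous calendar day. A day with
#' no heartbeat event in its window, or whose minimum reported battery
#' voltage falls below `battery_threshold`, is censored as a dead-battery
#' day; otherwise it is adherent if at least one opening falls in the window
#' and non-adherent if none does.
#'
#' @param events tibble with `timestamp` (POSIXct, local clock),
#'   `event_type` (`"opening"`/`"heartbeat"`) and `battery_voltage` for one
#'   participant.
#' @param start_date first monitor day (`Date`); `end_date` exclusive.
#' @param battery_threshold device-unit voltage floor (default 3660).
#' @return tibble with one row per day in `[start_date, end_date)`: `day` and
#'   `status` in `{"adherent", "nonadherent", "censored"}`.
#' @export
eamd_day_classification <- function(events, start_date, end_date,
                                    battery_threshold = 3660) {
  days <- seq(start_date, end_date - 1L, by = "day")
  if (nrow(events) == 0) {
    return(tibble::tibble(day = days, status = "censored"))
  }
  ev <- events |>
    mutate(day = as.Date(floor(
      (as.numeric(.data$timestamp) - 6 * 3600) / 86400
    ), origin = "1970-01-01"))
  per_day <- ev |>
    group_by(.data$day) |>
    summarise(has_heartbeat = any(.data$event_type == "heartbeat"),
              has_opening = any(.data$event_type == "opening"),
              min_voltage = min(.data$battery_voltage),
              .groups = "drop")
  tibble::tibble(day = days) |>
    left_join(per_day, by = "day") |>
    mutate(status = dplyr::case_when(
      is.na(.data$has_heartbeat) | !.data$has_heartbeat ~ "censored",
      .data$min_voltage < battery_threshold ~ "censored",
      .data$has_opening ~ "adherent",
      TRUE ~ "nonadherent"
    )) |>
    select("day", "status")
}

#' Cumulative electronic-monitor adherence
#'
#' Adherent days divided by days in care, with censored (dead-battery) days
#' removed from the denominator so that a dead battery does not masquerade as
#' non-adherence. The full-denominator variant (censored days counted as
#' non-adherent) is reported alongside so the alternative reading is
#' recoverable.
#'
#' @param adherent_days,censored_days,days_in_care integer counts; the day
#'   classification must cover the full period of care.
#' @return tibble with `value` (percent, `NA` when every day is censored),
#'   `value_full_denominator`, `censored_days` and `censored_fraction`.
#' @export
eamd_adherence <- function(adherent_days, censored_days, days_in_care) {
  denom <- days_in_care - censored_days
  tibble::tibble(
    value = ifelse(denom > 0, 100 * adherent_days / denom, NA_real_),
    value_full_denominator = ifelse(days_in_care > 0,
                                    100 * adherent_days / days_in_care,
                                    NA_real_),
    censored_days = censored_days,
    censored_fraction = ifelse(days_in_care > 0,
                               censored_days / days_in_care, NA_real_)
  )
}

#' Efavirenz therapeutic-drug-monitoring features
#'
#' Mid-dose efavirenz concentration features for the models: the raw value in
#' mg/L, its log10 (undetectable/zero values floored first, since log10(0) is
#' undefined), and a therapeutic-range flag for the inclusive 1-4 mg/L range.
#'
#' @param efv_mg_per_l non-negative concentrations (mg/L).
#' @param floor_mg_per_l detection floor applied before the log transform.
#' @return tibble with `raw_mg_per_l`, `log10_value`, `therapeutic_flag`.
#' @export
tdm_features <- function(efv_mg_per_l, floor_mg_per_l = 0.05) {
  if (any(efv_mg_per_l < 0, na.rm = TRUE)) {
    stop("negative efavirenz concentration")
  }
  tibble::tibble(
    raw_mg_per_l = efv_mg_per_l,
    log10_value = log10(pmax(efv_mg_per_l, floor_mg_per_l)),
    therapeutic_flag = efv_mg_per_l >= 1 & efv_mg_per_l <= 4
  )
}
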