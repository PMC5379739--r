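# Picks, per participant, the record of a visit-based stream (self-report,
# pill count, TDM) closest to the nominal landmark day within the landmark
# window; ties go to the earlier date.
pick_landmark_record <- function(tbl, date_col, sel, win) {
  tbl |>
    inner_join(sel |> select("participant_id", "randomisation_date"),
               by = "participant_id") |>
    mutate(day = as.integer(.data[[date_col]] - .data$randomisation_date)) |>
    filter(.data$day >= win$lo, .data$day <= win$hi) |>
    group_by(.data$participant_id) |>
    arrange(abs(.data$day - win$nominal), .data$day, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
}

#' Compute all six adherence estimates at a landmark
#'
#' Per-protocol evaluation: only participants with an HIV-RNA inside the
#' landmark window contribute. Cumulative measures (pharmacy-refill average
#' and gaps, electronic monitoring) are evaluated over
#' `[randomisation, viral-load date)`; the clinic pill count covers the
#' interval since the most recent dispensing before the count; self-report
#' and efavirenz concentration come from the landmark study visit when
#' attended. Missing streams yield absent estimates for that method only.
#'
#' @param cohort a validated cohort bundle from [read_cohort()] or
#'   [simulate_cohort()].
#' @param landmark `"week16"` or `"week48"`.
#' @param config see [default_config()].
#' @return tibble of adherence estimates: `participant_id`, `method`
#'   (`SR`, `CPC`, `PR_AVERAGE`, `PR_GAPS`, `EAMD`, `TDM`), `landmark`,
#'   `value` (percent; raw mg/L for TDM), `log10_value` (TDM only),
#'   `therapeutic` (TDM only), `window_start`, `window_end`,
#'   `denominator_days`, `censored_days` (EAMD only) and `flag`.
#' @export
compute_adherence <- function(cohort, landmark, config = cohort$config %||% default_config()) {
  win <- landmark_window(landmark, config)
  sel <- select_landmark_vl(cohort$labs, cohort$participants, landmark, config)
  if (nrow(sel) == 0) return(empty_estimates())

  anchor <- cohort$dispensing |>
    filter(.data$drug %in% config$anchor_drugs) |>
    inner_join(sel |> select("participant_id", "randomisation_date",
                             "days_in_care"),
               by = "participant_id") |>
    mutate(day = as.integer(.data$dispense_date - .data$randomisation_date))
  disp_split <- split(anchor, anchor$participant_id)
  ev_split <- split(cohort$eamd_events, cohort$eamd_events$participant_id)

  cumulative <- purrr::pmap_dfr(
    sel |> select("participant_id", "randomisation_date", "days_in_care"),
    function(participant_id, randomisation_date, days_in_care) {
      out <- list()
      win_start <- randomisation_date
      win_end <- randomisation_date + days_in_care
      dd <- disp_split[[participant_id]]
      if (!is.null(dd) && nrow(dd) > 0 && days_in_care > 0) {
        pra <- pr_average_adherence(dd$day, dd$days_supplied, days_in_care)
        if (!is.na(pra)) {
          out$pra <- tibble::tibble(
            participant_id = participant_id, method = "PR_AVERAGE",
            value = pra, window_start = win_start, window_end = win_end,
            denominator_days = days_in_care)
        }
        ledger <- build_stock_ledger(dd$day, dd$days_supplied, days_in_care)
        out$prg <- tibble::tibble(
          participant_id = participant_id, method = "PR_GAPS",
          value = pr_gaps_adherence(ledger$medication_free_days, days_in_care),
          window_start = win_start, window_end = win_end,
          denominator_days = days_in_care)
      }
      ev <- ev_split[[participant_id]]
      if (!is.null(ev) && nrow(ev) > 0 && days_in_care > 0) {
        days <- eamd_day_classification(ev, win_start, win_end,
                                        config$battery_threshold)
        ea <- eamd_adherence(sum(days$status == "adherent"),
                             sum(days$status == "censored"), days_in_care)
        out$eamd <- tibble::tibble(
          participant_id = participant_id, method = "EAMD",
          value = ea$value, window_start = win_start, window_end = win_end,
          denominator_days = days_in_care - ea$censored_days,
          censored_days = ea$censored_days,
          flag = ifelse(is.na(ea$value), "all_days_censored", NA_character_))
      }
      bind_rows(out)
    })

  sr_rec <- pick_landmark_record(cohort$self_report, "visit_date", sel, win)
  sr_est <- if (nrow(sr_rec)) {
    sr_rec |>
      transmute(.data$participant_id, method = "SR",
                value = sr_adherence(.data$took_day1, .data$took_day2,
                                     .data$took_day3),
                window_start = .data$visit_date - 3L,
                window_end = .data$visit_date,
                denominator_days = 3L) |>
      filter(!is.na(.data$value))
  } else empty_estimates()

  cpc_rec <- pick_landmark_record(cohort$pill_returns, "count_date", sel, win) |>
    filter(.data$drug %in% config$anchor_drugs)
  cpc_est <- if (nrow(cpc_rec)) {
    vals <- cpc_adherence(cpc_rec$tablets_dispensed_since_last,
                          cpc_rec$tablets_returned, cpc_rec$count_date,
                          cpc_rec$last_dispense_date, cpc_rec$doses_per_day)
    cpc_rec |>
      transmute(.data$participant_id, method = "CPC", value = vals$value,
                window_start = .data$last_dispense_date,
                window_end = .data$count_date,
                denominator_days = vals$denominator_days,
                flag = vals$flag) |>
      filter(!is.na(.data$value))
  } else empty_estimates()

  tdm_rec <- pick_landmark_record(cohort$efv_concentrations, "sample_date",
                                  sel, win)
  tdm_est <- if (nrow(tdm_rec)) {
    feats <- tdm_features(tdm_rec$efv_mg_per_l, config$efv_log_floor_mg_per_l)
    tdm_rec |>
      transmute(.data$participant_id, method = "TDM",
                value = feats$raw_mg_per_l, log10_value = feats$log10_value,
                therapeutic = feats$therapeutic_flag,
                window_start = .data$sample_date,
                window_end = .data$sample_date + 1L,
                denominator_days = 1L)
  } else empty_estimates()

  bind_rows(cumulative, sr_est, cpc_est, tdm_est) |>
    mutate(landmark = landmark) |>
    relocate("participant_id", "method", "landmark", "value") |>
    arrange(.data$participant_id, factor(.data$method, adherence_methods))
}

empty_estimates <- function() {
  tibble::tibble(participant_id = character(), method = character(),
                 landmark = character(), value = numeric())
}
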