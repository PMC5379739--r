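#' Default synthetic-cohort generator settings
#'
#' The generator emulates the measurement processes of a prospective
#' ART-naive adherence cohort: latent adherence classes following a
#' two-state (dosing/gap) daily Markov chain so that missed days cluster
#' into gaps; a standard-of-care dispensing schedule (visits at days 0, 28,
#' 56, 84, then every 56 days) with refill jitter and class-dependent missed
#' visits; electronic-monitor under-capture through pocket dosing and
#' dead-battery censoring episodes calibrated to about 10% of days;
#' optimistically biased 3-day self-report; partial pill dumping inflating
#' clinic pill counts; a simple log-linear efavirenz concentration model
#' driven by recent dosing with between-subject variability and white-coat
#' dosing on the visit eve; and logistic virological failure / resistance
#' outcomes driven by cumulative true adherence with prespecified baseline
#' covariate effects.
#'
#' @param ... named overrides merged over the defaults (top-level entries).
#' @return nested settings list.
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    n_participants = 230L,
    follow_up_days = 336L,
    adherence_mix = list(
      p_class = c(high = 0.50, medium = 0.30, low = 0.20),
      stay_dosing = c(high = 0.99, medium = 0.97, low = 0.93),
      stay_gap = c(high = 0.65, medium = 0.85, low = 0.93)
    ),
    dispensing = list(
      early_visit_days = c(0L, 28L, 56L, 84L),
      later_interval = 56L,
      supply_early = 28L,  # visits at days 0/28/56
      supply_later = 56L,  # day 84 onwards (next visit 56 days away)
      jitter_sd = 1.5,
      miss_prob = c(high = 0.03, medium = 0.08, low = 0.20)
    ),
    measurement = list(
      p_pocket_dose = 0.08,
      dead_battery_start = 0.0111,  # alive -> dead per day
      dead_battery_recover = 0.10,  # dead -> alive per day (mean episode 10 d)
      sr_yes_bias = 0.85,           # P(report "yes" | dose missed)
      pill_dump_prob = 0.25,        # participant dumps part of the leftovers
      pill_dump_range = c(0.05, 0.30),
      study_visit_attend = 0.85,
      folder_vl_prob = 0.40,        # VL from clinic folder when visit missed
      battery_voltage_mean = 3950, battery_voltage_sd = 60,
      efv = list(log_conc_full = log(2.2), slope_per_dose = 0.4,
                 bsv_sd = 0.35, residual_sd = 0.25, white_coat_prob = 0.5)
    ),
    outcome = list(
      beta0 = 1.0,
      beta_adherence_per_10pct = log(0.70),
      beta_age = -0.01,        # per year, centred at 35
      beta_cd4_per_100 = -0.25,  # per 100 cells, centred at 225
      beta_logvl = 0.25,       # per log10, centred at 4.9
      resistance_b0 = 3.0, resistance_slope = -0.03,  # vs adherence %
      amplify_prob = 0.88
    ),
    attrition = c(in_care = 0.808, transferred = 0.070, died = 0.035,
                  ltfu = 0.083, withdrew = 0.004),
    baseline = list(age_mean = 34.5, age_sd = 9.1,
                    cd4_meanlog = log(225), cd4_sdlog = 0.55,
                    logvl_mean = 4.9, logvl_sd = 0.7, p_female = 0.652)
  )
  overrides <- list(...)
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(names(overrides) %in% names(cfg)))
    cfg <- utils::modifyList(cfg, overrides)
  }
  stopifnot(abs(sum(cfg$adherence_mix$p_class) - 1) < 1e-8,
            abs(sum(cfg$attrition) - 1) < 1e-8)
  cfg
}

#' Stationary dosing probability of the two-state daily chain
#'
#' Closed form for the long-run fraction of dosing days of a chain with
#' persistence `stay_dosing` in the dosing state and `stay_gap` in the gap
#' state.
#'
#' @param stay_dosing,stay_gap per-day self-transition probabilities.
#' @return stationary probability of the dosing state.
#' @export
markov_stationary_adherence <- function(stay_dosing, stay_gap) {
  (1 - stay_gap) / ((1 - stay_dosing) + (1 - stay_gap))
}

# Simulates an n x T 0/1 matrix from per-row two-state chains.
simulate_two_state <- function(n, T, p_start, p_stay1, p_stay0) {
  M <- matrix(0L, n, T)
  M[, 1] <- rbinom(n, 1, p_start)
  for (t in 2:T) {
    p <- ifelse(M[, t - 1] == 1L, p_stay1, 1 - p_stay0)
    M[, t] <- rbinom(n, 1, p)
  }
  M
}

#' Simulate a synthetic adherence cohort
#'
#' Generates ground-truth daily dosing plus every measured stream in the
#' cohort CSV normal form, deterministically for a given seed. The returned
#' bundle is a `cohort` (directly usable by [compute_adherence()] and
#' [derive_outcomes()]) that additionally carries `truth` (per-day dosing
#' ground truth) and `internal` day-level matrices for oracle checks.
#'
#' @param config generator settings, see [default_sim_config()].
#' @param seed integer RNG seed.
#' @param include_events generate the event-level electronic-monitor stream
#'   (openings/heartbeats with battery voltages). Disable for
#'   replication-heavy studies that only need day-level summaries.
#' @param analysis_config the analysis configuration attached to the bundle.
#' @return a `cohort` bundle with elements as in [read_cohort()], plus
#'   `truth`, `truth_summary` and `internal`.
#' @export
simulate_cohort <- function(config = default_sim_config(), seed = 1,
                            include_events = TRUE,
                            analysis_config = default_config()) {
  set.seed(seed)
  n <- config$n_participants
  T <- config$follow_up_days
  mix <- config$adherence_mix
  meas <- config$measurement

  ids <- sprintf("P%04d", seq_len(n))
  cls <- sample(names(mix$p_class), n, replace = TRUE, prob = mix$p_class)
  epoch <- as.Date("2012-07-12")
  rand_date <- epoch + sample(0:270, n, replace = TRUE)

  # ground-truth daily dosing
  pi1 <- markov_stationary_adherence(mix$stay_dosing[cls], mix$stay_gap[cls])
  dose <- simulate_two_state(n, T, pi1, mix$stay_dosing[cls], mix$stay_gap[cls])

  # attrition
  status <- sample(names(config$attrition), n, replace = TRUE,
                   prob = config$attrition)
  end_day <- ifelse(status == "in_care", NA_integer_,
                    sample(28:T, n, replace = TRUE))
  in_care_until <- ifelse(is.na(end_day), T, end_day)

  # baseline covariates
  bl <- config$baseline
  age <- pmax(16, rnorm(n, bl$age_mean, bl$age_sd))
  cd4 <- round(stats::rlnorm(n, bl$cd4_meanlog, bl$cd4_sdlog))
  logvl <- rnorm(n, bl$logvl_mean, bl$logvl_sd)
  sex <- ifelse(runif(n) < bl$p_female, "female", "male")

  participants <- tibble::tibble(
    participant_id = ids, sex = sex, age_years = round(age, 1),
    baseline_cd4 = cd4, baseline_log10_vl = round(logvl, 2),
    randomisation_date = rand_date,
    end_of_care_date = rand_date + ifelse(is.na(end_day), NA_integer_, end_day),
    care_status = status
  )

  # dead-battery episodes and monitor capture
  dead <- simulate_two_state(n, T, 0,
                             1 - meas$dead_battery_recover,
                             1 - meas$dead_battery_start)
  pocket <- matrix(rbinom(n * T, 1, meas$p_pocket_dose), n, T)
  monitored_open <- dose == 1L & pocket == 0L & dead == 0L

  # dispensing schedule
  dsp <- config$dispensing
  visit_days <- c(dsp$early_visit_days,
                  seq(max(dsp$early_visit_days) + dsp$later_interval, T - 1L,
                      by = dsp$later_interval))
  supply <- ifelse(visit_days < max(dsp$early_visit_days),
                   dsp$supply_early, dsp$supply_later)
  nv <- length(visit_days)
  grid <- tibble::tibble(
    i = rep(seq_len(n), each = nv),
    sched = rep(visit_days, n),
    days_supplied = rep(supply, n)
  ) |>
    mutate(
      attended = .data$sched == 0L |
        runif(dplyr::n()) >= dsp$miss_prob[cls[.data$i]],
      day = ifelse(.data$sched == 0L, 0L,
                   pmax(1L, .data$sched + round(rnorm(dplyr::n(), 0, dsp$jitter_sd))))
    ) |>
    filter(.data$attended, .data$day < in_care_until[.data$i])
  dispensing <- tibble::tibble(
    participant_id = ids[grid$i],
    dispense_date = rand_date[grid$i] + grid$day,
    drug = "efavirenz",
    days_supplied = as.integer(grid$days_supplied)
  ) |> distinct(.data$participant_id, .data$dispense_date, .data$drug,
                .data$days_supplied)

  # study visits (week 16 / 48) and lab draws
  nominal <- c(week16 = 112L, week48 = 336L)
  visit_tbl <- tidyr::expand_grid(i = seq_len(n), landmark = names(nominal)) |>
    mutate(
      nominal_day = unname(nominal[.data$landmark]),
      lab_day = pmin(pmax(.data$nominal_day +
                            round(rnorm(dplyr::n(), 0, 3)), 1L), T),
      in_care = .data$lab_day <= in_care_until[.data$i],
      attended = .data$in_care & runif(dplyr::n()) < meas$study_visit_attend,
      vl_present = .data$attended |
        (.data$in_care & runif(dplyr::n()) < meas$folder_vl_prob)
    )

  # outcomes: logistic in cumulative true adherence at the lab date
  oc <- config$outcome
  lab_rows <- visit_tbl |> filter(.data$vl_present)
  lab_adh <- vapply(seq_len(nrow(lab_rows)), function(k) {
    100 * mean(dose[lab_rows$i[k], seq_len(lab_rows$lab_day[k])])
  }, numeric(1))
  lp <- oc$beta0 + oc$beta_adherence_per_10pct * lab_adh / 10 +
    oc$beta_age * (age[lab_rows$i] - 35) +
    oc$beta_cd4_per_100 * (cd4[lab_rows$i] - 225) / 100 +
    oc$beta_logvl * (logvl[lab_rows$i] - 4.9)
  failed <- runif(nrow(lab_rows)) < plogis(lp)
  vl <- ifelse(lab_rows$landmark == "week16",
               ifelse(failed, 10^runif(nrow(lab_rows), 2.8, 5.2), 25),
               ifelse(failed, 10^runif(nrow(lab_rows), 1.7, 5.2), 20))
  labs <- tibble::tibble(
    participant_id = c(ids, ids[lab_rows$i]),
    sample_date = c(rand_date, rand_date[lab_rows$i] + lab_rows$lab_day),
    hiv_rna_copies_per_ml = c(round(10^logvl), round(vl)),
    cd4 = c(cd4, pmax(0, round(cd4[lab_rows$i] + rnorm(nrow(lab_rows), 120, 80))))
  ) |> arrange(.data$participant_id, .data$sample_date)

  # genotypes on amplifiable failures
  gt_rows <- which(failed & vl > 500)
  gt <- purrr::map_dfr(gt_rows, function(k) {
    amplified <- runif(1) < oc$amplify_prob
    muts <- character()
    if (amplified) {
      resistant <- runif(1) < plogis(oc$resistance_b0 +
                                       oc$resistance_slope * lab_adh[k])
      if (resistant) {
        muts <- c(sample(c("K103N", "V106M", "Y181C", "G190A"), 1),
                  if (runif(1) < 0.35) "K65R",
                  if (runif(1) < 0.35) "M184V")
      } else if (runif(1) < 0.5) {
        muts <- "V90I"  # minor/other mutation, not in the major table
      }
    }
    tibble::tibble(participant_id = ids[lab_rows$i[k]],
                   sample_date = rand_date[lab_rows$i[k]] +
                     lab_rows$lab_day[k] + 14L,
                   mutations = list(sort(muts)), amplified = amplified)
  })
  if (nrow(gt) == 0) {
    gt <- tibble::tibble(participant_id = character(),
                         sample_date = as.Date(character()),
                         mutations = list(), amplified = logical())
  }

  # cumulative doses per participant: dose_csum[i, d + 1] = doses in days
  # [0, d), so doses over columns (a, b] are dose_csum[, b + 1] - dose_csum[, a + 1]
  dose_csum <- cbind(0L, t(apply(dose, 1, cumsum)))

  # 3-day self-report (attended study visits only); a missed dose is still
  # reported as taken with probability sr_yes_bias
  sr_rows <- visit_tbl |> filter(.data$attended)
  nsr <- nrow(sr_rows)
  sr_day <- function(back) {
    col <- sr_rows$lab_day - back + 1L  # matrix column of "back days ago"
    taken <- col >= 1 & dose[cbind(sr_rows$i, pmax(col, 1L))] == 1L
    taken | runif(nsr) < meas$sr_yes_bias
  }
  self_report <- tibble::tibble(
    participant_id = ids[sr_rows$i],
    visit_date = rand_date[sr_rows$i] + sr_rows$lab_day,
    took_day1 = sr_day(1), took_day2 = sr_day(2), took_day3 = sr_day(3)
  )

  # clinic pill count at attended study visits: returned tablets are the
  # untaken leftovers from the latest dispensing, minus any dumped fraction
  dump_frac <- ifelse(runif(n) < meas$pill_dump_prob,
                      runif(n, meas$pill_dump_range[1], meas$pill_dump_range[2]),
                      0)
  last_disp <- grid |>
    inner_join(sr_rows |> select("i", vday = "lab_day"), by = "i",
               relationship = "many-to-many") |>
    filter(.data$day < .data$vday) |>
    group_by(.data$i, .data$vday) |>
    slice_max(.data$day, n = 1, with_ties = FALSE) |>
    ungroup()
  taken_int <- dose_csum[cbind(last_disp$i, last_disp$vday + 1L)] -
    dose_csum[cbind(last_disp$i, last_disp$day + 1L)]
  leftover <- pmax(0L, last_disp$days_supplied - taken_int)
  pr_list <- tibble::tibble(
    participant_id = ids[last_disp$i],
    count_date = rand_date[last_disp$i] + last_disp$vday,
    drug = "efavirenz",
    tablets_dispensed_since_last = as.integer(last_disp$days_supplied),
    tablets_returned = as.integer(round(leftover * (1 - dump_frac[last_disp$i]))),
    last_dispense_date = rand_date[last_disp$i] + last_disp$day,
    doses_per_day = 1
  ) |> arrange(.data$participant_id, .data$count_date)

  # efavirenz mid-dose concentrations at attended study visits, driven by
  # dosing over the last three days; white-coat dosing can add the visit-eve
  # dose to the measured exposure without touching the truth
  efv <- meas$efv
  re <- rnorm(n, 0, efv$bsv_sd)
  d3 <- dose_csum[cbind(sr_rows$i, sr_rows$lab_day + 1L)] -
    dose_csum[cbind(sr_rows$i, pmax(sr_rows$lab_day - 3L, 0L) + 1L)]
  eve_missed <- dose[cbind(sr_rows$i, sr_rows$lab_day)] == 0L
  d3 <- d3 + (eve_missed & runif(nsr) < efv$white_coat_prob)
  efv_concentrations <- tibble::tibble(
    participant_id = ids[sr_rows$i],
    sample_date = rand_date[sr_rows$i] + sr_rows$lab_day,
    efv_mg_per_l = round(exp(efv$log_conc_full +
                               efv$slope_per_dose * (d3 - 3) +
                               re[sr_rows$i] +
                               rnorm(nsr, 0, efv$residual_sd)), 2),
    reported_last_dose_time = "20:00"
  )

  # event-level monitor stream
  eamd_events <- if (include_events) {
    hb <- which(dead == 0L, arr.ind = TRUE)
    hb <- hb[hb[, 2] <= in_care_until[hb[, 1]], , drop = FALSE]
    op <- which(monitored_open, arr.ind = TRUE)
    op <- op[op[, 2] <= in_care_until[op[, 1]], , drop = FALSE]
    open_offset <- pmin(pmax(rnorm(nrow(op), 13, 1.5), 0.5), 23.5)
    ev <- tibble::tibble(
      participant_id = c(ids[hb[, 1]], ids[op[, 1]]),
      timestamp = c(
        as.POSIXct(rand_date[hb[, 1]], tz = "UTC") + (hb[, 2] - 1) * 86400 +
          12 * 3600,
        as.POSIXct(rand_date[op[, 1]], tz = "UTC") + (op[, 2] - 1) * 86400 +
          6 * 3600 + round(open_offset * 3600)
      ),
      event_type = c(rep("heartbeat", nrow(hb)), rep("opening", nrow(op))),
      battery_voltage = as.integer(round(rnorm(nrow(hb) + nrow(op),
                                               meas$battery_voltage_mean,
                                               meas$battery_voltage_sd)))
    ) |> arrange(.data$participant_id, .data$timestamp)
    ev
  } else {
    tibble::tibble(participant_id = character(),
                   timestamp = as.POSIXct(character(), tz = "UTC"),
                   event_type = character(), battery_voltage = integer())
  }

  truth <- tibble::tibble(
    participant_id = rep(ids, each = T),
    day = rep(seq_len(T) - 1L, n),
    dose_taken = as.integer(t(dose))
  )
  truth_summary <- tibble::tibble(
    participant_id = ids, latent_class = cls,
    days_in_care = as.integer(in_care_until),
    true_cumulative_adherence = vapply(seq_len(n), function(i) {
      100 * mean(dose[i, seq_len(in_care_until[i])])
    }, numeric(1))
  )

  structure(
    list(participants = participants, dispensing = dispensing,
         eamd_events = eamd_events, pill_returns = pr_list,
         self_report = self_report, efv_concentrations = efv_concentrations,
         labs = labs, genotypes = gt,
         truth = truth, truth_summary = truth_summary,
         internal = list(dose = dose, dead = dead,
                         monitored_open = monitored_open, class = cls,
                         in_care_until = in_care_until, ids = ids,
                         rand_date = rand_date, visit_grid = grid,
                         seed = seed, sim_config = config),
         issues = tibble::tibble(file = character(), row = integer(),
                                 problem = character()),
         config = analysis_config),
    class = c("sim_cohort", "cohort")
  )
}

#' Ground-truth cumulative adherence over a window
#'
#' @param truth per-day truth table (`participant_id`, `day`, `dose_taken`).
#' @param upto tibble with `participant_id` and `days_in_care`; adherence is
#'   averaged over days `[0, days_in_care)`.
#' @return tibble `participant_id`, `truth_adherence` (percent).
#' @export
truth_adherence <- function(truth, upto) {
  truth |>
    inner_join(upto |> select("participant_id", "days_in_care"),
               by = "participant_id") |>
    filter(.data$day < .data$days_in_care) |>
    group_by(.data$participant_id) |>
    summarise(truth_adherence = 100 * mean(.data$dose_taken), .groups = "drop")
}

#' Write a cohort bundle to its CSV normal form
#'
#' Emits the eight input CSVs (plus `truth.csv` for synthetic cohorts) in
#' the schema accepted by [read_cohort()]. Deterministic content for a
#' deterministic bundle, so regeneration with the same seed is
#' byte-identical.
#'
#' @param cohort a cohort bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    readr::write_csv(tbl, file.path(dir, paste0(name, ".csv")), na = "")
  }
  w(cohort$participants, "participants")
  w(cohort$dispensing, "dispensing")
  ev <- cohort$eamd_events |>
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  w(ev, "eamd_events")
  w(cohort$pill_returns, "pill_returns")
  w(cohort$self_report, "self_report")
  w(cohort$efv_concentrations, "efv_concentrations")
  w(cohort$labs, "labs")
  gt <- cohort$genotypes |>
    mutate(mutations = vapply(.data$mutations, paste, character(1),
                              collapse = ";"))
  w(gt, "genotypes")
  if (!is.null(cohort$truth)) w(cohort$truth, "truth")
  invisible(dir)
}

#' Fast per-landmark measurement summary of a synthetic cohort
#'
#' Computes, directly from the generator's day-level ground truth and
#' measured streams, one row per per-protocol participant with the true
#' cumulative adherence, all available adherence estimates and the landmark
#' outcome. Numerically identical to running the full estimator pipeline on
#' the event-level streams (asserted in the test-suite) but avoids
#' event-table construction, so large replicate studies stay cheap.
#'
#' @param sim a [simulate_cohort()] bundle.
#' @param landmark `"week16"` or `"week48"`.
#' @param config analysis configuration.
#' @return tibble with `participant_id`, `truth`, `sr`, `cpc`,
#'   `pr_average`, `pr_gaps`, `eamd`, `efv_log10`, `failed`,
#'   `vl_copies_per_ml`, plus baseline covariates.
#' @export
measured_landmark_summary <- function(sim, landmark,
                                      config = sim$config %||% default_config()) {
  stopifnot(inherits(sim, "sim_cohort"))
  win <- landmark_window(landmark, config)
  sel <- select_landmark_vl(sim$labs, sim$participants, landmark, config) |>
    filter(.data$days_in_care > 0)
  int <- sim$internal
  idx <- match(sel$participant_id, int$ids)

  csum_open <- cbind(0L, t(apply(int$monitored_open, 1, cumsum)))
  csum_dead <- cbind(0L, t(apply(int$dead, 1, cumsum)))
  csum_dose <- cbind(0L, t(apply(int$dose, 1, cumsum)))
  d <- sel$days_in_care
  truth_v <- 100 * csum_dose[cbind(idx, d + 1L)] / d
  eamd_tbl <- eamd_adherence(csum_open[cbind(idx, d + 1L)],
                             csum_dead[cbind(idx, d + 1L)], d)

  disp <- int$visit_grid |>
    inner_join(tibble::tibble(i = idx, days_in_care = d,
                              row = seq_along(idx)), by = "i") |>
    filter(.data$day < .data$days_in_care)
  pr <- disp |>
    group_by(.data$row) |>
    summarise(supplied = sum(.data$days_supplied), .groups = "drop")
  pr_avg <- rep(NA_real_, length(idx))
  pr_avg[pr$row] <- 100 * pr$supplied / d[pr$row]
  pr_gap <- rep(NA_real_, length(idx))
  disp_split <- split(disp[c("day", "days_supplied")], disp$row)
  for (k in names(disp_split)) {
    kk <- as.integer(k)
    dd <- disp_split[[k]]
    led <- build_stock_ledger(dd$day, dd$days_supplied, d[kk])
    pr_gap[kk] <- pr_gaps_adherence(led$medication_free_days, d[kk])
  }

  sr_rec <- pick_landmark_record(sim$self_report, "visit_date", sel, win)
  sr_v <- rep(NA_real_, length(idx))
  m <- match(sr_rec$participant_id, sel$participant_id)
  sr_v[m] <- sr_adherence(sr_rec$took_day1, sr_rec$took_day2, sr_rec$took_day3)

  cpc_v <- rep(NA_real_, length(idx))
  if (nrow(sim$pill_returns)) {
    cpc_rec <- pick_landmark_record(sim$pill_returns, "count_date", sel, win)
    vals <- cpc_adherence(cpc_rec$tablets_dispensed_since_last,
                          cpc_rec$tablets_returned, cpc_rec$count_date,
                          cpc_rec$last_dispense_date, cpc_rec$doses_per_day)
    cpc_v[match(cpc_rec$participant_id, sel$participant_id)] <- vals$value
  }

  tdm_v <- rep(NA_real_, length(idx))
  if (nrow(sim$efv_concentrations)) {
    tdm_rec <- pick_landmark_record(sim$efv_concentrations, "sample_date",
                                    sel, win)
    tdm_v[match(tdm_rec$participant_id, sel$participant_id)] <-
      tdm_features(tdm_rec$efv_mg_per_l,
                   config$efv_log_floor_mg_per_l)$log10_value
  }

  threshold <- unname(config$vl_threshold[landmark])
  pp <- sim$participants
  pm <- match(sel$participant_id, pp$participant_id)
  tibble::tibble(
    participant_id = sel$participant_id,
    truth = truth_v, sr = sr_v, cpc = cpc_v, pr_average = pr_avg,
    pr_gaps = pr_gap, eamd = eamd_tbl$value, efv_log10 = tdm_v,
    failed = sel$vl_copies_per_ml > threshold,
    vl_copies_per_ml = sel$vl_copies_per_ml,
    age_years = pp$age_years[pm], baseline_cd4 = pp$baseline_cd4[pm],
    baseline_log10_vl = pp$baseline_log10_vl[pm]
  )
}

#' Simulate a plain logistic adherence-outcome cohort
#'
#' Minimal generator for calibration studies of the logistic model itself:
#' adherence percentages drawn from a right-skewed Beta mixture and a binary
#' outcome drawn from a logistic model with a known odds ratio per 10%
#' adherence increase. No measurement error.
#'
#' @param n participants.
#' @param or_per_10pct true odds ratio per 10% adherence increase (1 gives a
#'   null cohort).
#' @param beta0 intercept on the logit scale (at adherence 0).
#' @param seed optional seed (`NULL` uses the current RNG state).
#' @return tibble with `adherence` (percent) and `y`.
#' @export
simulate_logistic_cohort <- function(n, or_per_10pct, beta0 = 0.5,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adherence <- 100 * rbeta(n, 6, 1.2)
  p <- plogis(beta0 + log(or_per_10pct) * adherence / 10)
  tibble::tibble(adherence = adherence, y = rbinom(n, 1, p))
}
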