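#' @keywords internal
cohort_schemas <- function() {
  list(
    participants = c("participant_id", "sex", "age_years", "baseline_cd4",
                     "baseline_log10_vl", "randomisation_date",
                     "end_of_care_date", "care_status"),
    dispensing = c("participant_id", "dispense_date", "drug", "days_supplied"),
    eamd_events = c("participant_id", "timestamp", "event_type",
                    "battery_voltage"),
    pill_returns = c("participant_id", "count_date", "drug",
                     "tablets_dispensed_since_last", "tablets_returned",
                     "last_dispense_date", "doses_per_day"),
    self_report = c("participant_id", "visit_date", "took_day1", "took_day2",
                    "took_day3"),
    efv_concentrations = c("participant_id", "sample_date", "efv_mg_per_l",
                           "reported_last_dose_time"),
    labs = c("participant_id", "sample_date", "hiv_rna_copies_per_ml", "cd4"),
    genotypes = c("participant_id", "sample_date", "mutations", "amplified")
  )
}

parse_iso_date <- function(x) as.Date(x, format = "%Y-%m-%d")

parse_iso_datetime <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# Collects row-level validation failures without aborting the load.
issue_row <- function(file, row, problem) {
  tibble::tibble(file = file, row = row, problem = problem)
}

#' Read and validate a cohort from its CSV normal form
#'
#' Loads the eight input streams (`participants.csv`, `dispensing.csv`,
#' `eamd_events.csv`, `pill_returns.csv`, `self_report.csv`,
#' `efv_concentrations.csv`, `labs.csv`, `genotypes.csv`) from `dir`,
#' validates every stream against its schema and type invariants, sorts
#' per-participant streams by date (stable, preserving input order on ties)
#' and removes obvious dispensing duplicates (same participant, date, drug
#' and quantity keep exactly one row).
#'
#' Rows violating an invariant (negative days supplied, unparseable date,
#' pill return dated on/before its dispensing, negative concentration, ...)
#' are dropped and logged in the returned `issues` table with their original
#' row number. A missing required column or a duplicated `participant_id` in
#' the demographics file is a hard error.
#'
#' @param dir directory containing the CSV files. Individual paths can be
#'   overridden via `paths`, a named list.
#' @param config see [default_config()].
#' @param paths optional named list of file paths overriding `dir` defaults.
#' @return a `cohort` list: one tibble per stream, plus `issues` (tibble of
#'   rejected/adjusted rows) and `config`.
#' @export
read_cohort <- function(dir, config = default_config(), paths = list()) {
  schemas <- cohort_schemas()
  files <- lapply(setNames(names(schemas), names(schemas)), function(nm) {
    paths[[nm]] %||% file.path(dir, paste0(nm, ".csv"))
  })
  missing <- !vapply(files, file.exists, logical(1))
  if (any(missing)) {
    stop("missing input file(s): ", paste(unlist(files[missing]), collapse = ", "))
  }

  raw <- lapply(setNames(names(schemas), names(schemas)), function(nm) {
    tbl <- readr::read_csv(files[[nm]], col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    absent <- setdiff(schemas[[nm]], names(tbl))
    if (length(absent)) {
      stop("schema error in ", nm, ".csv: missing column(s) ",
           paste(absent, collapse = ", "))
    }
    tbl
  })

  issues <- issue_row(character(), integer(), character())
  note <- function(file, rows, problem) {
    if (length(rows)) issues <<- bind_rows(issues, issue_row(file, rows, problem))
  }

  # -- participants ----------------------------------------------------------
  pp <- raw$participants
  if (anyDuplicated(pp$participant_id)) {
    stop("duplicate participant_id in participants.csv")
  }
  pp <- pp |>
    mutate(
      age_years = as.numeric(.data$age_years),
      baseline_cd4 = as.numeric(.data$baseline_cd4),
      baseline_log10_vl = as.numeric(.data$baseline_log10_vl),
      randomisation_date = parse_iso_date(.data$randomisation_date),
      end_of_care_date = parse_iso_date(.data$end_of_care_date),
      .row = dplyr::row_number()
    )
  bad <- which(is.na(pp$randomisation_date) | is.na(pp$age_years) |
                 pp$age_years <= 0 |
                 (!is.na(pp$baseline_cd4) & pp$baseline_cd4 < 0) |
                 (!is.na(pp$end_of_care_date) &
                    pp$end_of_care_date < pp$randomisation_date))
  note("participants", bad, "invalid demographics row")
  participants <- pp[setdiff(seq_len(nrow(pp)), bad), ] |> select(-".row")

  # -- dispensing ------------------------------------------------------------
  dd <- raw$dispensing |>
    mutate(dispense_date = parse_iso_date(.data$dispense_date),
           days_supplied = suppressWarnings(as.integer(.data$days_supplied)),
           .row = dplyr::row_number())
  bad <- which(is.na(dd$dispense_date) | is.na(dd$days_supplied) |
                 dd$days_supplied < 1)
  note("dispensing", bad, "unparseable date or days_supplied < 1")
  dd <- dd[setdiff(seq_len(nrow(dd)), bad), ]
  dedup <- dedupe_dispensing(dd)
  note("dispensing", dedup$removed_rows, "duplicate dispensing removed")
  dispensing <- dedup$records |>
    arrange(.data$participant_id, .data$dispense_date, .data$.row) |>
    select(-".row")

  # -- EAMD events -----------------------------------------------------------
  ee <- raw$eamd_events |>
    mutate(timestamp = parse_iso_datetime(.data$timestamp),
           battery_voltage = suppressWarnings(as.integer(.data$battery_voltage)),
           .row = dplyr::row_number())
  bad <- which(is.na(ee$timestamp) |
                 !ee$event_type %in% c("opening", "heartbeat") |
                 is.na(ee$battery_voltage) | ee$battery_voltage < 0)
  note("eamd_events", bad, "invalid EAMD event row")
  eamd_events <- ee[setdiff(seq_len(nrow(ee)), bad), ] |>
    arrange(.data$participant_id, .data$timestamp, .data$.row) |>
    select(-".row")

  # -- pill returns ----------------------------------------------------------
  pr <- raw$pill_returns |>
    mutate(count_date = parse_iso_date(.data$count_date),
           last_dispense_date = parse_iso_date(.data$last_dispense_date),
           tablets_dispensed_since_last =
             suppressWarnings(as.integer(.data$tablets_dispensed_since_last)),
           tablets_returned = suppressWarnings(as.integer(.data$tablets_returned)),
           doses_per_day = as.numeric(.data$doses_per_day),
           .row = dplyr::row_number())
  bad <- which(is.na(pr$count_date) | is.na(pr$last_dispense_date) |
                 is.na(pr$tablets_returned) | pr$tablets_returned < 0 |
                 pr$count_date <= pr$last_dispense_date)
  note("pill_returns", bad, "invalid pill-return row")
  pill_returns <- pr[setdiff(seq_len(nrow(pr)), bad), ] |>
    arrange(.data$participant_id, .data$count_date, .data$.row) |>
    select(-".row")

  # -- self report -----------------------------------------------------------
  sr <- raw$self_report |>
    mutate(visit_date = parse_iso_date(.data$visit_date),
           across(c("took_day1", "took_day2", "took_day3"),
                  ~ as.logical(.x)),
           .row = dplyr::row_number())
  bad <- which(is.na(sr$visit_date) | is.na(sr$took_day1) |
                 is.na(sr$took_day2) | is.na(sr$took_day3))
  note("self_report", bad, "incomplete 3-day recall row")
  self_report <- sr[setdiff(seq_len(nrow(sr)), bad), ] |>
    arrange(.data$participant_id, .data$visit_date, .data$.row) |>
    select(-".row")

  # -- EFV concentrations ----------------------------------------------------
  ec <- raw$efv_concentrations |>
    mutate(sample_date = parse_iso_date(.data$sample_date),
           efv_mg_per_l = as.numeric(.data$efv_mg_per_l),
           .row = dplyr::row_number())
  bad <- which(is.na(ec$sample_date) | is.na(ec$efv_mg_per_l) |
                 ec$efv_mg_per_l < 0)
  note("efv_concentrations", bad, "invalid concentration row")
  efv_concentrations <- ec[setdiff(seq_len(nrow(ec)), bad), ] |>
    arrange(.data$participant_id, .data$sample_date, .data$.row) |>
    select(-".row")

  # -- labs ------------------------------------------------------------------
  lb <- raw$labs |>
    mutate(sample_date = parse_iso_date(.data$sample_date),
           hiv_rna_copies_per_ml = as.numeric(.data$hiv_rna_copies_per_ml),
           cd4 = as.numeric(.data$cd4),
           .row = dplyr::row_number())
  bad <- which(is.na(lb$sample_date) | is.na(lb$hiv_rna_copies_per_ml) |
                 lb$hiv_rna_copies_per_ml < 0)
  note("labs", bad, "invalid lab row")
  labs <- lb[setdiff(seq_len(nrow(lb)), bad), ] |>
    arrange(.data$participant_id, .data$sample_date, .data$.row) |>
    select(-".row")

  # -- genotypes -------------------------------------------------------------
  gt <- raw$genotypes |>
    mutate(sample_date = parse_iso_date(.data$sample_date),
           amplified = as.logical(.data$amplified),
           mutations = lapply(strsplit(dplyr::coalesce(.data$mutations, ""), ";"),
                              function(m) m[nzchar(m)]),
           .row = dplyr::row_number())
  bad <- which(is.na(gt$sample_date) | is.na(gt$amplified) |
                 (!gt$amplified & lengths(gt$mutations) > 0))
  note("genotypes", bad, "invalid genotype row")
  genotypes <- gt[setdiff(seq_len(nrow(gt)), bad), ] |>
    arrange(.data$participant_id, .data$sample_date, .data$.row) |>
    select(-".row")

  structure(
    list(participants = participants, dispensing = dispensing,
         eamd_events = eamd_events, pill_returns = pill_returns,
         self_report = self_report, efv_concentrations = efv_concentrations,
         labs = labs, genotypes = genotypes, issues = issues, config = config),
    class = "cohort"
  )
}

#' Remove obvious dispensing duplicates
#'
#' Duplicate dispensing rows — identical participant, date, drug and quantity,
#' typically data-entry artefacts — are collapsed to a single row (the first
#' in input order). Idempotent.
#'
#' @param dispensing tibble of dispensing records.
#' @return list with `records` (deduplicated tibble) and `removed_rows`
#'   (original row numbers dropped, when a `.row` column is present).
#' @export
dedupe_dispensing <- function(dispensing) {
  keys <- c("participant_id", "dispense_date", "drug", "days_supplied")
  dup <- duplicated(dispensing[keys])
  removed <- if (".row" %in% names(dispensing)) dispensing$.row[dup] else which(dup)
  list(records = dispensing[!dup, , drop = FALSE], removed_rows = removed)
}
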