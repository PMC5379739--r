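#' Select the landmark viral load for each participant
#'
#' Per-protocol landmark selection: a participant contributes to a landmark
#' only if at least one HIV-RNA result falls inside that landmark's day
#' window (weeks 12-20 for week 16, weeks 32-64 for week 48, measured in days
#' since randomisation). When several results qualify, the one closest to the
#' nominal landmark day (112 or 336) is used, ties going to the earlier date;
#' such participants are flagged.
#'
#' @param labs tibble of lab records (`participant_id`, `sample_date`,
#'   `hiv_rna_copies_per_ml`).
#' @param participants tibble with `participant_id`, `randomisation_date` and
#'   optionally `end_of_care_date`.
#' @param landmark `"week16"` or `"week48"`.
#' @param config see [default_config()].
#' @return tibble with one row per included participant: `participant_id`,
#'   `vl_date`, `vl_day` (days since randomisation), `vl_copies_per_ml`,
#'   `randomisation_date`, `days_in_care` (randomisation to viral-load date,
#'   truncated at the end of care), and `multiple_in_window`.
#' @export
select_landmark_vl <- function(labs, participants, landmark,
                               config = default_config()) {
  win <- landmark_window(landmark, config)
  pp <- participants |>
    select("participant_id", "randomisation_date",
           dplyr::any_of("end_of_care_date"))
  if (!"end_of_care_date" %in% names(pp)) {
    pp$end_of_care_date <- as.Date(NA)
  }
  labs |>
    inner_join(pp, by = "participant_id") |>
    mutate(vl_day = as.integer(.data$sample_date - .data$randomisation_date)) |>
    filter(.data$vl_day >= win$lo, .data$vl_day <= win$hi) |>
    group_by(.data$participant_id) |>
    mutate(multiple_in_window = dplyr::n() > 1L) |>
    arrange(abs(.data$vl_day - win$nominal), .data$vl_day, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    mutate(
      end_day = ifelse(is.na(.data$end_of_care_date), NA_integer_,
                       as.integer(.data$end_of_care_date - .data$randomisation_date)),
      days_in_care = pmin(.data$vl_day, dplyr::coalesce(.data$end_day, .data$vl_day))
    ) |>
    transmute(.data$participant_id, vl_date = .data$sample_date,
              .data$vl_day, vl_copies_per_ml = .data$hiv_rna_copies_per_ml,
              randomisation_date = .data$randomisation_date,
              days_in_care = as.integer(.data$days_in_care),
              .data$multiple_in_window)
}
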