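#' Viral-suppression summary at a landmark
#'
#' @param outcomes outcome records from [derive_outcomes()].
#' @return tibble per landmark: `n` with a landmark viral load, `suppressed`
#'   (not failed) and `pct` suppressed.
#' @export
suppression_summary <- function(outcomes) {
  outcomes |>
    group_by(.data$landmark) |>
    summarise(n = dplyr::n(), suppressed = sum(!.data$failed),
              pct = 100 * .data$suppressed / .data$n, .groups = "drop")
}

#' Dead-battery censoring summary over monitor days
#'
#' @param eamd_days day-classification table (`status` column) pooled over
#'   participants.
#' @return one-row tibble: total `dosing_days`, `censored` days and `pct`
#'   censored (dead-battery fraction).
#' @export
censoring_summary <- function(eamd_days) {
  tibble::tibble(
    dosing_days = nrow(eamd_days),
    censored = sum(eamd_days$status == "censored"),
    pct = 100 * sum(eamd_days$status == "censored") / nrow(eamd_days)
  )
}

#' Prevalence of a mutation among genotyped samples
#'
#' @param genotypes genotype records (list-column `mutations`, flag
#'   `amplified`).
#' @param mutation mutation code, e.g. `"K65R"`.
#' @return one-row tibble: `genotyped` (amplified samples), `carriers`,
#'   `pct`.
#' @export
mutation_prevalence <- function(genotypes, mutation) {
  amp <- genotypes |> filter(.data$amplified)
  carriers <- sum(vapply(amp$mutations, function(m) mutation %in% m, logical(1)))
  tibble::tibble(genotyped = nrow(amp), carriers = carriers,
                 pct = 100 * carriers / nrow(amp))
}

#' Retention / end-of-care summary
#'
#' @param participants participant table with `care_status`.
#' @return tibble per care status: `n` and `pct` of the cohort.
#' @export
retention_summary <- function(participants) {
  participants |>
    count(.data$care_status, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Median (IQR) adherence per method and landmark
#'
#' The descriptive companion to the model report: per-method medians with
#' interquartile ranges and available n, mirroring how cohort adherence is
#' conventionally tabulated.
#'
#' @param estimates adherence estimates (stacked landmarks).
#' @return tibble per landmark x method: `n`, `median`, `q1`, `q3`.
#' @export
adherence_summary <- function(estimates) {
  estimates |>
    group_by(.data$landmark, .data$method) |>
    summarise(n = sum(!is.na(.data$value)),
              median = median(.data$value, na.rm = TRUE),
              q1 = unname(quantile(.data$value, 0.25, na.rm = TRUE)),
              q3 = unname(quantile(.data$value, 0.75, na.rm = TRUE)),
              .groups = "drop") |>
    arrange(.data$landmark, factor(.data$method, adherence_methods))
}
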