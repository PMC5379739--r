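#' Major-mutation resistance rule
#'
#' Maps major HIV-1 drug-resistance mutation codes to the drug(s) they
#' compromise. A participant is classified resistant when at least one listed
#' major mutation affects at least one drug in their regimen. The default
#' table covers the common first-line mutations (NRTI: K65R -> tenofovir,
#' M184V/I -> lamivudine/emtricitabine; NNRTI -> efavirenz and nevirapine);
#' it is user-replaceable configuration, not a curated catalogue.
#'
#' @param major_mutation_table named list: mutation code -> character vector
#'   of affected drugs.
#' @param regimen drugs in the participant's regimen.
#' @return a `resistance_rule` list.
#' @export
resistance_rule <- function(major_mutation_table = NULL, regimen = NULL) {
  nnrti <- c("efavirenz", "nevirapine")
  tbl <- major_mutation_table %||% list(
    K65R = "tenofovir",
    M184V = c("lamivudine", "emtricitabine"),
    M184I = c("lamivudine", "emtricitabine"),
    L100I = nnrti, K101E = nnrti, K103N = nnrti, V106M = nnrti,
    Y181C = nnrti, Y188L = nnrti, G190A = nnrti, G190S = nnrti,
    H221Y = nnrti, F227L = nnrti
  )
  structure(list(major_mutation_table = tbl,
                 regimen = regimen %||% c("tenofovir", "lamivudine", "efavirenz")),
            class = "resistance_rule")
}

#' Apply a resistance rule to a mutation list
#'
#' @param mutations character vector of mutation codes for one genotype.
#' @param rule a [resistance_rule()].
#' @return `TRUE` when >=1 major mutation affects >=1 regimen drug.
#' @export
is_resistant <- function(mutations, rule = resistance_rule()) {
  if (length(mutations) == 0) return(FALSE)
  hits <- rule$major_mutation_table[intersect(mutations,
                                              names(rule$major_mutation_table))]
  any(unlist(hits) %in% rule$regimen)
}

#' Derive landmark virological and resistance outcomes
#'
#' Virological failure is a single HIV-RNA above the landmark threshold
#' (>400 copies/ml at week 16, >40 copies/ml at week 48) on the selected
#' in-window viral load. Genotyping eligibility requires >500 copies/ml (the
#' amplification minimum); the resistance flag is defined only for genotyped,
#' amplified samples and applies the major-mutation rule against the
#' regimen. Baseline covariates (age, CD4, log10 HIV-RNA) are carried for
#' the multivariable models.
#'
#' @param cohort a cohort bundle.
#' @param landmark `"week16"` or `"week48"`.
#' @param rule a [resistance_rule()].
#' @param config see [default_config()].
#' @return tibble of outcome records: `participant_id`, `landmark`,
#'   `vl_copies_per_ml`, `failed`, `genotype_eligible`, `genotyped`,
#'   `resistant` (`NA` unless genotyped and amplified), covariates
#'   `age_years`, `baseline_cd4`, `baseline_log10_vl`.
#' @export
derive_outcomes <- function(cohort, landmark, rule = resistance_rule(),
                            config = cohort$config %||% default_config()) {
  win <- landmark_window(landmark, config)
  sel <- select_landmark_vl(cohort$labs, cohort$participants, landmark, config)
  threshold <- unname(config$vl_threshold[landmark])

  gt <- cohort$genotypes |>
    inner_join(sel |> select("participant_id", "randomisation_date"),
               by = "participant_id") |>
    mutate(day = as.integer(.data$sample_date - .data$randomisation_date)) |>
    filter(.data$day >= win$lo, .data$day <= win$hi) |>
    group_by(.data$participant_id) |>
    arrange(abs(.data$day - win$nominal), .data$day, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select("participant_id", "mutations", "amplified")

  in_window_gt <- cohort$genotypes |>
    inner_join(cohort$participants |>
                 select("participant_id", "randomisation_date"),
               by = "participant_id") |>
    mutate(day = as.integer(.data$sample_date - .data$randomisation_date)) |>
    filter(.data$day >= win$lo, .data$day <= win$hi + 30L)
  orphan <- setdiff(in_window_gt$participant_id, sel$participant_id)
  if (length(orphan)) {
    warning(length(orphan),
            " genotype record(s) without a matching landmark viral load; ",
            "resistance left absent for: ", paste(orphan, collapse = ", "))
  }

  sel |>
    left_join(gt, by = "participant_id") |>
    left_join(cohort$participants |>
                select("participant_id", "age_years", "baseline_cd4",
                       "baseline_log10_vl"),
              by = "participant_id") |>
    transmute(
      .data$participant_id, landmark = landmark,
      .data$vl_copies_per_ml,
      failed = .data$vl_copies_per_ml > threshold,
      genotype_eligible = .data$vl_copies_per_ml > config$genotype_vl_min,
      genotyped = !vapply(.data$mutations, is.null, logical(1)) &
        dplyr::coalesce(.data$amplified, FALSE),
      resistant = ifelse(.data$genotyped,
                         vapply(.data$mutations, is_resistant, logical(1),
                                rule = rule),
                         NA),
      .data$age_years, .data$baseline_cd4, .data$baseline_log10_vl,
      .data$multiple_in_window
    )
}
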