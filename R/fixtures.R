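# Reconstruction builders: expand published summary counts into minimal
# row-level tables with the right marginals, so the tabulation operations
# can be exercised against printed cohort summaries without participant
# data. All reconstructed values beyond the counts themselves are synthetic
# placeholders (suppressed viral loads are set to 20 copies/ml, failures to
# 5000, etc.).

#' Reconstruct a landmark lab table from suppression counts
#'
#' Builds a minimal cohort (participants + labs) in which `n_total`
#' participants have a viral load on the nominal landmark day and exactly
#' `n_suppressed` of them are at or below the landmark failure threshold.
#'
#' @param n_total participants with a landmark viral load.
#' @param n_suppressed of these, how many are suppressed.
#' @param landmark `"week16"` or `"week48"`.
#' @param config see [default_config()].
#' @return list with `participants` and `labs` tibbles (a partial cohort
#'   bundle usable by [select_landmark_vl()] and [derive_outcomes()]).
#' @export
reconstruct_suppression_cohort <- function(n_total, n_suppressed, landmark,
                                           config = default_config()) {
  stopifnot(n_suppressed <= n_total)
  epoch <- as.Date("2012-07-12")
  ids <- sprintf("P%03d", seq_len(n_total))
  participants <- tibble::tibble(
    participant_id = ids, sex = "female", age_years = 35,
    baseline_cd4 = 225, baseline_log10_vl = 4.9,
    randomisation_date = epoch, end_of_care_date = as.Date(NA),
    care_status = "in_care"
  )
  threshold <- unname(config$vl_threshold[landmark])
  labs <- tibble::tibble(
    participant_id = ids,
    sample_date = epoch + unname(config$nominal_day[landmark]),
    hiv_rna_copies_per_ml = c(rep(threshold / 2, n_suppressed),
                              rep(5000, n_total - n_suppressed)),
    cd4 = NA_real_
  )
  list(participants = participants, labs = labs)
}

#' Reconstruct a pooled monitor-day table from censoring counts
#'
#' @param n_days total participant dosing days recorded.
#' @param n_censored dead-battery (censored) days among them.
#' @param p_adherent share of the non-censored days marked adherent (only
#'   the censored margin matters for the censoring summary).
#' @return tibble with a `status` column of length `n_days`.
#' @export
reconstruct_eamd_days <- function(n_days, n_censored, p_adherent = 0.9) {
  stopifnot(n_censored <= n_days)
  live <- n_days - n_censored
  n_adh <- round(p_adherent * live)
  tibble::tibble(status = c(rep("censored", n_censored),
                            rep("adherent", n_adh),
                            rep("nonadherent", live - n_adh)))
}

#' Reconstruct a genotype table from mutation counts
#'
#' Builds one amplified genotype record per genotyped sample with each named
#' mutation assigned to the stated number of carriers (assignments overlap
#' from the first record on; co-occurrence beyond the margins is not
#' published and not represented).
#'
#' @param n_genotyped successfully amplified genotypes.
#' @param mutation_counts named integer vector, e.g. `c(K65R = 8)`.
#' @return genotype tibble (`participant_id`, `sample_date`, `mutations`
#'   list-column, `amplified`).
#' @export
reconstruct_genotypes <- function(n_genotyped, mutation_counts) {
  stopifnot(all(mutation_counts <= n_genotyped))
  muts <- rep(list(character()), n_genotyped)
  for (m in names(mutation_counts)) {
    k <- mutation_counts[[m]]
    if (k > 0) muts[seq_len(k)] <- lapply(muts[seq_len(k)], c, m)
  }
  tibble::tibble(
    participant_id = sprintf("G%03d", seq_len(n_genotyped)),
    sample_date = as.Date("2012-07-12") + 112,
    mutations = muts,
    amplified = TRUE
  )
}

#' Reconstruct a participant table from retention counts
#'
#' @param status_counts named integer vector over care statuses, e.g.
#'   `c(in_care = 186, transferred = 16, died = 8, ltfu = 19, withdrew = 1)`.
#' @return participant tibble with the stated `care_status` margin.
#' @export
reconstruct_retention <- function(status_counts) {
  n <- sum(status_counts)
  epoch <- as.Date("2012-07-12")
  tibble::tibble(
    participant_id = sprintf("R%03d", seq_len(n)),
    sex = "female", age_years = 35, baseline_cd4 = 225,
    baseline_log10_vl = 4.9, randomisation_date = epoch,
    end_of_care_date = as.Date(NA),
    care_status = rep(names(status_counts), status_counts)
  )
}
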