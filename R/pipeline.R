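#' Estimate adherence at both landmarks
#'
#' @param cohort a cohort bundle.
#' @param landmarks landmarks to evaluate.
#' @param config analysis configuration.
#' @return stacked estimate tibble (see [compute_adherence()]).
#' @export
run_estimates <- function(cohort, landmarks = c("week16", "week48"),
                          config = cohort$config %||% default_config()) {
  purrr::map_dfr(landmarks, function(lm) compute_adherence(cohort, lm, config))
}

#' Derive outcomes at both landmarks
#'
#' @inheritParams run_estimates
#' @param rule resistance classification rule.
#' @return stacked outcome tibble (see [derive_outcomes()]).
#' @export
run_outcomes <- function(cohort, landmarks = c("week16", "week48"),
                         rule = resistance_rule(),
                         config = cohort$config %||% default_config()) {
  purrr::map_dfr(landmarks, function(lm) derive_outcomes(cohort, lm, rule, config))
}

#' Fit all models and AUC comparisons
#'
#' @param estimates,outcomes stacked tibbles from [run_estimates()] /
#'   [run_outcomes()].
#' @param reference_method reference for the paired AUC comparison matrix.
#' @param bootstrap bootstrap resamples for comparison sensitivity CIs.
#' @param seed bootstrap seed.
#' @return list with `report` (one row per method x landmark x outcome, see
#'   [build_model_report()])
#'   and `auc_comparisons`.
#' @export
run_models <- function(estimates, outcomes, reference_method = "EAMD",
                       bootstrap = 2000, seed = 1) {
  report <- build_model_report(estimates, outcomes)
  comparisons <- purrr::map_dfr(
    intersect(c("week16", "week48"), unique(estimates$landmark)),
    function(lm) {
      purrr::map_dfr(c("failure", "resistance"), function(oc) {
        tryCatch(
          compare_methods_auc(estimates, outcomes, lm, oc,
                              reference = reference_method,
                              bootstrap = bootstrap, seed = seed),
          warning = function(w) tibble::tibble())
      })
    })
  list(report = report, auc_comparisons = comparisons)
}

#' Run the full pipeline on a cohort
#'
#' estimate -> outcomes -> models -> (optionally) files on disk.
#'
#' @param cohort a cohort bundle from [read_cohort()] or
#'   [simulate_cohort()].
#' @param out_dir optional output directory for [write_outputs()].
#' @param reference_method reference for AUC comparisons.
#' @param seed seed for the bootstrap comparisons.
#' @param config analysis configuration.
#' @return list with `estimates`, `outcomes`, `models` (report +
#'   comparisons), `adherence_summary` and `suppression`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, reference_method = "EAMD",
                         seed = 1, config = cohort$config %||% default_config()) {
  estimates <- run_estimates(cohort, config = config)
  outcomes <- run_outcomes(cohort, config = config)
  models <- run_models(estimates, outcomes, reference_method = reference_method,
                       seed = seed)
  result <- list(estimates = estimates, outcomes = outcomes, models = models,
                 adherence_summary = adherence_summary(estimates),
                 suppression = suppression_summary(outcomes))
  if (!is.null(out_dir)) {
    write_outputs(estimates, models$report, out_dir,
                  auc_comparisons = models$auc_comparisons,
                  config = config, seed = seed)
  }
  result
}

#' Write pipeline outputs
#'
#' Writes `adherence_estimates.csv` (tidy estimate rows),
#' `model_report.csv` (method, landmark, outcome, n, events,
#' or/CI/p, aor/CI/p, auc/CI), one `roc_points_<method>_<landmark>.csv` per
#' fitted failure cell, optionally `auc_comparisons.csv`, and a `run_log.txt`
#' echoing the configuration and seed. Rewriting the same inputs is
#' byte-identical.
#'
#' @param estimates estimate tibble (non-empty).
#' @param report model report tibble.
#' @param out_dir output directory (created if needed; unwritable is an
#'   error).
#' @param auc_comparisons optional comparison tibble.
#' @param config,seed echoed into the run log.
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(estimates, report, out_dir, auc_comparisons = NULL,
                          config = default_config(), seed = NA) {
  stopifnot(nrow(estimates) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  readr::write_csv(estimates, file.path(out_dir, "adherence_estimates.csv"),
                   na = "")
  flat <- report |> select(-dplyr::any_of("roc_points"))
  readr::write_csv(flat, file.path(out_dir, "model_report.csv"), na = "")
  fail_rows <- report |> filter(.data$outcome == "failure")
  for (r in seq_len(nrow(fail_rows))) {
    pts <- fail_rows$roc_points[[r]]
    if (!is.null(pts)) {
      readr::write_csv(pts, file.path(out_dir, sprintf(
        "roc_points_%s_%s.csv", tolower(fail_rows$method[r]),
        fail_rows$landmark[r])))
    }
  }
  if (!is.null(auc_comparisons) && nrow(auc_comparisons)) {
    readr::write_csv(auc_comparisons, file.path(out_dir, "auc_comparisons.csv"),
                     na = "")
  }
  log_lines <- c(
    "adherekit run log",
    paste0("seed: ", seed),
    paste0("config: ", paste(names(config), vapply(config, function(x)
      paste(format(unlist(x)), collapse = ","), character(1)),
      sep = "=", collapse = "; "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Run manifest for reproducibility checks
#'
#' @param config configuration to snapshot.
#' @param seed run seed.
#' @param input_files files to digest (md5).
#' @return one-row tibble with the seed, package version and a digest per
#'   input file (semicolon-separated `name:md5` pairs).
#' @export
run_manifest <- function(config, seed, input_files = character()) {
  digests <- if (length(input_files)) {
    md5 <- tools::md5sum(input_files)
    paste(basename(names(md5)), unname(md5), sep = ":", collapse = ";")
  } else ""
  tibble::tibble(
    seed = seed,
    package_version = as.character(utils::packageVersion("adherekit")),
    n_inputs = length(input_files),
    input_digests = digests
  )
}
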