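# Model predictor per method: percentage measures enter in 10%-units so the
# odds ratio reads "per 10% adherence increase"; TDM enters as log10
# concentration so its OR reads "per 1 log10 mg/L increase".
model_predictor <- function(estimates, method) {
  est <- estimates |> filter(.data$method == !!method)
  if (method == "TDM") {
    est |> transmute(.data$participant_id, x = .data$log10_value)
  } else {
    est |> transmute(.data$participant_id, x = .data$value / 10)
  }
}

#' Fit the full adherence-outcome model report
#'
#' For every adherence method, landmark and outcome (virological failure,
#' resistance) present in the inputs, fits the univariate logistic model
#' (outcome ~ adherence in 10%-units, or log10 efavirenz for TDM) and the
#' multivariable model adding the prespecified baseline covariates (age, CD4
#' count, log10 HIV-RNA), and computes the univariate-model ROC AUC with
#' DeLong 95% CI. Complete-case per method: a participant missing one
#' measure is dropped from that measure's models only. Cells with no events
#' (or no non-events) are reported with `NA` and a reason; small cells
#' (fewer than 5 events or non-events) carry a small-sample flag.
#'
#' @param estimates adherence estimates from [compute_adherence()] (both
#'   landmarks may be stacked).
#' @param outcomes outcome records from [derive_outcomes()] (stacked to
#'   match).
#' @param outcomes_set which outcomes to model.
#' @param methods which adherence methods to model.
#' @return tibble with one row per method x landmark x outcome: `n`,
#'   `events`, `or`, `or_lcl`, `or_ucl`, `p`, `aor`, `aor_lcl`, `aor_ucl`,
#'   `ap`, `auc`, `auc_lcl`, `auc_ucl`, `fit_method`, `flag`, and a
#'   `roc_points` list-column.
#' @export
build_model_report <- function(estimates, outcomes,
                               outcomes_set = c("failure", "resistance"),
                               methods = adherence_methods) {
  cells <- tidyr::expand_grid(
    method = intersect(methods, unique(estimates$method)),
    landmark = intersect(c("week16", "week48"), unique(estimates$landmark)),
    outcome = outcomes_set
  )
  purrr::pmap_dfr(cells, function(method, landmark, outcome) {
    est <- estimates |> filter(.data$landmark == !!landmark)
    out <- outcomes |> filter(.data$landmark == !!landmark)
    df <- model_predictor(est, method) |>
      inner_join(out, by = "participant_id")
    df$yy <- if (outcome == "failure") df$failed else df$resistant
    df <- df |> filter(!is.na(.data$yy), !is.na(.data$x))
    base <- tibble::tibble(method = method, landmark = landmark,
                           outcome = outcome, n = nrow(df),
                           events = sum(df$yy))
    if (nrow(df) == 0 || sum(df$yy) == 0 || sum(df$yy) == nrow(df)) {
      return(base |> mutate(or = NA_real_, or_lcl = NA_real_,
                            or_ucl = NA_real_, p = NA_real_, aor = NA_real_,
                            aor_lcl = NA_real_, aor_ucl = NA_real_,
                            ap = NA_real_, auc = NA_real_, auc_lcl = NA_real_,
                            auc_ucl = NA_real_, fit_method = NA_character_,
                            flag = "no informative outcomes",
                            roc_points = list(NULL)))
    }
    uni <- fit_logistic(df$yy, df$x)
    covs <- df |> select("age_years", "baseline_cd4", "baseline_log10_vl")
    multi <- fit_logistic(df$yy, df$x, covariates = covs)
    uor <- or_from_fit(uni)
    adj <- or_from_fit(multi)
    roc <- if (isTRUE(uni$ok)) auc_delong(uni$fitted, df$yy) else NULL
    flag <- c(
      if (min(sum(df$yy), sum(!df$yy)) < 5) "small sample" else NULL,
      if (isTRUE(uni$separation) || isTRUE(multi$separation))
        "separation: Firth penalized fit" else NULL
    )
    base |>
      mutate(or = uor$or, or_lcl = uor$or_lcl, or_ucl = uor$or_ucl, p = uor$p,
             aor = adj$or, aor_lcl = adj$or_lcl, aor_ucl = adj$or_ucl,
             ap = adj$p,
             auc = roc$auc %||% NA_real_,
             auc_lcl = roc$ci[1] %||% NA_real_,
             auc_ucl = roc$ci[2] %||% NA_real_,
             fit_method = uni$method %||% NA_character_,
             flag = if (length(flag)) paste(flag, collapse = "; ") else NA_character_,
             roc_points = list(roc$roc_points))
  })
}

#' Paired AUC comparison matrix against a reference method
#'
#' Compares each method's univariate failure/resistance AUC with a reference
#' method (default the electronic monitor) on the participants shared by the
#' two methods, using the paired DeLong test with a seed-fixed bootstrap
#' sensitivity analysis. Risk orientation is handled by scoring with each
#' univariate model's fitted probabilities.
#'
#' @param estimates,outcomes as in [build_model_report()].
#' @param landmark landmark to compare at.
#' @param outcome `"failure"` or `"resistance"`.
#' @param reference reference method (default `"EAMD"`).
#' @param bootstrap bootstrap resamples for the sensitivity CI.
#' @param seed bootstrap seed.
#' @return tibble with one row per non-reference method: AUCs on the shared
#'   subjects, difference (method minus reference), DeLong `se`, `ci`, `p`,
#'   bootstrap CI/p and shared-subject counts. Empty (with a warning) when
#'   the reference method is absent.
#' @export
compare_methods_auc <- function(estimates, outcomes, landmark,
                                outcome = "failure", reference = "EAMD",
                                bootstrap = 2000, seed = 1) {
  est <- estimates |> filter(.data$landmark == !!landmark)
  out <- outcomes |> filter(.data$landmark == !!landmark)
  if (!reference %in% est$method) {
    warning("reference method ", reference, " absent; empty comparison")
    return(tibble::tibble())
  }
  ref <- model_predictor(est, reference) |> rename(x_ref = "x")
  others <- setdiff(intersect(adherence_methods, unique(est$method)), reference)
  purrr::map_dfr(others, function(m) {
    df <- model_predictor(est, m) |>
      inner_join(ref, by = "participant_id") |>
      inner_join(out, by = "participant_id")
    df$yy <- if (outcome == "failure") df$failed else df$resistant
    df <- df |> filter(!is.na(.data$yy), !is.na(.data$x), !is.na(.data$x_ref))
    if (nrow(df) == 0 || sum(df$yy) == 0 || sum(df$yy) == nrow(df)) {
      return(tibble::tibble(method = m, reference = reference,
                            landmark = landmark, outcome = outcome,
                            n = nrow(df), flag = "no informative outcomes"))
    }
    f_m <- fit_logistic(df$yy, df$x)
    f_r <- fit_logistic(df$yy, df$x_ref)
    if (!isTRUE(f_m$ok) || !isTRUE(f_r$ok)) {
      return(tibble::tibble(method = m, reference = reference,
                            landmark = landmark, outcome = outcome,
                            n = nrow(df), flag = "degenerate model"))
    }
    cmp <- compare_auc(f_m$fitted, f_r$fitted, df$yy,
                       bootstrap = bootstrap, seed = seed)
    tibble::tibble(method = m, reference = reference, landmark = landmark,
                   outcome = outcome, n = cmp$n, events = cmp$events,
                   auc = cmp$auc_a, auc_reference = cmp$auc_b,
                   difference = cmp$difference, se = cmp$se,
                   ci_lcl = cmp$ci[1], ci_ucl = cmp$ci[2], p = cmp$p,
                   boot_lcl = cmp$boot_ci[1] %||% NA_real_,
                   boot_ucl = cmp$boot_ci[2] %||% NA_real_,
                   boot_p = cmp$boot_p %||% NA_real_,
                   flag = NA_character_)
  })
}
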