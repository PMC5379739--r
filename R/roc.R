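# Placement values: for each case (event), the fraction of controls it
# outscores (ties count 1/2); and symmetrically for controls. The mean of
# either vector is the Mann-Whitney AUC; their variances drive DeLong
# inference.
auc_placements <- function(scores, y) {
  y <- as.logical(y)
  cases <- scores[y]
  controls <- scores[!y]
  m <- length(cases)
  n <- length(controls)
  stopifnot(m > 0, n > 0)
  r <- rank(c(cases, controls), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(cases, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(controls, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' ROC AUC with DeLong confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability via placement values (ties counted one half), with the
#' DeLong variance estimate `var(V10)/m + var(V01)/n` and a Wald 95% CI
#' truncated to `[0, 1]`. Scores must be oriented so that higher values mean
#' higher predicted risk; fitted probabilities from a logistic model satisfy
#' this automatically.
#'
#' @param scores numeric risk scores.
#' @param y binary outcome (event = 1/TRUE).
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (length 2), `m` events, `n` controls
#'   and `roc_points` (tibble `fpr`, `tpr`, `threshold`).
#' @export
auc_delong <- function(scores, y, conf_level = 0.95) {
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- as.logical(y)[keep]
  if (!any(y) || all(y)) {
    return(list(auc = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                m = sum(y), n = sum(!y), flag = "single outcome class"))
  }
  pl <- auc_placements(scores, y)
  se <- sqrt(var(pl$v10) / pl$m + var(pl$v01) / pl$n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * se, 0), 1)
  list(auc = pl$auc, se = se, ci = ci, m = pl$m, n = pl$n,
       roc_points = roc_curve_points(scores, y))
}

#' ROC curve points at every observed threshold
#'
#' One operating point per unique score threshold (classifying
#' `score >= threshold` as predicted failure), anchored at (0,0) and (1,1).
#'
#' @inheritParams auc_delong
#' @return tibble with `fpr`, `tpr`, `threshold` ordered along the curve.
#' @export
roc_curve_points <- function(scores, y) {
  y <- as.logical(y)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thresholds, function(t) sum(scores >= t & y), numeric(1))
  fp <- vapply(thresholds, function(t) sum(scores >= t & !y), numeric(1))
  tibble::tibble(
    fpr = c(0, fp / sum(!y), 1),
    tpr = c(0, tp / sum(y), 1),
    threshold = c(Inf, thresholds, -Inf)
  )
}

#' Paired nonparametric comparison of two AUCs (DeLong)
#'
#' Compares the AUCs of two risk scores measured on the same subjects using
#' the paired DeLong placement covariance, with an optional seed-fixed
#' stratified bootstrap reported alongside as a sensitivity analysis.
#'
#' @param scores_a,scores_b risk scores on the same subjects (pairwise
#'   complete cases are used).
#' @param y shared binary outcome.
#' @param bootstrap number of bootstrap resamples (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return list with `auc_a`, `auc_b`, `difference`, `se`, `ci`, `p`
#'   (DeLong), and when bootstrapped `boot_ci`, `boot_p`.
#' @export
compare_auc <- function(scores_a, scores_b, y, bootstrap = 0, seed = 1) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y)) {
    stop("paired comparison requires score vectors on the same subjects")
  }
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(y)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]
  y <- as.logical(y)[keep]
  pa <- auc_placements(scores_a, y)
  pb <- auc_placements(scores_b, y)
  diff <- pa$auc - pb$auc
  s10 <- var(pa$v10 - pb$v10)
  s01 <- var(pa$v01 - pb$v01)
  se <- sqrt(s10 / pa$m + s01 / pa$n)
  if (!is.finite(se)) {
    # fewer than two events or two non-events: no paired variance estimate
    p <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else if (se < .Machine$double.eps^0.5) {
    p <- if (abs(diff) < .Machine$double.eps^0.5) 1 else 0
    ci <- c(diff, diff)
  } else {
    z <- diff / se
    p <- 2 * pnorm(-abs(z))
    ci <- diff + c(-1, 1) * qnorm(0.975) * se
  }
  out <- list(auc_a = pa$auc, auc_b = pb$auc, difference = diff, se = se,
              ci = ci, p = p, n = length(y), events = pa$m)
  if (bootstrap > 0 && pa$m >= 2 && pa$n >= 2) {
    set.seed(seed)
    idx_case <- which(y); idx_ctrl <- which(!y)
    resample <- function(ix) ix[sample.int(length(ix), replace = TRUE)]
    diffs <- replicate(bootstrap, {
      i <- c(resample(idx_case), resample(idx_ctrl))
      auc_placements(scores_a[i], y[i])$auc -
        auc_placements(scores_b[i], y[i])$auc
    })
    out$boot_ci <- unname(quantile(diffs, c(0.025, 0.975)))
    out$boot_p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    out$boot_p <- min(out$boot_p, 1)
  }
  out
}
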