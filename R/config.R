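#' Default analysis configuration
#'
#' Central switchboard for the thresholds and windows used throughout the
#' pipeline. All day arithmetic is half-open `[start, end)` relative to the
#' randomisation date, so "days between" two dates is their integer
#' difference.
#'
#' @param ... named overrides of any default entry.
#'
#' @return A named list with entries:
#' \describe{
#'   \item{battery_threshold}{EAMD battery voltage (device units, mV scale)
#'     below which a monitor day is censored as a dead-battery day
#'     (default 3660).}
#'   \item{efv_log_floor_mg_per_l}{floor applied to undetectable/zero
#'     efavirenz concentrations before the log10 transform (default 0.05).}
#'   \item{landmark_days}{list of `c(lo, hi)` day windows (inclusive) within
#'     which a viral load qualifies for each landmark: weeks 12-20 for the
#'     week-16 landmark, weeks 32-64 for week 48.}
#'   \item{nominal_day}{the nominal landmark day used to pick among multiple
#'     in-window viral loads (closest wins, ties to the earlier date).}
#'   \item{vl_threshold}{landmark-specific virological-failure thresholds in
#'     copies/ml (>400 at week 16, >40 at week 48).}
#'   \item{genotype_vl_min}{minimum viral load for genotype amplification
#'     eligibility (500 copies/ml).}
#'   \item{anchor_drugs}{drugs whose dispensings/counts feed the adherence
#'     calculations.}
#'   \item{doses_per_day}{default dosing frequency.}
#' }
#' @export
default_config <- function(...) {
  cfg <- list(
    battery_threshold = 3660,
    efv_log_floor_mg_per_l = 0.05,
    landmark_days = list(week16 = c(84L, 140L), week48 = c(224L, 448L)),
    nominal_day = c(week16 = 112L, week48 = 336L),
    vl_threshold = c(week16 = 400, week48 = 40),
    genotype_vl_min = 500,
    anchor_drugs = c("efavirenz", "nevirapine", "lopinavir_r"),
    doses_per_day = 1
  )
  overrides <- list(...)
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(names(overrides) %in% names(cfg)))
    cfg[names(overrides)] <- overrides
  }
  cfg
}

#' Landmark evaluation window
#'
#' @param landmark `"week16"` or `"week48"`.
#' @param config see [default_config()].
#' @return list with `landmark`, inclusive day bounds `lo`/`hi`, and the
#'   `nominal` landmark day, all in days since randomisation.
#' @export
landmark_window <- function(landmark, config = default_config()) {
  landmark <- match.arg(landmark, c("week16", "week48"))
  bounds <- config$landmark_days[[landmark]]
  list(landmark = landmark, lo = bounds[1], hi = bounds[2],
       nominal = unname(config$nominal_day[landmark]))
}

adherence_methods <- c("SR", "CPC", "PR_AVERAGE", "PR_GAPS", "EAMD", "TDM")
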