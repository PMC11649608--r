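#' Measurement scale specifications for the monitoring factors
#'
#' Returns the per-factor measurement metadata used throughout the package:
#' the raw scale bounds, the normalization rule that maps raw values onto the
#' analysis scale, the normalized bounds, and the two category axes used for
#' factor attribution (psychological vs. physiological, self-report vs.
#' sensor).
#'
#' Self-reports on a visual-analogue scale (VAS, 0--100) are divided by 100;
#' self-reports on a category-ratio scale (CRS, 6--20) are divided by 20, so
#' their normalized range is 0.3--1.0 and the theoretical scale range used by
#' the distribution measure is 0.7; sensor-derived factors (and the session
#' RPE load, which is unbounded above) are divided by the maximum value of
#' that factor for each individual, giving a 0--1 range.
#'
#' The raw factor `exertion` (RPE, CRS 6--20) is listed because it is
#' measured directly, but it enters the analysis multiplied by session
#' duration as the internal load factor `srpe` (see
#' [build_daily_factors()]); it is therefore not part of
#' [default_factor_set()].
#'
#' @return A data.frame with one row per factor and columns `factor`,
#'   `raw_min`, `raw_max` (`Inf` when the factor is normalized by the
#'   individual maximum), `normalization` (one of `"divide_by_100"`,
#'   `"divide_by_20"`, `"divide_by_individual_max"`), `norm_min`, `norm_max`,
#'   `category` (`"psychological"` or `"physiological"`) and `source`
#'   (`"self_report"` or `"sensor"`).
#' @seealso [default_factor_set()], [normalize_factors()]
#' @examples
#' default_scale_specs()
#' @export
default_scale_specs <- function() {
  specs <- data.frame(
    factor = c("recovery", "self_efficacy", "motivation", "mood",
               "exertion", "perceived_performance", "enjoyment",
               "distance", "sprints", "duration", "hr_zone5", "srpe"),
    raw_min = c(6, 0, 0, 0, 6, 0, 0, 0, 0, 0, 0, 0),
    raw_max = c(20, 100, 100, 100, 20, 100, 100, Inf, Inf, Inf, Inf, Inf),
    normalization = c("divide_by_20", "divide_by_100", "divide_by_100",
                      "divide_by_100", "divide_by_20", "divide_by_100",
                      "divide_by_100", "divide_by_individual_max",
                      "divide_by_individual_max", "divide_by_individual_max",
                      "divide_by_individual_max", "divide_by_individual_max"),
    norm_min = c(0.3, 0, 0, 0, 0.3, 0, 0, 0, 0, 0, 0, 0),
    norm_max = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    category = c("physiological", "psychological", "psychological",
                 "psychological", "physiological", "psychological",
                 "psychological", "physiological", "physiological",
                 "physiological", "physiological", "physiological"),
    source = c("self_report", "self_report", "self_report", "self_report",
               "self_report", "self_report", "self_report",
               "sensor", "sensor", "sensor", "sensor", "self_report"),
    stringsAsFactors = FALSE
  )
  specs
}

#' Default factor set entering the dynamic complexity analysis
#'
#' The eleven monitoring factors analysed by default: four morning/evening
#' psychological self-reports (self-efficacy, motivation, mood, perceived
#' performance plus enjoyment), perceived recovery, four sensor-derived load
#' factors (distance, sprints, duration, seconds in heart-rate zone 5) and
#' the internal training load `srpe` (RPE times session duration, summed
#' over a day's sessions). Raw RPE (`exertion`) enters only through `srpe`;
#' `duration` is kept both as its own factor and inside `srpe`. The set is
#' an argument everywhere it is used, so alternatives can be analysed.
#'
#' @return Character vector of factor names.
#' @export
default_factor_set <- function() {
  c("recovery", "self_efficacy", "motivation", "mood",
    "distance", "sprints", "duration", "hr_zone5",
    "srpe", "perceived_performance", "enjoyment")
}

#' Raw factors emitted by the synthetic generator
#'
#' The factors as they are measured (before daily aggregation): `exertion`
#' instead of the derived `srpe`.
#'
#' @return Character vector of factor names.
#' @export
default_raw_factor_set <- function() {
  c("recovery", "self_efficacy", "motivation", "mood", "exertion",
    "distance", "sprints", "duration", "hr_zone5",
    "perceived_performance", "enjoyment")
}

# look up spec rows for a set of factors, erroring on gaps
spec_rows <- function(specs, factors) {
  idx <- match(factors, specs$factor)
  if (anyNA(idx)) {
    stop("no scale specification for factor(s): ",
         paste(factors[is.na(idx)], collapse = ", "))
  }
  specs[idx, , drop = FALSE]
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
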