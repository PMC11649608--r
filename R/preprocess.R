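#' Apply the cohort inclusion criteria
#'
#' A player is retained iff (a) at least one injury onset falls between
#' measurement `dc_window` and the last seven measurements (so that the
#' moving-window analysis can observe the pre-injury period), and (b) no
#' measured factor is missing on more than `max_missing` of the player's
#' occasions (strictly more than the threshold excludes). An occasion
#' counts as missing for a factor when no non-missing value of that factor
#' was recorded on it.
#'
#' @param cohort A `"dc_cohort"` object.
#' @param max_missing Maximum tolerated per-factor missing fraction
#'   (default 0.20).
#' @param dc_window Dynamic complexity window length (default 7); injuries
#'   with an onset before this occasion cannot be analysed.
#' @return A list with `included` (a `"dc_cohort"` restricted to the
#'   retained players) and `report` (a data.frame with one row per player:
#'   `player_id`, `included`, `rule`, `detail`).
#' @examples
#' cohort <- generate_cohort(sim_config(n_players = 3,
#'                                      series_length_range = c(60, 80),
#'                                      seed = 3))
#' sel <- select_players(cohort)
#' sel$report
#' @export
select_players <- function(cohort, max_missing = 0.2, dc_window = 7) {
  stopifnot(inherits(cohort, "dc_cohort"), length(cohort$tables) > 0)
  report <- lapply(names(cohort$tables), function(id) {
    tab <- cohort$tables[[id]]
    T <- max(tab$occasion)
    inj <- cohort$injuries[cohort$injuries$player_id == id, , drop = FALSE]
    ok_a <- any(inj$onset_occasion >= dc_window & inj$onset_occasion <= T - 7)
    miss <- vapply(split(tab, tab$factor), function(ft) {
      present <- unique(ft$occasion[!is.na(ft$value)])
      1 - length(present) / T
    }, numeric(1))
    bad <- names(miss)[miss > max_missing]
    rule <- if (!ok_a) {
      "no_eligible_injury"
    } else if (length(bad) > 0) {
      "excess_missingness"
    } else {
      ""
    }
    detail <- if (!ok_a) {
      sprintf("no injury onset in [%d, %d]", dc_window, T - 7)
    } else if (length(bad) > 0) {
      sprintf("%s missing %.0f%%", bad[1], 100 * miss[bad[1]])
    } else {
      ""
    }
    data.frame(player_id = id, included = ok_a && length(bad) == 0,
               rule = rule, detail = detail, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  keep <- report$player_id[report$included]
  included <- structure(list(
    tables = cohort$tables[keep],
    injuries = cohort$injuries[cohort$injuries$player_id %in% keep, ,
                               drop = FALSE],
    config = cohort$config
  ), class = "dc_cohort")
  list(included = included, report = report)
}

#' Impute missing raw values
#'
#' Default method: per-factor linear interpolation over the occasion index
#' with nearest-edge fill at the series boundaries. The method is
#' deterministic, keeps imputed values inside the raw scale bounds (a
#' convex combination of observed values), and is recorded in the output
#' attributes so downstream metadata can report it.
#'
#' @param table Long-format raw table.
#' @param method Imputation method; only `"linear"` is built in.
#' @return The table with no missing values; attribute
#'   `"imputation_method"` names the method.
#' @examples
#' tab <- data.frame(player_id = "P1", occasion = 1:3, session = 1L,
#'                   factor = "mood", value = c(40, NA, 60))
#' impute_missing(tab)$value  # 40 50 60
#' @export
impute_missing <- function(table, method = "linear") {
  method <- match.arg(method, "linear")
  for (f in unique(table$factor)) {
    idx <- which(table$factor == f)
    v <- table$value[idx]
    if (!anyNA(v)) next
    obs <- !is.na(v)
    if (!any(obs)) {
      stop("factor '", f, "' is entirely missing; cannot impute")
    }
    x <- table$occasion[idx]
    if (length(unique(x[obs])) >= 2) {
      fill <- approx(x[obs], v[obs], xout = x[!obs], rule = 2,
                     ties = mean)$y
    } else {
      fill <- mean(v[obs])
    }
    v[!obs] <- fill
    table$value[idx] <- v
  }
  attr(table, "imputation_method") <- method
  table
}

.sum_factors <- c("distance", "sprints", "duration", "hr_zone5")
.once_factors <- c("recovery", "self_efficacy", "motivation", "mood",
                   "perceived_performance", "enjoyment")

#' Build daily analysis factors (including the session RPE load)
#'
#' Collapses a session-level raw table to one row per occasion and factor.
#' The internal training load is `srpe = RPE x session duration (minutes)`
#' per session; when an occasion has several sessions, `srpe`, `distance`,
#' `sprints`, `duration` and heart-rate-zone-5 seconds are summed to the
#' daily total, while the single-administration self-reports (recovery,
#' self-efficacy, motivation, mood, perceived performance, enjoyment) are
#' averaged if duplicated. The raw `exertion` factor is consumed by `srpe`
#' and does not appear in the output.
#'
#' @param table Long-format raw table with no missing values.
#' @return Long-format table with exactly one row per (occasion, factor).
#' @examples
#' tab <- data.frame(player_id = "P1", occasion = 1L, session = c(1L, 1L),
#'                   factor = c("exertion", "duration"), value = c(15, 60))
#' build_daily_factors(tab)  # srpe = 900, duration = 60
#' @export
build_daily_factors <- function(table) {
  facs <- unique(table$factor)
  out <- list()
  daily <- function(f, fun) {
    ft <- table[table$factor == f, ]
    agg <- tapply(ft$value, ft$occasion, fun)
    data.frame(player_id = ft$player_id[1],
               occasion = as.integer(names(agg)), session = 1L,
               factor = f, value = as.numeric(agg),
               stringsAsFactors = FALSE)
  }
  for (f in intersect(.sum_factors, facs)) {
    out[[f]] <- daily(f, sum)
  }
  for (f in intersect(.once_factors, facs)) {
    out[[f]] <- daily(f, mean)
  }
  if ("exertion" %in% facs) {
    rpe <- table[table$factor == "exertion", ]
    dur <- table[table$factor == "duration", ]
    key <- function(d) paste(d$occasion, d$session, sep = "/")
    mdur <- dur$value[match(key(rpe), key(dur))]
    if (anyNA(mdur)) {
      bad <- rpe$occasion[is.na(mdur)]
      stop("RPE recorded without a matching session duration at occasion(s) ",
           paste(unique(bad), collapse = ", "),
           "; cannot compute the session RPE load")
    }
    srpe <- data.frame(occasion = rpe$occasion, value = rpe$value * mdur)
    agg <- tapply(srpe$value, srpe$occasion, sum)
    out[["srpe"]] <- data.frame(player_id = rpe$player_id[1],
                                occasion = as.integer(names(agg)),
                                session = 1L, factor = "srpe",
                                value = as.numeric(agg),
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$occasion, res$factor), ]
  rownames(res) <- NULL
  res
}

#' Normalize factors onto their analysis scales
#'
#' Maps each factor onto its normalized analysis scale: VAS self-reports
#' are divided by 100 (range 0--1), CRS self-reports by 20 (range
#' 0.3--1.0), and sensor-derived factors (and `srpe`) by the maximum value
#' of that factor for this player (range 0--1). The result is the
#' occasion-by-factor matrix the dynamic complexity analysis runs on.
#'
#' @param table Complete long-format daily table (one row per occasion and
#'   factor, no missing values; see [build_daily_factors()]).
#' @param specs Scale specifications ([default_scale_specs()]).
#' @param injuries Optional injury log rows for this player (columns
#'   `onset_occasion`, `time_loss_occasions`, ...).
#' @param factor_set Factors to keep, in analysis order; defaults to the
#'   intersection of [default_factor_set()] with the factors present.
#' @return An object of class `"athlete_series"`: list with `player_id`,
#'   `values` (T x V matrix of normalized values), `specs` (the matching
#'   spec rows), `injured_mask` (logical per occasion) and `injuries`.
#' @export
normalize_factors <- function(table, specs = default_scale_specs(),
                              injuries = NULL, factor_set = NULL) {
  if (is.null(factor_set)) {
    factor_set <- intersect(default_factor_set(), unique(table$factor))
  }
  missing_fac <- setdiff(factor_set, unique(table$factor))
  if (length(missing_fac) > 0) {
    stop("table lacks factor(s): ", paste(missing_fac, collapse = ", "))
  }
  sp <- spec_rows(specs, factor_set)
  T <- max(table$occasion)
  vals <- matrix(NA_real_, nrow = T, ncol = length(factor_set),
                 dimnames = list(NULL, factor_set))
  for (k in seq_along(factor_set)) {
    f <- factor_set[k]
    ft <- table[table$factor == f, ]
    agg <- tapply(ft$value, ft$occasion, mean)
    vals[as.integer(names(agg)), k] <- as.numeric(agg)
    if (anyNA(vals[, k])) {
      stop("factor '", f, "' is incomplete (occasions without a value); ",
           "impute before normalizing")
    }
    vals[, k] <- switch(sp$normalization[k],
      divide_by_100 = vals[, k] / 100,
      divide_by_20 = vals[, k] / 20,
      divide_by_individual_max = {
        mx <- max(vals[, k])
        if (mx <= 0) {
          stop("factor '", f, "' has no positive values; the individual ",
               "maximum normalization is undefined")
        }
        vals[, k] / mx
      },
      stop("unknown normalization rule ", sp$normalization[k])
    )
  }
  injured_mask <- rep(FALSE, T)
  if (!is.null(injuries) && nrow(injuries) > 0) {
    for (k in seq_len(nrow(injuries))) {
      span <- injuries$onset_occasion[k]:
        min(T, injuries$onset_occasion[k] +
              max(injuries$time_loss_occasions[k], 1L) - 1L)
      injured_mask[span[span >= 1 & span <= T]] <- TRUE
    }
  }
  structure(list(player_id = as.character(table$player_id[1]),
                 values = vals, specs = sp,
                 injured_mask = injured_mask,
                 injuries = injuries),
            class = "athlete_series")
}

#' @export
print.athlete_series <- function(x, ...) {
  cat("Athlete series", x$player_id, ":", nrow(x$values), "occasions x",
      ncol(x$values), "factors;", sum(x$injured_mask), "injured occasions\n")
  invisible(x)
}

#' Preprocess one player's raw table into a normalized series
#'
#' Convenience wrapper chaining [impute_missing()],
#' [build_daily_factors()] and [normalize_factors()].
#'
#' @inheritParams impute_missing
#' @inheritParams normalize_factors
#' @return An `"athlete_series"` object.
#' @export
preprocess_player <- function(table, injuries = NULL, method = "linear",
                              specs = default_scale_specs(),
                              factor_set = NULL) {
  table <- impute_missing(table, method = method)
  table <- build_daily_factors(table)
  normalize_factors(table, specs = specs, injuries = injuries,
                    factor_set = factor_set)
}
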