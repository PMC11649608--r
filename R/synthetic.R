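#' Simulation configuration for a synthetic monitoring cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. The defaults
#' emulate the shape of a two-season professional youth football monitoring
#' data set: 23 players with 155--430 measurement occasions each, eleven
#' monitoring factors on their native scales, sparse injuries (about 0.83
#' per 100 occasions, i.e. roughly 2.8 injuries per player over a full
#' series), up to 20% missingness, and a destabilization (critical
#' fluctuation) window injected before a configurable fraction of injuries.
#'
#' @param n_players Number of players to simulate.
#' @param series_length_range Integer vector `c(min, max)`; each player's
#'   series length is drawn uniformly from this range. The minimum must be
#'   at least 15 so that the dynamic complexity window and the leading and
#'   trailing exclusion margins fit.
#' @param factor_set Raw factor names to generate (see
#'   [default_raw_factor_set()]).
#' @param injury_rate Expected injuries per 100 measurement occasions.
#' @param time_loss_range Integer `c(min, max)`: occasions flagged as
#'   injured per injury, starting at the onset occasion.
#' @param destabilization_fraction Proportion of injuries preceded by an
#'   injected turbulence window, in `[0, 1]`.
#' @param destabilization_lead Length (occasions) of the injected window,
#'   which spans `[onset - lead, onset - 1]`.
#' @param destabilization_gain Multiplier `>= 1` on the oscillation
#'   amplitude; `1` leaves the series untouched.
#' @param affected_factor_count Number of factors perturbed per
#'   destabilized injury.
#' @param missing_rate Probability that any raw value is missing (missing
#'   completely at random), in `[0, 1)`.
#' @param baseline_autocorr AR(1) coefficient of the baseline factor
#'   dynamics, in `(-1, 1)`.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   seed.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_players = 2, series_length_range = c(60, 80), seed = 1)
#' @export
sim_config <- function(n_players = 23,
                       series_length_range = c(155, 430),
                       factor_set = default_raw_factor_set(),
                       injury_rate = 0.83,
                       time_loss_range = c(1, 15),
                       destabilization_fraction = 0.3,
                       destabilization_lead = 6,
                       destabilization_gain = 6,
                       affected_factor_count = 4,
                       missing_rate = 0.1,
                       baseline_autocorr = 0.4,
                       seed = 1L) {
  stopifnot(length(n_players) == 1, n_players >= 1,
            length(series_length_range) == 2,
            length(injury_rate) == 1, injury_rate >= 0,
            length(time_loss_range) == 2, time_loss_range[1] >= 0,
            time_loss_range[2] >= time_loss_range[1],
            length(seed) == 1, is.finite(seed))
  if (series_length_range[1] < 15) {
    stop("series_length_range minimum must be >= 15: the dynamic complexity ",
         "window plus the 7-occasion leading and trailing exclusion margins ",
         "must fit in every series")
  }
  if (series_length_range[2] < series_length_range[1]) {
    stop("series_length_range must be increasing")
  }
  if (destabilization_fraction < 0 || destabilization_fraction > 1) {
    stop("destabilization_fraction must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (destabilization_gain < 1) stop("destabilization_gain must be >= 1")
  if (destabilization_lead < 1) stop("destabilization_lead must be >= 1")
  if (abs(baseline_autocorr) >= 1) {
    stop("baseline_autocorr must lie in (-1, 1)")
  }
  if (affected_factor_count < 1 || affected_factor_count > length(factor_set)) {
    stop("affected_factor_count must be between 1 and the number of factors")
  }
  structure(list(
    n_players = as.integer(n_players),
    series_length_range = as.integer(series_length_range),
    factor_set = factor_set,
    injury_rate = injury_rate,
    time_loss_range = as.integer(time_loss_range),
    destabilization_fraction = destabilization_fraction,
    destabilization_lead = as.integer(destabilization_lead),
    destabilization_gain = destabilization_gain,
    affected_factor_count = as.integer(affected_factor_count),
    missing_rate = missing_rate,
    baseline_autocorr = baseline_autocorr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# stationary mean / sd of the baseline AR(1) process per raw factor
.gen_params <- function() {
  data.frame(
    factor = c("recovery", "self_efficacy", "motivation", "mood", "exertion",
               "perceived_performance", "enjoyment",
               "distance", "sprints", "duration", "hr_zone5"),
    mu = c(14, 70, 72, 70, 13, 65, 70, 5200, 10, 75, 300),
    sigma = c(2, 12, 11, 12, 2.5, 13, 12, 1400, 4, 15, 150),
    stringsAsFactors = FALSE
  )
}

.session_factors <- c("exertion", "distance", "sprints", "duration", "hr_zone5")

# bounded AR(1) path of length T
.ar1_path <- function(T, mu, sigma, phi, lo, hi) {
  innov_sd <- sigma * sqrt(1 - phi^2)
  x <- numeric(T)
  x[1] <- rnorm(1, mu, sigma)
  for (t in seq_len(T)[-1]) {
    x[t] <- mu + phi * (x[t - 1] - mu) + rnorm(1, 0, innov_sd)
  }
  clip(x, lo, hi)
}

# place n non-overlapping injury periods, onsets restricted to [8, T - 7]
.place_injuries <- function(n, T, time_loss_range) {
  if (T - 7 < 8) {
    stop("series of length ", T, " is too short to place injuries: ",
         "onsets must lie between occasion 8 and occasion T - 7")
  }
  onsets <- integer(0)
  losses <- integer(0)
  occupied <- logical(T)
  attempts <- 0L
  while (length(onsets) < n && attempts < 60L * n) {
    attempts <- attempts + 1L
    onset <- sample(8:(T - 7), 1)
    loss <- sample(time_loss_range[1]:time_loss_range[2], 1)
    span <- onset:min(T, onset + max(loss, 1L) - 1L)
    if (!any(occupied[span]) && !occupied[onset]) {
      occupied[span] <- TRUE
      onsets <- c(onsets, onset)
      losses <- c(losses, min(loss, T - onset + 1L))
    }
  }
  ord <- order(onsets)
  data.frame(onset_occasion = onsets[ord], time_loss_occasions = losses[ord])
}

#' Generate a synthetic monitoring cohort
#'
#' Simulates raw long-format monitoring tables and an injury log with the
#' statistical structure the downstream analysis assumes. Each factor
#' follows a bounded AR(1) process on its raw scale (VAS 0--100, CRS 6--20,
#' sensor factors non-negative); session-level factors are occasionally
#' split across two sessions per occasion. Injuries are placed uniformly at
#' random, excluding the first seven and last seven occasions and avoiding
#' overlapping injury periods; a configurable fraction of them is preceded
#' by an injected destabilization window (see [inject_destabilization()]).
#' Missingness is applied last, completely at random.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"dc_cohort"`: a list with `tables` (named
#'   list of long-format data.frames with columns `player_id`, `occasion`,
#'   `session`, `factor`, `value`), `injuries` (data.frame with columns
#'   `player_id`, `onset_occasion`, `time_loss_occasions`, `mechanism`,
#'   plus generator ground truth `destabilized` and `affected_factors`),
#'   and the `config`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_players = 2,
#'                                      series_length_range = c(40, 60),
#'                                      seed = 7))
#' names(cohort$tables)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gen <- .gen_params()
  specs <- default_scale_specs()
  phi <- config$baseline_autocorr
  ids <- sprintf("P%02d", seq_len(config$n_players))
  tables <- vector("list", config$n_players)
  names(tables) <- ids
  injury_rows <- list()

  for (p in seq_len(config$n_players)) {
    T <- if (config$series_length_range[1] == config$series_length_range[2]) {
      config$series_length_range[1]
    } else {
      sample(config$series_length_range[1]:config$series_length_range[2], 1)
    }
    two_sessions <- runif(T) < 0.15
    rows <- list()
    for (f in config$factor_set) {
      g <- gen[gen$factor == f, ]
      sp <- specs[specs$factor == f, ]
      if (nrow(g) == 0) stop("no generation parameters for factor ", f)
      x <- .ar1_path(T, g$mu, g$sigma, phi, sp$raw_min, sp$raw_max)
      if (f == "sprints") x <- round(x)
      if (f %in% .session_factors) {
        # session-level factor: daily aggregate keeps the AR(1) structure
        if (f == "exertion") {
          v1 <- x
          v2 <- clip(x + rnorm(T, 0, 1), sp$raw_min, sp$raw_max)
        } else {
          v1 <- ifelse(two_sessions, 0.6 * x, x)
          v2 <- 0.4 * x
          if (f == "sprints") { v1 <- round(v1); v2 <- round(v2) }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          player_id = ids[p], occasion = seq_len(T), session = 1L,
          factor = f, value = v1, stringsAsFactors = FALSE)
        if (any(two_sessions)) {
          rows[[length(rows) + 1L]] <- data.frame(
            player_id = ids[p], occasion = which(two_sessions), session = 2L,
            factor = f, value = v2[two_sessions], stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          player_id = ids[p], occasion = seq_len(T), session = 1L,
          factor = f, value = x, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$occasion, tab$factor, tab$session), ]
    rownames(tab) <- NULL

    n_inj <- rpois(1, config$injury_rate / 100 * T)
    inj <- if (n_inj > 0) {
      .place_injuries(n_inj, T, config$time_loss_range)
    } else {
      data.frame(onset_occasion = integer(0), time_loss_occasions = integer(0))
    }
    if (nrow(inj) > 0) {
      inj$player_id <- ids[p]
      inj$mechanism <- sample(c("traumatic", "overuse"), nrow(inj),
                              replace = TRUE, prob = c(0.6, 0.4))
      inj$destabilized <- runif(nrow(inj)) < config$destabilization_fraction
      inj$affected_factors <- NA_character_
      for (k in seq_len(nrow(inj))) {
        if (!inj$destabilized[k]) next
        perturb <- sample(config$factor_set, config$affected_factor_count)
        inj$affected_factors[k] <- paste(perturb, collapse = ";")
        ev <- list(player_id = ids[p],
                   onset_occasion = inj$onset_occasion[k],
                   time_loss_occasions = inj$time_loss_occasions[k])
        tab <- inject_destabilization(tab, ev,
                                      lead = config$destabilization_lead,
                                      gain = config$destabilization_gain,
                                      factors = perturb)
      }
      injury_rows[[length(injury_rows) + 1L]] <-
        inj[, c("player_id", "onset_occasion", "time_loss_occasions",
                "mechanism", "destabilized", "affected_factors")]
    }
    if (config$missing_rate > 0) {
      tab <- apply_missingness(tab, config$missing_rate,
                               seed = sample.int(.Machine$integer.max, 1))
    }
    tables[[p]] <- tab
  }

  injuries <- if (length(injury_rows) > 0) {
    do.call(rbind, injury_rows)
  } else {
    data.frame(player_id = character(0), onset_occasion = integer(0),
               time_loss_occasions = integer(0), mechanism = character(0),
               destabilized = logical(0), affected_factors = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(injuries) <- NULL
  structure(list(tables = tables, injuries = injuries, config = config),
            class = "dc_cohort")
}

#' Inject a pre-injury destabilization window into a raw table
#'
#' Emulates the short window of critical fluctuations that complex-systems
#' theory places before a phase transition: within the `lead` occasions
#' before the injury onset, the selected factors oscillate with alternating
#' sign around their course, with an amplitude of `(gain - 1)` times the
#' factor's series standard deviation, clipped to the raw scale bounds.
#' `gain = 1` (or an empty factor selection) returns the table unchanged;
#' large gains approach full-scale alternation. Values outside the window
#' are untouched; missing values stay missing.
#'
#' @param table Long-format raw table (columns `player_id`, `occasion`,
#'   `session`, `factor`, `value`).
#' @param event A list or one-row data.frame with at least `onset_occasion`.
#' @param lead Window length; the window is `[onset - lead, onset - 1]` and
#'   is truncated (with a warning) if it would extend before occasion 1.
#' @param gain Amplitude multiplier, `>= 1`.
#' @param factors Character vector of factor names to perturb.
#' @param specs Scale specifications, for the raw clipping bounds.
#' @return The modified table.
#' @examples
#' cohort <- generate_cohort(sim_config(n_players = 1,
#'                                      series_length_range = c(40, 40),
#'                                      injury_rate = 0, seed = 2))
#' tab <- inject_destabilization(cohort$tables[[1]],
#'                               list(onset_occasion = 20), lead = 6,
#'                               gain = 8, factors = "mood")
#' @export
inject_destabilization <- function(table, event, lead, gain, factors,
                                   specs = default_scale_specs()) {
  stopifnot(lead >= 1, gain >= 1)
  if (length(factors) == 0 || gain == 1) return(table)
  onset <- as.integer(event$onset_occasion)
  win <- (onset - lead):(onset - 1L)
  if (any(win < 1L)) {
    warning("destabilization window truncated at occasion 1 (onset ", onset,
            ", lead ", lead, ")")
    win <- win[win >= 1L]
  }
  if (length(win) == 0) return(table)
  sp <- spec_rows(specs, factors)
  for (k in seq_along(factors)) {
    f <- factors[k]
    sel_f <- table$factor == f
    amp <- sd(table$value[sel_f], na.rm = TRUE)
    if (!is.finite(amp) || amp == 0) {
      span <- sp$raw_max[k] - sp$raw_min[k]
      amp <- if (is.finite(span)) span / 10 else 1
    }
    idx <- which(sel_f & table$occasion %in% win & !is.na(table$value))
    if (length(idx) == 0) next
    sign_t <- ifelse((onset - table$occasion[idx]) %% 2 == 0, 1, -1)
    table$value[idx] <- clip(table$value[idx] + (gain - 1) * amp * sign_t,
                             sp$raw_min[k], sp$raw_max[k])
  }
  table
}

#' Set values missing completely at random
#'
#' Each value is independently set missing with probability `rate`;
#' deterministic given the seed.
#'
#' @param table Long-format raw table.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with `NA` values inserted.
#' @export
apply_missingness <- function(table, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(table)
  set.seed(seed)
  table$value[runif(nrow(table)) < rate] <- NA_real_
  table
}

#' @export
print.dc_cohort <- function(x, ...) {
  lens <- vapply(x$tables, function(t) max(t$occasion), numeric(1))
  cat("Synthetic monitoring cohort:", length(x$tables), "players,",
      nrow(x$injuries), "injuries\n")
  cat("Series lengths:", min(lens), "-", max(lens), "occasions\n")
  invisible(x)
}

#' Write a cohort to long-format CSV files
#'
#' Writes `monitoring.csv` (columns `player_id`, `occasion`, `session`,
#' `factor`, `value`) and `injuries.csv` (columns `player_id`,
#' `onset_occasion`, `time_loss_occasions`, `mechanism`) into a directory.
#'
#' @param cohort A `"dc_cohort"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mon <- do.call(rbind, cohort$tables)
  rownames(mon) <- NULL
  f1 <- file.path(dir, "monitoring.csv")
  f2 <- file.path(dir, "injuries.csv")
  write.csv(mon, f1, row.names = FALSE)
  inj <- cohort$injuries
  write.csv(inj[, c("player_id", "onset_occasion", "time_loss_occasions",
                    "mechanism")], f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Read a cohort from long-format CSV files
#'
#' Counterpart of [write_cohort()]: reads `monitoring.csv` and
#' `injuries.csv` from a directory.
#'
#' @param dir Directory containing the two CSV files.
#' @return A `"dc_cohort"` object (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  mon <- read.csv(file.path(dir, "monitoring.csv"), stringsAsFactors = FALSE)
  inj <- read.csv(file.path(dir, "injuries.csv"), stringsAsFactors = FALSE)
  need <- c("player_id", "occasion", "session", "factor", "value")
  if (!all(need %in% names(mon))) {
    stop("monitoring.csv must have columns ", paste(need, collapse = ", "))
  }
  tables <- split(mon, mon$player_id)
  structure(list(tables = tables, injuries = inj, config = NULL),
            class = "dc_cohort")
}
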