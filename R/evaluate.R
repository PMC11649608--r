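#' Select the injuries eligible for the moving-window analysis
#'
#' Injuries with an onset before occasion `m` or within the last seven
#' occasions are excluded: a window of `m` data points can only capture
#' dynamic complexity changes in between.
#'
#' @param injuries Injury log rows for one player (column
#'   `onset_occasion`).
#' @param T Series length in occasions.
#' @param m Dynamic complexity window length (default 7).
#' @return The eligible subset of `injuries`.
#' @export
eligible_injuries <- function(injuries, T, m = 7) {
  if (is.null(injuries) || nrow(injuries) == 0) return(injuries)
  injuries[injuries$onset_occasion >= m &
             injuries$onset_occasion <= T - 7, , drop = FALSE]
}

#' Classify occasions into the warning-signal confusion counts
#'
#' Applies the counting rules of the proof-of-concept analysis for one
#' player. For each eligible injury, the pre-injury window is the `W`
#' occasions before the onset (the onset itself is excluded), minus any
#' occasions belonging to an earlier injury period. If at least one
#' cumulative complexity peak falls in that window the injury counts as a
#' single true positive (the remaining window occasions are left out); if
#' none does, it counts as a single false negative. All pre-injury window
#' occasions are removed from the negative pool in either case, as are all
#' injured occasions (turbulence is expected during an injury) and the
#' first `m - 1` occasions (the analysis starts on occasion `m`). Every
#' remaining occasion is a false positive if it carries a CCP and a true
#' negative otherwise.
#'
#' An injury whose pre-injury window lies entirely inside a previous
#' injury period is reported as unevaluable rather than silently counted.
#'
#' @param ccp A `"ccp_series"` for the player.
#' @param injuries Injury log rows for the player.
#' @param injured_mask Logical vector per occasion (TRUE during injury
#'   periods).
#' @param W Pre-injury window length in occasions, `>= 1`.
#' @param m Dynamic complexity window length (default 7).
#' @param player_id Optional identifier carried into the result.
#' @return An object of class `"dc_confusion"`: list with `player_id`,
#'   `tp`, `fp`, `tn`, `fn`, `W`, `eligible_injuries` (number evaluated),
#'   `unevaluable`, `excluded_occasions` (defined occasions excluded from
#'   the pool), `pool_size`, and `detail` (one row per eligible injury:
#'   onset, outcome, detection occasions).
#' @examples
#' ccp <- structure(list(count = c(rep(NA, 6), rep(0L, 24)),
#'                       ccp = c(rep(NA, 6), rep(FALSE, 24)),
#'                       alpha = 0.05, z_crit = qnorm(0.95),
#'                       baseline = "global"), class = "ccp_series")
#' ccp$ccp[c(10, 20)] <- TRUE
#' inj <- data.frame(onset_occasion = 24, time_loss_occasions = 3)
#' mask <- rep(FALSE, 30); mask[24:26] <- TRUE
#' classify_occasions(ccp, inj, mask, W = 6)
#' @export
classify_occasions <- function(ccp, injuries, injured_mask, W, m = 7,
                               player_id = NA_character_) {
  stopifnot(inherits(ccp, "ccp_series"), W >= 1)
  T <- length(ccp$count)
  stopifnot(length(injured_mask) == T)
  elig <- eligible_injuries(injuries, T, m)
  has_ccp <- function(occ) {
    occ <- occ[occ >= 1 & occ <= T]
    any(ccp$ccp[occ] %in% TRUE)
  }
  tp <- 0L; fn <- 0L
  unevaluable <- 0L
  window_occ <- integer(0)
  detail <- list()
  if (!is.null(elig) && nrow(elig) > 0) {
    elig <- elig[order(elig$onset_occasion), , drop = FALSE]
    for (k in seq_len(nrow(elig))) {
      onset <- elig$onset_occasion[k]
      win <- (onset - W):(onset - 1L)
      win <- win[win >= 1L]
      window_occ <- union(window_occ, win)
      win_eval <- win[!injured_mask[win]]
      outcome <- if (length(win_eval) == 0) {
        unevaluable <- unevaluable + 1L
        "unevaluable"
      } else if (has_ccp(win_eval)) {
        tp <- tp + 1L
        "TP"
      } else {
        fn <- fn + 1L
        "FN"
      }
      det <- win_eval[ccp$ccp[win_eval] %in% TRUE]
      detail[[k]] <- data.frame(
        player_id = player_id, onset_occasion = onset,
        outcome = outcome, n_window = length(win_eval),
        detections = paste(det, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  pool <- setdiff(m:T, union(window_occ, which(injured_mask)))
  fp <- sum(ccp$ccp[pool] %in% TRUE)
  tn <- length(pool) - fp
  structure(list(
    player_id = player_id, tp = tp, fp = as.integer(fp),
    tn = as.integer(tn), fn = fn, W = as.integer(W),
    eligible_injuries = tp + fn, unevaluable = unevaluable,
    excluded_occasions = as.integer(length(m:T) - length(pool)),
    pool_size = length(pool),
    detail = if (length(detail) > 0) do.call(rbind, detail) else
      data.frame(player_id = character(0), onset_occasion = integer(0),
                 outcome = character(0), n_window = integer(0),
                 detections = character(0), stringsAsFactors = FALSE)
  ), class = "dc_confusion")
}

#' @export
print.dc_confusion <- function(x, ...) {
  cat(sprintf("Confusion counts (W = %d): TP %d  FP %d  TN %d  FN %d\n",
              x$W, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

.pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Per-player warning-signal metrics
#'
#' Sensitivity `= TP / (TP + FN)`, specificity `= TN / (TN + FP)` and
#' accuracy `= (TP + TN) / (TP + TN + FP + FN)`, each as a percentage.
#' A metric with a zero denominator is reported as `NA` and is excluded
#' from cohort averages.
#'
#' @param counts A `"dc_confusion"` object or a list of them.
#' @return A data.frame with one row per player: the four counts and the
#'   three metrics in percent.
#' @examples
#' # 19 detected of 64 injuries
#' x <- structure(list(player_id = "pooled", tp = 19L, fp = 0L, tn = 0L,
#'                     fn = 45L, W = 6L), class = "dc_confusion")
#' player_metrics(x)$sensitivity  # 29.6875
#' @export
player_metrics <- function(counts) {
  if (inherits(counts, "dc_confusion")) counts <- list(counts)
  rows <- lapply(counts, function(cc) {
    data.frame(
      player_id = cc$player_id, tp = cc$tp, fp = cc$fp, tn = cc$tn,
      fn = cc$fn,
      sensitivity = .pct(cc$tp, cc$tp + cc$fn),
      specificity = .pct(cc$tn, cc$tn + cc$fp),
      accuracy = .pct(cc$tp + cc$tn, cc$tp + cc$tn + cc$fp + cc$fn),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort summary of warning-signal performance
#'
#' Per-player sensitivity, specificity and accuracy are averaged
#' (unweighted) across the players for which they are defined
#' (individual-level analysis). Because the data are heavily imbalanced
#' (far more non-injury than injury occasions), a pooled group-level F1
#' score is also computed over the summed counts: precision
#' `= sum(TP) / (sum(TP) + sum(FP))`, recall `= sum(TP) / (sum(TP) +
#' sum(FN))`, `F1 = 2 * precision * recall / (precision + recall)`, with
#' `F1 = 0` when no true positives exist.
#'
#' @param counts A list of `"dc_confusion"` objects (one per player).
#' @return An object of class `"dc_metrics"`: list with `per_player` (the
#'   [player_metrics()] table), `mean_sensitivity`, `mean_specificity`,
#'   `mean_accuracy` (percent), `precision`, `recall`, `f1` (proportions),
#'   the summed counts, `n_players` and `W`.
#' @export
cohort_summary <- function(counts) {
  if (inherits(counts, "dc_confusion")) counts <- list(counts)
  stopifnot(length(counts) >= 1)
  pp <- player_metrics(counts)
  tp <- sum(pp$tp); fp <- sum(pp$fp); tn <- sum(pp$tn); fn <- sum(pp$fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (tp == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    per_player = pp,
    mean_sensitivity = mean(pp$sensitivity, na.rm = TRUE),
    mean_specificity = mean(pp$specificity, na.rm = TRUE),
    mean_accuracy = mean(pp$accuracy, na.rm = TRUE),
    precision = precision, recall = recall, f1 = f1,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_players = nrow(pp), W = counts[[1]]$W
  ), class = "dc_metrics")
}

#' @export
print.dc_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Cohort of %d players (W = %d):\n",
    "  mean sensitivity %.1f%%  mean specificity %.1f%%  mean accuracy %.1f%%\n",
    "  pooled precision %.3f  recall %.3f  F1 %.3f\n"),
    x$n_players, x$W, x$mean_sensitivity, x$mean_specificity,
    x$mean_accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Stepwise search for the optimal pre-injury window
#'
#' Evaluates the cohort metrics for pre-injury windows `W = 1, 2, ...` and
#' applies the stepwise stopping rule: the window is increased as long as
#' the objective improves; at the first `W` that does not improve on
#' `W - 1`, the previous window is the optimum. The default objective is
#' cohort mean sensitivity; exact ties on the objective are broken by a
#' strictly higher cohort mean specificity, and otherwise the smaller
#' window wins. The metrics table is computed for the whole range so the
#' search path can be inspected.
#'
#' @param players A list, one element per player, each a list with
#'   components `ccp` (a `"ccp_series"`), `injuries` and `injured_mask`.
#' @param w_range Candidate windows (default `1:10`).
#' @param objective `"sensitivity"`, `"f1"` or `"accuracy"`.
#' @param m Dynamic complexity window length.
#' @return An object of class `"ews_window_search"`: list with `table`
#'   (per-W cohort metrics), `chosen` (the optimum W), `objective` and
#'   `trace` (per-step improvement flags up to the stop).
#' @export
optimize_ews_window <- function(players, w_range = 1:10,
                                objective = c("sensitivity", "f1",
                                              "accuracy"),
                                m = 7) {
  objective <- match.arg(objective)
  stopifnot(length(w_range) >= 1)
  w_range <- sort(unique(as.integer(w_range)))
  summaries <- lapply(w_range, function(W) {
    counts <- lapply(players, function(p) {
      classify_occasions(p$ccp, p$injuries, p$injured_mask, W = W, m = m,
                         player_id = p$player_id %||% NA_character_)
    })
    cohort_summary(counts)
  })
  tab <- do.call(rbind, lapply(seq_along(w_range), function(k) {
    s <- summaries[[k]]
    data.frame(W = w_range[k],
               mean_sensitivity = s$mean_sensitivity,
               mean_specificity = s$mean_specificity,
               mean_accuracy = s$mean_accuracy,
               precision = s$precision, recall = s$recall, f1 = s$f1,
               tp = s$tp, fp = s$fp, tn = s$tn, fn = s$fn)
  }))
  obj <- switch(objective,
                sensitivity = tab$mean_sensitivity,
                f1 = tab$f1,
                accuracy = tab$mean_accuracy)
  obj[is.na(obj)] <- -Inf
  tie <- tab$mean_specificity
  tie[is.na(tie)] <- -Inf
  eps <- 1e-9
  chosen_idx <- 1L
  improved <- logical(length(w_range))
  improved[1] <- TRUE
  for (k in seq_along(w_range)[-1]) {
    better <- obj[k] > obj[k - 1] + eps ||
      (abs(obj[k] - obj[k - 1]) <= eps && tie[k] > tie[k - 1] + eps)
    improved[k] <- better
    if (!better) break
    chosen_idx <- k
  }
  structure(list(table = tab, chosen = w_range[chosen_idx],
                 objective = objective,
                 trace = data.frame(W = w_range, objective = obj,
                                    improved = improved)),
            class = "ews_window_search")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ews_window_search <- function(x, ...) {
  cat("Pre-injury window search (objective:", x$objective,
      ") chose W =", x$chosen, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Attribute true-positive warning signals to factors
#'
#' For every true-positive injury of one player, the factors showing a
#' significant dynamic complexity peak on the CCP occasion(s) inside its
#' pre-injury window are collected; each contributes to a per-factor
#' count, and the injury is labelled by the categories of its contributing
#' factors: `psychological-only` (all psychological self-reports),
#' `sensor-only`, `physiological-only` (physiological self-reports and/or
#' sensors), `self-report-only` (psychological and physiological
#' self-reports, no sensors) or `combination` otherwise.
#'
#' @param peaks A `"peak_matrix"` for the player.
#' @param ccp The matching `"ccp_series"` (unused beyond validation; the
#'   detection occasions come from `confusion`).
#' @param confusion A `"dc_confusion"` from [classify_occasions()].
#' @param specs Scale specifications supplying the category axes.
#' @return An object of class `"dc_attribution"`: list with
#'   `factor_counts` (factor, count, category, source) and
#'   `injury_labels` (one row per true-positive injury).
#' @export
attribute_factors <- function(peaks, ccp, confusion,
                              specs = default_scale_specs()) {
  stopifnot(inherits(peaks, "peak_matrix"), inherits(confusion,
                                                     "dc_confusion"))
  facs <- colnames(peaks$values)
  sp <- spec_rows(specs, facs)
  counts <- setNames(integer(length(facs)), facs)
  labels <- list()
  det <- confusion$detail
  tp_rows <- which(det$outcome == "TP")
  for (k in tp_rows) {
    occ <- as.integer(strsplit(det$detections[k], ";")[[1]])
    pm <- peaks$values[occ, , drop = FALSE]
    pm[is.na(pm)] <- FALSE
    contrib <- facs[colSums(pm) > 0]
    counts[contrib] <- counts[contrib] + 1L
    cat_f <- sp$category[match(contrib, facs)]
    src_f <- sp$source[match(contrib, facs)]
    label <- if (length(contrib) == 0) {
      "none"
    } else if (all(cat_f == "psychological")) {
      "psychological-only"
    } else if (all(src_f == "sensor")) {
      "sensor-only"
    } else if (all(cat_f == "physiological")) {
      "physiological-only"
    } else if (all(src_f == "self_report")) {
      "self-report-only"
    } else {
      "combination"
    }
    labels[[length(labels) + 1L]] <- data.frame(
      player_id = confusion$player_id,
      onset_occasion = det$onset_occasion[k],
      label = label, factors = paste(contrib, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  structure(list(
    factor_counts = data.frame(factor = facs, count = as.integer(counts),
                               category = sp$category, source = sp$source,
                               stringsAsFactors = FALSE),
    injury_labels = if (length(labels) > 0) do.call(rbind, labels) else
      data.frame(player_id = character(0), onset_occasion = integer(0),
                 label = character(0), factors = character(0),
                 stringsAsFactors = FALSE)
  ), class = "dc_attribution")
}
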