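#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the simulation (or input
#' directory), the inclusion threshold, the dynamic complexity window, the
#' significance level and z-test baseline, the pre-injury window (fixed or
#' searched), the search objective and the imputation method.
#'
#' @param simulation A [sim_config()] used when `input_dir` is `NULL`.
#' @param input_dir Directory with `monitoring.csv` and `injuries.csv`
#'   (see [read_cohort()]); overrides `simulation`.
#' @param out_dir Optional output directory; when given, all artifacts are
#'   written there (see [run_pipeline()]).
#' @param dc_window Moving-window length `m` (default 7, must be `>= 2`).
#' @param alpha One-sided significance level for both z-tests.
#' @param baseline z-test baseline, `"global"` or `"running"` (see
#'   [significant_dc_peaks()]).
#' @param ews_window `"auto"` (stepwise search over `1:10`) or a fixed
#'   integer in `1:10`.
#' @param objective Search objective (see [optimize_ews_window()]).
#' @param imputation Imputation method (see [impute_missing()]).
#' @param factor_set Factors entering the analysis.
#' @param max_missing Inclusion threshold on per-factor missingness.
#' @param seed Optional integer; when given it overrides the simulation
#'   seed so one configuration can be replayed under several seeds.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            input_dir = NULL,
                            out_dir = NULL,
                            dc_window = 7,
                            alpha = 0.05,
                            baseline = c("global", "running"),
                            ews_window = "auto",
                            objective = "sensitivity",
                            imputation = "linear",
                            factor_set = default_factor_set(),
                            max_missing = 0.2,
                            seed = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(dc_window >= 2, alpha > 0, alpha < 1)
  if (!identical(ews_window, "auto")) {
    ews_window <- as.integer(ews_window)
    if (ews_window < 1 || ews_window > 10) {
      stop("a fixed ews_window must lie in 1..10")
    }
  }
  if (!is.null(seed) && !is.null(simulation)) {
    simulation$seed <- as.integer(seed)
  }
  structure(list(simulation = simulation, input_dir = input_dir,
                 out_dir = out_dir, dc_window = as.integer(dc_window),
                 alpha = alpha, baseline = baseline,
                 ews_window = ews_window, objective = objective,
                 imputation = imputation, factor_set = factor_set,
                 max_missing = max_missing),
            class = "pipeline_config")
}

#' Run the full early-warning-signal pipeline
#'
#' Executes, in order: cohort simulation (or CSV input), inclusion
#' criteria, imputation, daily factor construction, normalization, moving
#' -window dynamic complexity, per-factor peak detection, cumulative
#' complexity peaks, the pre-injury window search (or a fixed window),
#' per-player confusion counts, cohort metrics and factor attribution.
#' Identical configuration and seed give identical outputs.
#'
#' When `config$out_dir` is set, the run writes: `monitoring.csv` and
#' `injuries.csv` (the raw cohort), `exclusion_report.csv`,
#' `resonance.csv` (long-format DC/peak/CCP table for all included
#' players, the data behind a complexity resonance diagram and critical
#' instability plot), `window_search.csv`, `confusion.csv`,
#' `attribution.csv`, `metrics.json` and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `"dc_pipeline_result"`: list with `cohort`,
#'   `report` (exclusions), `series`, `dc`, `peaks`, `ccp` (per included
#'   player), `window_search` (`NULL` for a fixed window), `W`,
#'   `confusion`, `metrics`, `attribution` and `config`.
#' @examples
#' cfg <- pipeline_config(simulation = sim_config(
#'   n_players = 3, series_length_range = c(60, 80), seed = 11))
#' res <- run_pipeline(cfg)
#' res$metrics
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- config$dc_window

  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    generate_cohort(config$simulation)
  }
  sel <- select_players(cohort, max_missing = config$max_missing,
                        dc_window = m)
  included <- sel$included
  ids <- names(included$tables)

  result <- list(cohort = cohort, report = sel$report, series = list(),
                 dc = list(), peaks = list(), ccp = list(),
                 window_search = NULL, W = NA_integer_, confusion = list(),
                 metrics = NULL, attribution = NULL, config = config)
  class(result) <- "dc_pipeline_result"

  if (length(ids) == 0) {
    if (!is.null(config$out_dir)) .write_outputs(result, empty = TRUE)
    return(result)
  }

  for (id in ids) {
    inj <- included$injuries[included$injuries$player_id == id, ,
                             drop = FALSE]
    series <- tryCatch(
      preprocess_player(included$tables[[id]], injuries = inj,
                        method = config$imputation,
                        factor_set = config$factor_set),
      error = function(e) stop("preprocessing failed for player ", id, ": ",
                               conditionMessage(e)))
    dc <- dynamic_complexity_series(series, m = m)
    peaks <- significant_dc_peaks(dc, alpha = config$alpha,
                                  baseline = config$baseline)
    ccp <- detect_ccp(cumulative_peak_count(peaks), alpha = config$alpha,
                      baseline = config$baseline)
    result$series[[id]] <- series
    result$dc[[id]] <- dc
    result$peaks[[id]] <- peaks
    result$ccp[[id]] <- ccp
  }

  players <- lapply(ids, function(id) {
    list(player_id = id, ccp = result$ccp[[id]],
         injuries = included$injuries[included$injuries$player_id == id, ,
                                      drop = FALSE],
         injured_mask = result$series[[id]]$injured_mask)
  })

  if (identical(config$ews_window, "auto")) {
    search <- optimize_ews_window(players, w_range = 1:10,
                                  objective = config$objective, m = m)
    result$window_search <- search
    result$W <- search$chosen
  } else {
    result$W <- config$ews_window
  }

  result$confusion <- lapply(players, function(p) {
    classify_occasions(p$ccp, p$injuries, p$injured_mask, W = result$W,
                       m = m, player_id = p$player_id)
  })
  names(result$confusion) <- ids
  result$metrics <- cohort_summary(result$confusion)

  attrib <- lapply(ids, function(id) {
    attribute_factors(result$peaks[[id]], result$ccp[[id]],
                      result$confusion[[id]])
  })
  fc <- attrib[[1]]$factor_counts
  if (length(attrib) > 1) {
    for (a in attrib[-1]) fc$count <- fc$count + a$factor_counts$count
  }
  result$attribution <- list(
    factor_counts = fc[order(-fc$count), ],
    injury_labels = do.call(rbind, lapply(attrib, `[[`, "injury_labels")))

  if (!is.null(config$out_dir)) .write_outputs(result)
  result
}

#' @export
print.dc_pipeline_result <- function(x, ...) {
  cat("Early-warning-signal pipeline:", length(x$series),
      "players analysed (of", nrow(x$report), ")\n")
  if (!is.null(x$metrics)) {
    cat("Chosen pre-injury window W =", x$W, "\n")
    print(x$metrics)
  } else {
    cat("No players passed the inclusion criteria.\n")
  }
  invisible(x)
}

#' Export the data behind a complexity resonance diagram
#'
#' Produces the long-format table that the resonance diagram (DC heat map)
#' and critical instability plot (significant peaks and CCPs) are drawn
#' from: one row per defined occasion and factor with the DC value, the
#' per-factor peak flag and the occasion's CCP flag.
#'
#' @param dc A `"dc_matrix"`.
#' @param peaks The matching `"peak_matrix"`.
#' @param ccp The matching `"ccp_series"`.
#' @return A data.frame with columns `occasion`, `factor`, `dc`, `peak`,
#'   `ccp`.
#' @export
export_resonance_diagram <- function(dc, peaks, ccp) {
  x <- dc$values
  if (!identical(dim(peaks$values), dim(x)) ||
      length(ccp$count) != nrow(x)) {
    stop("dc, peaks and ccp have misaligned shapes")
  }
  facs <- colnames(x)
  if (is.null(facs)) facs <- paste0("V", seq_len(ncol(x)))
  def <- which(!is.na(x), arr.ind = TRUE)
  out <- data.frame(occasion = def[, 1], factor = facs[def[, 2]],
                    dc = x[def], peak = peaks$values[def],
                    ccp = ccp$ccp[def[, 1]], stringsAsFactors = FALSE)
  out[order(out$occasion, out$factor), , drop = FALSE]
}

#' Plot a complexity resonance diagram
#'
#' Renders the [export_resonance_diagram()] table as a heat map with peak
#' and CCP overlays. Requires ggplot2; purely cosmetic.
#'
#' @inheritParams export_resonance_diagram
#' @return A ggplot object.
#' @export
plot_resonance_diagram <- function(dc, peaks, ccp) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_resonance_diagram requires the ggplot2 package")
  }
  tab <- export_resonance_diagram(dc, peaks, ccp)
  occasion <- dc <- NULL # silence lints; columns of tab
  ggplot2::ggplot(tab, ggplot2::aes(x = occasion, y = factor)) +
    ggplot2::geom_tile(ggplot2::aes(fill = dc)) +
    ggplot2::geom_point(data = tab[tab$peak %in% TRUE, ],
                        shape = 0, size = 0.8) +
    ggplot2::geom_point(data = tab[tab$ccp %in% TRUE, ],
                        shape = 15, size = 0.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::labs(x = "measurement occasion", y = NULL, fill = "DC")
}

# write all pipeline artifacts; manifest carries config and version only
# (no timestamps) so identical runs produce identical files.
.write_outputs <- function(result, empty = FALSE) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, dir)
  write.csv(result$report, file.path(dir, "exclusion_report.csv"),
            row.names = FALSE)
  cfg <- result$config
  manifest <- list(
    package = "dcews",
    version = as.character(packageVersion("dcews")),
    dc_window = cfg$dc_window, alpha = cfg$alpha,
    baseline = cfg$baseline,
    ews_window = cfg$ews_window, objective = cfg$objective,
    imputation = cfg$imputation, factor_set = cfg$factor_set,
    max_missing = cfg$max_missing,
    seed = if (!is.null(cfg$simulation)) cfg$simulation$seed else NA,
    simulation = if (!is.null(cfg$simulation))
      unclass(cfg$simulation) else NULL,
    n_players_analysed = length(result$series),
    empty_result = empty
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (empty) {
    jsonlite::write_json(list(empty_result = TRUE),
                         file.path(dir, "metrics.json"), auto_unbox = TRUE)
    return(invisible(NULL))
  }
  res_tabs <- lapply(names(result$dc), function(id) {
    tab <- export_resonance_diagram(result$dc[[id]], result$peaks[[id]],
                                    result$ccp[[id]])
    cbind(player_id = id, tab)
  })
  write.csv(do.call(rbind, res_tabs), file.path(dir, "resonance.csv"),
            row.names = FALSE)
  if (!is.null(result$window_search)) {
    write.csv(result$window_search$table,
              file.path(dir, "window_search.csv"), row.names = FALSE)
  }
  write.csv(result$metrics$per_player, file.path(dir, "confusion.csv"),
            row.names = FALSE)
  write.csv(result$attribution$factor_counts,
            file.path(dir, "attribution.csv"), row.names = FALSE)
  met <- result$metrics
  jsonlite::write_json(list(
    W = result$W,
    mean_sensitivity = met$mean_sensitivity,
    mean_specificity = met$mean_specificity,
    mean_accuracy = met$mean_accuracy,
    precision = met$precision, recall = met$recall, f1 = met$f1,
    tp = met$tp, fp = met$fp, tn = met$tn, fn = met$fn,
    n_players = met$n_players
  ), file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
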