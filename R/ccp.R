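# one-sided z-test flags on a numeric vector; NA stays NA.
# baseline "global": mean/sd (n - 1) over the whole defined series.
# baseline "running": mean/sd over up to baseline_n most recent defined
# values strictly before each occasion; occasions with fewer than
# baseline_min history values are never flagged.
.z_flags <- function(x, z_crit, baseline = c("global", "running"),
                     baseline_n = 50L, baseline_min = 10L) {
  baseline <- match.arg(baseline)
  out <- rep(NA, length(x))
  def <- which(!is.na(x))
  if (length(def) == 0) return(out)
  if (baseline == "global") {
    mu <- mean(x[def])
    sdv <- sd(x[def])
    out[def] <- if (!is.finite(sdv) || sdv == 0) {
      FALSE
    } else {
      (x[def] - mu) / sdv > z_crit
    }
  } else {
    out[def] <- FALSE
    for (k in seq_along(def)) {
      hist_idx <- def[seq_len(k - 1L)]
      if (length(hist_idx) > baseline_n) {
        hist_idx <- hist_idx[(length(hist_idx) - baseline_n + 1L):
                               length(hist_idx)]
      }
      if (length(hist_idx) < baseline_min) next
      mu <- mean(x[hist_idx])
      sdv <- sd(x[hist_idx])
      if (!is.finite(sdv) || sdv == 0) next
      out[def[k]] <- (x[def[k]] - mu) / sdv > z_crit
    }
  }
  out
}

#' Flag significant dynamic complexity peaks per factor
#'
#' Applies a one-sided z-test per factor: an occasion is a peak when its DC
#' value lies more than `z_crit = qnorm(1 - alpha)` sample standard
#' deviations above the factor's mean (one-sided, because only *increased*
#' critical fluctuations are of interest). By default mean and standard
#' deviation are taken over the factor's entire defined DC series; the
#' `"running"` baseline instead standardizes each occasion against up to
#' `baseline_n` preceding defined values. A factor with zero variance
#' yields no peaks.
#'
#' @param dc A `"dc_matrix"` or a plain numeric matrix (occasions x
#'   factors, `NA` = undefined).
#' @param alpha One-sided significance level (default 0.05, `z_crit`
#'   1.645).
#' @param baseline `"global"` (default) or `"running"`.
#' @param baseline_n,baseline_min Running-baseline history length and the
#'   minimum history required before an occasion can be flagged.
#' @return An object of class `"peak_matrix"`: list with `values` (logical
#'   T x V, `NA` where DC undefined), `alpha`, `z_crit`, `baseline`.
#' @export
significant_dc_peaks <- function(dc, alpha = 0.05,
                                 baseline = c("global", "running"),
                                 baseline_n = 50L, baseline_min = 10L) {
  baseline <- match.arg(baseline)
  x <- if (inherits(dc, "dc_matrix")) dc$values else as.matrix(dc)
  if (all(is.na(x))) stop("all dynamic complexity values are undefined")
  if (all(colSums(!is.na(x)) < 2)) {
    stop("need at least 2 defined occasions to standardize")
  }
  z_crit <- qnorm(1 - alpha)
  flags <- apply(x, 2, .z_flags, z_crit = z_crit, baseline = baseline,
                 baseline_n = baseline_n, baseline_min = baseline_min)
  flags <- matrix(as.logical(flags), nrow = nrow(x),
                  dimnames = dimnames(x))
  structure(list(values = flags, alpha = alpha, z_crit = z_crit,
                 baseline = baseline),
            class = "peak_matrix")
}

#' Count simultaneous factor peaks per occasion
#'
#' @param peaks A `"peak_matrix"` or logical matrix.
#' @return Integer vector: number of factors flagged per occasion, `NA`
#'   where no factor is defined.
#' @export
cumulative_peak_count <- function(peaks) {
  x <- if (inherits(peaks, "peak_matrix")) peaks$values else as.matrix(peaks)
  cnt <- rowSums(x, na.rm = TRUE)
  cnt[rowSums(!is.na(x)) == 0] <- NA
  as.integer(cnt)
}

#' Detect cumulative complexity peaks (CCPs)
#'
#' The per-occasion count of simultaneous factor peaks forms a new time
#' series; a second one-sided z-test on this series flags the occasions on
#' which the number of simultaneous peaks is itself significantly
#' elevated. These cumulative complexity peaks are the early warning
#' signal evaluated against the injury log.
#'
#' @param count Integer vector from [cumulative_peak_count()] (or a
#'   `"peak_matrix"`, which is counted first).
#' @inheritParams significant_dc_peaks
#' @return An object of class `"ccp_series"`: list with `count`, `ccp`
#'   (logical per occasion), `alpha`, `z_crit`, `baseline`.
#' @export
detect_ccp <- function(count, alpha = 0.05,
                       baseline = c("global", "running"),
                       baseline_n = 50L, baseline_min = 10L) {
  baseline <- match.arg(baseline)
  if (inherits(count, "peak_matrix")) count <- cumulative_peak_count(count)
  if (sum(!is.na(count)) < 2) {
    stop("need at least 2 defined occasions to test for CCPs")
  }
  z_crit <- qnorm(1 - alpha)
  ccp <- .z_flags(as.numeric(count), z_crit, baseline = baseline,
                  baseline_n = baseline_n, baseline_min = baseline_min)
  structure(list(count = as.integer(count), ccp = ccp, alpha = alpha,
                 z_crit = z_crit, baseline = baseline),
            class = "ccp_series")
}

#' @export
print.ccp_series <- function(x, ...) {
  cat("CCP series:", length(x$count), "occasions,",
      sum(x$ccp, na.rm = TRUE), "cumulative complexity peaks (alpha =",
      x$alpha, ", baseline =", x$baseline, ")\n")
  invisible(x)
}
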