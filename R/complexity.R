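#' Fluctuation measure of a window
#'
#' The fluctuation measure F is sensitive to the amplitude and frequency of
#' change within a short window. The window is decomposed into maximal
#' monotone segments between turning points; each segment contributes the
#' absolute value change divided by its length in occasions, and the sum is
#' normalized by `s * (m - 1)`, where `s = norm_max - norm_min` is the
#' theoretical scale range. A constant window has `F = 0`; full-scale
#' alternation on every step has `F = 1`.
#'
#' A segment is a maximal run of same-direction (nonzero) steps. Plateaus
#' (runs of equal consecutive values) interior to such a run are absorbed
#' into it, diluting its slope; a plateau across which the direction
#' reverses -- and any leading or trailing plateau -- belongs to no
#' segment. This symmetric rule keeps every segment slope well defined and
#' makes F invariant under time reversal of the window.
#'
#' @param window Numeric vector of at least two values within the scale
#'   bounds.
#' @param norm_min,norm_max Theoretical scale bounds; their difference `s`
#'   must be positive.
#' @return F in `[0, 1]`.
#' @examples
#' fluctuation_measure(c(0, 1, 0, 1, 0, 1, 0))           # 1
#' fluctuation_measure(c(0, 0.5, 0.25, 0.75, 0.25, 1, 0)) # 3.5/6
#' @export
fluctuation_measure <- function(window, norm_min = 0, norm_max = 1) {
  m <- length(window)
  stopifnot(m >= 2, !anyNA(window))
  s <- norm_max - norm_min
  if (s <= 0) stop("scale range norm_max - norm_min must be positive")
  d <- diff(window)
  nz <- which(d != 0)
  if (length(nz) == 0) return(0)
  sg <- sign(d[nz])
  runs <- split(nz, cumsum(c(TRUE, sg[-1] != sg[-length(sg)])))
  acc <- 0
  for (r in runs) {
    a <- r[1]                  # start index of the run's first step
    b <- r[length(r)] + 1L     # end index of the run's last step
    acc <- acc + abs(window[b] - window[a]) / (b - a)
  }
  acc / (s * (m - 1))
}

#' Distribution measure of a window
#'
#' The distribution measure D quantifies how evenly the window's values are
#' scattered across the theoretical scale range. The sorted values are
#' compared against the ideal equidistant spread over the full scale: for
#' every pair `i < j` the ideal gap is `(j - i) * s / (m - 1)`; only
#' shortfalls below the ideal count as deviation, and
#' `D = 1 - sum(deviations) / sum(ideal gaps)`. A constant window has
#' `D = 0`; a full-range equidistant window has `D = 1`.
#'
#' @inheritParams fluctuation_measure
#' @return D in `[0, 1]`.
#' @examples
#' distribution_measure((0:6) / 6)           # 1
#' distribution_measure(c(rep(0, 6), 1))     # 0.375
#' @export
distribution_measure <- function(window, norm_min = 0, norm_max = 1) {
  m <- length(window)
  stopifnot(m >= 2, !anyNA(window))
  s <- norm_max - norm_min
  if (s <= 0) stop("scale range norm_max - norm_min must be positive")
  y <- sort(window)
  ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  ideal <- (ij[, 2] - ij[, 1]) * s / (m - 1)
  actual <- y[ij[, 2]] - y[ij[, 1]]
  1 - sum(pmax(0, ideal - actual)) / sum(ideal)
}

#' Dynamic complexity of a window
#'
#' `DC = F * D`, the product of [fluctuation_measure()] and
#' [distribution_measure()].
#'
#' @inheritParams fluctuation_measure
#' @return DC in `[0, 1]`.
#' @export
dynamic_complexity <- function(window, norm_min = 0, norm_max = 1) {
  fluctuation_measure(window, norm_min, norm_max) *
    distribution_measure(window, norm_min, norm_max)
}

#' Dynamic complexity of a multivariate series in a moving window
#'
#' Computes `DC = F x D` for every factor in an overlapping moving window
#' of `m` occasions with step one. The value of a window is assigned to its
#' last occasion, so the first `m - 1` occasions are undefined (`NA`) and
#' the analysis effectively starts on occasion `m`.
#'
#' @param series An `"athlete_series"` (whose scale specs supply the
#'   theoretical ranges) or a numeric matrix (occasions x factors).
#' @param m Window length, default 7.
#' @param norm_min,norm_max Scale bounds per factor (recycled), used when
#'   `series` is a plain matrix.
#' @param engine `"cpp"` (compiled moving-window kernel, default) or `"r"`
#'   (per-window calls to the R functions; slower, used for cross-checks).
#' @return An object of class `"dc_matrix"`: list with `player_id`, `m`,
#'   `values` (T x V matrix of DC), `F`, `D` (component matrices),
#'   `norm_min`, `norm_max` and `defined_from = m`.
#' @examples
#' x <- matrix(runif(60), ncol = 2)
#' dc <- dynamic_complexity_series(x, m = 7)
#' range(dc$values, na.rm = TRUE)
#' @export
dynamic_complexity_series <- function(series, m = 7, norm_min = 0,
                                      norm_max = 1,
                                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(series, "athlete_series")) {
    x <- series$values
    norm_min <- series$specs$norm_min
    norm_max <- series$specs$norm_max
    player_id <- series$player_id
  } else {
    x <- as.matrix(series)
    player_id <- NA_character_
  }
  V <- ncol(x)
  norm_min <- rep_len(norm_min, V)
  norm_max <- rep_len(norm_max, V)
  if (nrow(x) < m) {
    stop("series length (", nrow(x), ") is shorter than the window (", m, ")")
  }
  if (engine == "cpp") {
    fd <- .dc_fd_kernel(x, as.integer(m), norm_min, norm_max)
    F <- fd$F; D <- fd$D
  } else {
    T <- nrow(x)
    F <- matrix(NA_real_, T, V)
    D <- matrix(NA_real_, T, V)
    for (v in seq_len(V)) {
      for (t in m:T) {
        w <- x[(t - m + 1):t, v]
        if (anyNA(w)) next
        F[t, v] <- fluctuation_measure(w, norm_min[v], norm_max[v])
        D[t, v] <- distribution_measure(w, norm_min[v], norm_max[v])
      }
    }
  }
  dimnames(F) <- dimnames(D) <- dimnames(x)
  structure(list(player_id = player_id, m = as.integer(m),
                 values = F * D, F = F, D = D,
                 norm_min = norm_min, norm_max = norm_max,
                 defined_from = as.integer(m)),
            class = "dc_matrix")
}

#' @export
print.dc_matrix <- function(x, ...) {
  cat("Dynamic complexity matrix:", nrow(x$values), "occasions x",
      ncol(x$values), "factors, window m =", x$m, "\n")
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("Defined from occasion %d; DC range %.3f-%.3f\n",
              x$defined_from, rng[1], rng[2]))
  invisible(x)
}
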