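# Independent brute-force implementations used as oracles. These are kept
# deliberately naive and structurally different from the package code.

# Fluctuation oracle: collapse plateaus with rle(), then enumerate maximal
# runs of equal direction between distinct values. A run of directions
# j1..j2 spans window indices ends[j1] (last index of the plateau before
# its first step) through starts[j2 + 1] (first index of the plateau after
# its last step); reversal plateaus belong to no run.
oracle_fluctuation <- function(w, lo = 0, hi = 1) {
  m <- length(w)
  s <- hi - lo
  r <- rle(w)
  ends <- cumsum(r$lengths)          # last index of each plateau
  starts <- ends - r$lengths + 1     # first index of each plateau
  vals <- r$values
  if (length(vals) == 1) return(0)   # constant window
  dirs <- sign(diff(vals))           # direction between plateaus
  acc <- 0
  j <- 1
  while (j <= length(dirs)) {
    k <- j
    while (k < length(dirs) && dirs[k + 1] == dirs[j]) k <- k + 1
    a <- ends[j]
    b <- starts[k + 1]
    acc <- acc + abs(w[b] - w[a]) / (b - a)
    j <- k + 1
  }
  acc / (s * (m - 1))
}

# Distribution oracle: explicit double loop over all pairs of the sorted
# window.
oracle_distribution <- function(w, lo = 0, hi = 1) {
  m <- length(w)
  s <- hi - lo
  y <- sort(w)
  dev_sum <- 0
  ideal_sum <- 0
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      ideal <- (j - i) * s / (m - 1)
      short <- ideal - (y[j] - y[i])
      if (short > 0) dev_sum <- dev_sum + short
      ideal_sum <- ideal_sum + ideal
    }
  }
  1 - dev_sum / ideal_sum
}

# Occasion-by-occasion reference for the confusion counting rules.
oracle_classify <- function(ccp_flags, injuries, mask, W, m = 7) {
  T <- length(ccp_flags)
  onsets <- sort(injuries$onset_occasion)
  elig <- onsets[onsets >= m & onsets <= T - 7]
  tp <- fn <- unev <- 0L
  in_window <- rep(FALSE, T)
  for (o in elig) {
    hit <- FALSE
    n_eval <- 0L
    for (t in seq(o - W, o - 1)) {
      if (t < 1 || t > T) next
      in_window[t] <- TRUE
      if (mask[t]) next
      n_eval <- n_eval + 1L
      if (isTRUE(ccp_flags[t])) hit <- TRUE
    }
    if (n_eval == 0) {
      unev <- unev + 1L
    } else if (hit) {
      tp <- tp + 1L
    } else {
      fn <- fn + 1L
    }
  }
  fp <- tn <- 0L
  for (t in m:T) {
    if (mask[t] || in_window[t]) next
    if (isTRUE(ccp_flags[t])) fp <- fp + 1L else tn <- tn + 1L
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn, unevaluable = unev)
}

# Build a "ccp_series" object directly from a logical flag vector (NA and
# undefined before occasion m), bypassing the z-tests.
make_ccp <- function(flags, m = 7) {
  T <- length(flags)
  pre <- seq_len(T) < m
  cnt <- as.integer(flags)
  cnt[pre] <- NA_integer_
  flags[pre] <- NA
  structure(list(count = cnt, ccp = flags, alpha = 0.05,
                 z_crit = qnorm(0.95), baseline = "global"),
            class = "ccp_series")
}

# Bare confusion-count object for metric arithmetic tests.
make_counts <- function(tp, fp, tn, fn, id = "X", W = 6L) {
  structure(list(player_id = id, tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn), W = as.integer(W),
                 eligible_injuries = as.integer(tp + fn), unevaluable = 0L,
                 excluded_occasions = NA_integer_,
                 pool_size = as.integer(fp + tn),
                 detail = data.frame()),
            class = "dc_confusion")
}

# Small raw long-format table builder.
make_raw_table <- function(factor, values, id = "P1", session = 1L) {
  data.frame(player_id = id, occasion = seq_along(values),
             session = session, factor = factor, value = values,
             stringsAsFactors = FALSE)
}
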