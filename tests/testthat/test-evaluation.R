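test_that("injury eligibility excludes the first and last seven occasions", {
  inj <- data.frame(onset_occasion = c(5, 50, 96), time_loss_occasions = 1)
  out <- eligible_injuries(inj, T = 100, m = 7)
  expect_identical(out$onset_occasion, 50)
})

test_that("the worked confusion example counts day by day", {
  # T = 30, CCPs at 10 and 20, injury onset 23 (the latest eligible onset:
  # 23 = T - 7) with time-loss 3, W = 6: window 17-22 contains the CCP at
  # 20 -> TP; pool = 7..30 minus 17-22 minus 23-25 = 15 occasions, of
  # which occasion 10 carries a CCP -> FP
  flags <- rep(FALSE, 30)
  flags[c(10, 20)] <- TRUE
  ccp <- make_ccp(flags)
  inj <- data.frame(onset_occasion = 23, time_loss_occasions = 3)
  mask <- rep(FALSE, 30)
  mask[23:25] <- TRUE
  cc <- classify_occasions(ccp, inj, mask, W = 6)
  expect_identical(c(cc$tp, cc$fn, cc$fp, cc$tn), c(1L, 0L, 1L, 14L))
  expect_identical(cc$pool_size, 15L)
})

test_that("no signal gives a false negative; saturation gives pool-wide FPs", {
  inj <- data.frame(onset_occasion = 20, time_loss_occasions = 2)
  mask <- rep(FALSE, 40)
  mask[20:21] <- TRUE
  none <- classify_occasions(make_ccp(rep(FALSE, 40)), inj, mask, W = 6)
  expect_identical(c(none$tp, none$fn, none$fp), c(0L, 1L, 0L))
  expect_identical(none$tn, none$pool_size)
  all_on <- classify_occasions(make_ccp(rep(TRUE, 40)), inj, mask, W = 6)
  expect_identical(c(all_on$tp, all_on$tn), c(1L, 0L))
  expect_identical(all_on$fp, all_on$pool_size)
})

test_that("a window swallowed by a previous injury period is unevaluable", {
  inj <- data.frame(onset_occasion = c(15, 22), time_loss_occasions = c(7, 1))
  mask <- rep(FALSE, 40)
  mask[15:21] <- TRUE
  mask[22] <- TRUE
  cc <- classify_occasions(make_ccp(rep(FALSE, 40)), inj, mask, W = 6)
  expect_identical(cc$unevaluable, 1L)
  expect_identical(cc$eligible_injuries, 1L) # only the first is evaluated
})

test_that("per-player metrics reproduce the stated ratios", {
  pm <- player_metrics(make_counts(tp = 19, fp = 0, tn = 0, fn = 45))
  expect_equal(pm$sensitivity, 100 * 19 / 64)
  expect_equal(round(pm$sensitivity), 30)
  expect_true(is.na(pm$specificity)) # zero denominator contract
  expect_equal(player_metrics(make_counts(1, 0, 0, 1))$sensitivity, 50)
  full <- player_metrics(make_counts(2, 5, 90, 3))
  expect_equal(full$specificity, 100 * 90 / 95)
  expect_equal(full$accuracy, 100 * 92 / 100)
})

test_that("cohort summary averages players and pools F1 over summed counts", {
  counts <- list(make_counts(1, 10, 90, 1, id = "A"),
                 make_counts(0, 5, 95, 2, id = "B"))
  s <- cohort_summary(counts)
  expect_equal(s$mean_sensitivity, mean(c(50, 0)))
  expect_equal(s$mean_specificity, mean(c(90, 95)))
  expect_equal(s$precision, 1 / 16)
  expect_equal(s$recall, 1 / 4)
  expect_equal(s$f1, 2 * (1 / 16) * (1 / 4) / (1 / 16 + 1 / 4))
  zero <- cohort_summary(list(make_counts(0, 3, 50, 2)))
  expect_identical(zero$f1, 0)
  perfect <- cohort_summary(list(make_counts(4, 0, 50, 0)))
  expect_equal(perfect$f1, 1)
})

test_that("confusion counting agrees with the occasion-by-occasion reference", {
  set.seed(1234)
  for (k in 1:300) {
    T <- sample(15:40, 1)
    flags <- runif(T) < 0.2
    mask <- rep(FALSE, T)
    inj <- data.frame(onset_occasion = integer(0),
                      time_loss_occasions = integer(0))
    last_end <- 0
    for (j in 1:sample(0:3, 1)) {
      onset <- sample(seq_len(T), 1)
      loss <- sample(1:5, 1)
      if (onset <= last_end) next
      end <- min(T, onset + loss - 1)
      inj <- rbind(inj, data.frame(onset_occasion = onset,
                                   time_loss_occasions = loss))
      mask[onset:end] <- TRUE
      last_end <- end
    }
    inj <- inj[order(inj$onset_occasion), , drop = FALSE]
    W <- sample(1:10, 1)
    got <- classify_occasions(make_ccp(flags), inj, mask, W = W)
    ref <- oracle_classify(make_ccp(flags)$ccp, inj, mask, W = W)
    expect_identical(c(got$tp, got$fn, got$fp, got$tn, got$unevaluable),
                     as.integer(c(ref$tp, ref$fn, ref$fp, ref$tn,
                                  ref$unevaluable)))
    # conservation identities
    expect_identical(got$tp + got$fn + got$unevaluable,
                     nrow(eligible_injuries(inj, T, 7)))
    expect_identical(got$fp + got$tn, got$pool_size)
    expect_identical(got$pool_size + got$excluded_occasions + 6L, T)
  }
})

test_that("window search follows the stepwise improvement rule", {
  # flags on the four occasions before each onset: sensitivity saturates at
  # W = 1 and the specificity tie-break keeps absorbing flagged occasions
  # until W = 4; W = 5 no longer improves, so 4 is the optimum
  T <- 120
  onsets <- c(30, 70, 100)
  flags <- rep(FALSE, T)
  for (o in onsets) flags[(o - 4):(o - 1)] <- TRUE
  mask <- rep(FALSE, T)
  for (o in onsets) mask[o:(o + 1)] <- TRUE
  inj <- data.frame(onset_occasion = onsets, time_loss_occasions = 2)
  players <- list(list(player_id = "A", ccp = make_ccp(flags),
                       injuries = inj, injured_mask = mask))
  search <- optimize_ews_window(players)
  expect_identical(search$chosen, 4L)
  expect_identical(nrow(search$table), 10L)
  # flat metrics: never improves, the first window stands
  flat <- list(list(player_id = "A", ccp = make_ccp(rep(FALSE, T)),
                    injuries = inj, injured_mask = mask))
  expect_identical(optimize_ews_window(flat)$chosen, 1L)
})

test_that("factor attribution counts contributors and labels categories", {
  flags <- matrix(FALSE, 20, 4,
                  dimnames = list(NULL, c("motivation", "mood",
                                          "sprints", "recovery")))
  pk <- structure(list(values = flags, alpha = 0.05,
                       z_crit = qnorm(0.95), baseline = "global"),
                  class = "peak_matrix")
  pk$values[1:6, ] <- NA
  mk_conf <- function(det_occ) {
    structure(list(player_id = "A", tp = 1L, fp = 0L, tn = 10L, fn = 0L,
                   W = 6L, eligible_injuries = 1L, unevaluable = 0L,
                   excluded_occasions = 0L, pool_size = 10L,
                   detail = data.frame(player_id = "A", onset_occasion = 15,
                                       outcome = "TP", n_window = 6,
                                       detections = det_occ,
                                       stringsAsFactors = FALSE)),
              class = "dc_confusion")
  }
  p1 <- pk; p1$values[12, c("motivation", "mood")] <- TRUE
  a1 <- attribute_factors(p1, NULL, mk_conf("12"))
  expect_identical(a1$injury_labels$label, "psychological-only")
  expect_identical(a1$factor_counts$count[
    a1$factor_counts$factor == "motivation"], 1L)
  p2 <- pk; p2$values[12, "sprints"] <- TRUE
  expect_identical(attribute_factors(p2, NULL,
                                     mk_conf("12"))$injury_labels$label,
                   "sensor-only")
  p3 <- pk; p3$values[12, c("sprints", "recovery")] <- TRUE
  expect_identical(attribute_factors(p3, NULL,
                                     mk_conf("12"))$injury_labels$label,
                   "physiological-only")
  p4 <- pk; p4$values[12, c("mood", "recovery")] <- TRUE
  expect_identical(attribute_factors(p4, NULL,
                                     mk_conf("12"))$injury_labels$label,
                   "self-report-only")
  p5 <- pk; p5$values[12, c("mood", "sprints")] <- TRUE
  expect_identical(attribute_factors(p5, NULL,
                                     mk_conf("12"))$injury_labels$label,
                   "combination")
})
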