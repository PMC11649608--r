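test_that("players without an analysable injury are excluded", {
  cohort <- generate_cohort(sim_config(n_players = 2,
                                       series_length_range = c(40, 50),
                                       injury_rate = 0, seed = 1))
  sel <- select_players(cohort)
  expect_true(all(!sel$report$included))
  expect_true(all(sel$report$rule == "no_eligible_injury"))
})

test_that("a factor missing more than the threshold excludes the player", {
  vals <- runif(20, 0, 100)
  vals[1:5] <- NA # 25% missing
  tab <- rbind(make_raw_table("mood", vals),
               make_raw_table("motivation", runif(20, 0, 100)))
  inj <- data.frame(player_id = "P1", onset_occasion = 10,
                    time_loss_occasions = 2, mechanism = "traumatic",
                    stringsAsFactors = FALSE)
  cohort <- structure(list(tables = list(P1 = tab), injuries = inj,
                           config = NULL), class = "dc_cohort")
  sel <- select_players(cohort)
  expect_false(sel$report$included)
  expect_identical(sel$report$rule, "excess_missingness")
  # exactly 20% missing is tolerated ("not more than 20%")
  vals2 <- runif(20, 0, 100)
  vals2[1:4] <- NA
  cohort$tables$P1 <- rbind(make_raw_table("mood", vals2),
                            make_raw_table("motivation", runif(20, 0, 100)))
  expect_true(select_players(cohort)$report$included)
})

test_that("select_players is idempotent", {
  cohort <- generate_cohort(sim_config(n_players = 5,
                                       series_length_range = c(60, 90),
                                       injury_rate = 3, seed = 9))
  once <- select_players(cohort)$included
  twice <- select_players(once)$included
  expect_identical(names(once$tables), names(twice$tables))
})

test_that("linear imputation interpolates and edge-fills", {
  tab <- make_raw_table("mood", c(40, NA, 60))
  expect_identical(impute_missing(tab)$value, c(40, 50, 60))
  tab2 <- make_raw_table("mood", c(NA, NA, 30, 40))
  expect_identical(impute_missing(tab2)$value, c(30, 30, 30, 40))
  tab3 <- make_raw_table("mood", runif(5, 0, 100))
  expect_identical(impute_missing(tab3)$value, tab3$value)
  tab4 <- make_raw_table("mood", rep(NA_real_, 5))
  expect_error(impute_missing(tab4), "entirely missing")
})

test_that("session RPE load follows RPE x duration and sums over sessions", {
  tab <- data.frame(player_id = "P1", occasion = 1L, session = c(1L, 1L),
                    factor = c("exertion", "duration"), value = c(15, 60),
                    stringsAsFactors = FALSE)
  out <- build_daily_factors(tab)
  expect_equal(out$value[out$factor == "srpe"], 900)
  two <- data.frame(player_id = "P1", occasion = 1L,
                    session = c(1L, 1L, 2L, 2L),
                    factor = c("exertion", "duration", "exertion", "duration"),
                    value = c(15, 60, 10, 30), stringsAsFactors = FALSE)
  out2 <- build_daily_factors(two)
  expect_equal(out2$value[out2$factor == "srpe"], 900 + 300)
  expect_equal(out2$value[out2$factor == "duration"], 90)
  expect_error(build_daily_factors(
    make_raw_table("exertion", c(15, 14))), "duration")
})

test_that("daily aggregation conserves total load and dedupes self-reports", {
  cohort <- generate_cohort(sim_config(n_players = 1,
                                       series_length_range = c(40, 40),
                                       injury_rate = 0, missing_rate = 0,
                                       seed = 4))
  tab <- cohort$tables[[1]]
  out <- build_daily_factors(tab)
  expect_identical(anyDuplicated(out[, c("occasion", "factor")]), 0L)
  srpe <- tab[tab$factor == "exertion", ]
  dur <- tab[tab$factor == "duration", ]
  key <- function(d) paste(d$occasion, d$session)
  sess_load <- srpe$value * dur$value[match(key(srpe), key(dur))]
  expect_equal(sum(out$value[out$factor == "srpe"]), sum(sess_load))
  expect_equal(sum(out$value[out$factor == "distance"]),
               sum(tab$value[tab$factor == "distance"]))
})

test_that("normalization applies the stated divisors", {
  tab <- rbind(make_raw_table("mood", c(75, 50, 25)),
               make_raw_table("recovery", c(14, 6, 20)),
               make_raw_table("distance", c(5000, 10000, 2500)))
  s <- normalize_factors(tab, factor_set = c("mood", "recovery", "distance"))
  expect_equal(unname(s$values[, "mood"]), c(0.75, 0.5, 0.25))
  expect_equal(unname(s$values[, "recovery"]), c(0.7, 0.3, 1.0))
  expect_equal(unname(s$values[, "distance"]), c(0.5, 1.0, 0.25))
})

test_that("normalization is monotone and bounded; all-zero sensor fails", {
  x <- runif(30, 0, 100)
  tab <- make_raw_table("mood", x)
  s <- normalize_factors(tab, factor_set = "mood")
  expect_identical(order(s$values[, 1]), order(x))
  expect_true(all(s$values >= 0 & s$values <= 1))
  zero <- make_raw_table("sprints", rep(0, 10))
  expect_error(normalize_factors(zero, factor_set = "sprints"),
               "individual")
})

test_that("the injured mask spans onset through onset + time_loss - 1", {
  tab <- make_raw_table("mood", runif(30, 0, 100))
  inj <- data.frame(player_id = "P1", onset_occasion = 10,
                    time_loss_occasions = 3)
  s <- normalize_factors(tab, injuries = inj, factor_set = "mood")
  expect_identical(which(s$injured_mask), 10:12)
})
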