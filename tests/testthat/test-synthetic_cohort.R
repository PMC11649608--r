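small_cfg <- function(...) {
  sim_config(n_players = 2, series_length_range = c(40, 60), seed = 1, ...)
}

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(a$tables, b$tables)
  expect_identical(a$injuries, b$injuries)
})

test_that("zero injury rate yields an empty injury log", {
  cohort <- generate_cohort(small_cfg(injury_rate = 0))
  expect_identical(nrow(cohort$injuries), 0L)
})

test_that("generated values respect raw scale bounds and injury placement margins", {
  cohort <- generate_cohort(sim_config(n_players = 4,
                                       series_length_range = c(60, 90),
                                       injury_rate = 3, seed = 42))
  specs <- default_scale_specs()
  for (tab in cohort$tables) {
    for (f in unique(tab$factor)) {
      v <- tab$value[tab$factor == f & !is.na(tab$value)]
      sp <- specs[specs$factor == f, ]
      expect_true(all(v >= sp$raw_min & v <= sp$raw_max), label = f)
    }
  }
  for (k in seq_len(nrow(cohort$injuries))) {
    id <- cohort$injuries$player_id[k]
    T <- max(cohort$tables[[id]]$occasion)
    o <- cohort$injuries$onset_occasion[k]
    expect_true(o >= 8 && o <= T - 7)
  }
  # injury periods of one player never overlap
  for (id in unique(cohort$injuries$player_id)) {
    inj <- cohort$injuries[cohort$injuries$player_id == id, ]
    inj <- inj[order(inj$onset_occasion), ]
    if (nrow(inj) > 1) {
      ends <- inj$onset_occasion + pmax(inj$time_loss_occasions, 1) - 1
      expect_true(all(inj$onset_occasion[-1] > ends[-nrow(inj)]))
    }
  }
})

test_that("injury placement rate matches the configured expectation", {
  # 20 players x 300 occasions at ~1/120 injuries per occasion: the mean
  # number of injuries per player should recover 2.5 within +/- 1
  rates <- sapply(1:20, function(seed) {
    cohort <- generate_cohort(sim_config(
      n_players = 20, series_length_range = c(300, 300),
      injury_rate = 100 / 120, missing_rate = 0,
      destabilization_fraction = 0, seed = seed))
    nrow(cohort$injuries) / 20
  })
  expect_lt(abs(mean(rates) - 2.5), 1)
})

test_that("destabilization with gain 1 or no factors is the identity", {
  cohort <- generate_cohort(small_cfg(injury_rate = 0, missing_rate = 0))
  tab <- cohort$tables[[1]]
  ev <- list(onset_occasion = 20)
  expect_identical(inject_destabilization(tab, ev, lead = 6, gain = 1,
                                          factors = "mood"), tab)
  expect_identical(inject_destabilization(tab, ev, lead = 6, gain = 5,
                                          factors = character(0)), tab)
})

test_that("strong destabilization raises in-window variance for each factor", {
  cohort <- generate_cohort(small_cfg(injury_rate = 0, missing_rate = 0))
  tab <- cohort$tables[[1]]
  facs <- c("mood", "recovery", "distance")
  out <- inject_destabilization(tab, list(onset_occasion = 25), lead = 6,
                                gain = 10, factors = facs)
  for (f in facs) {
    inside <- out$value[out$factor == f & out$occasion %in% 19:24 &
                          out$session == 1]
    before <- out$value[out$factor == f & out$occasion %in% 13:18 &
                          out$session == 1]
    expect_gt(var(inside), var(before))
  }
})

test_that("a window reaching before occasion 1 is truncated with a warning", {
  cohort <- generate_cohort(small_cfg(injury_rate = 0, missing_rate = 0))
  tab <- cohort$tables[[1]]
  expect_warning(
    out <- inject_destabilization(tab, list(onset_occasion = 3), lead = 6,
                                  gain = 10, factors = "mood"),
    "truncated")
  expect_false(identical(out, tab))
})

test_that("missingness is Bernoulli at the requested rate and seed-stable", {
  tab <- make_raw_table("mood", runif(10000, 0, 100))
  expect_identical(apply_missingness(tab, 0, seed = 1), tab)
  a <- apply_missingness(tab, 0.2, seed = 7)
  b <- apply_missingness(tab, 0.2, seed = 7)
  expect_identical(which(is.na(a$value)), which(is.na(b$value)))
  frac <- mean(is.na(a$value))
  expect_gte(frac, 0.18)
  expect_lte(frac, 0.22)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(series_length_range = c(10, 40)), ">= 15")
  expect_error(sim_config(destabilization_gain = 0.5), "gain")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(destabilization_fraction = 1.2), "fraction")
})
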