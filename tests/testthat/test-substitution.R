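# Baseline built from a record holding 200 g/day of a dairy item whose
# composition equals the published dairy profile, so the worked substitution
# arithmetic is exact.
dairy_only_baseline <- function() {
  t3 <- table3_profiles()
  dairy <- t3[t3$label == "dairy", ]
  cat <- tiny_catalogue()[1, ]
  for (comp in nv) cat[[comp]] <- dairy[[comp]]
  cat$ghge <- dairy$ghge_100g * 10
  cat$lu <- dairy$lu_100g * 10
  rec <- make_record("r1", list(list(1, "milk", 200), list(2, "milk", 200),
                                list(3, "milk", 200)))
  compute_daily_intake(rec, as_catalogue(cat))
}

test_that("gram-for-gram replacement reproduces the worked arithmetic", {
  base <- dairy_only_baseline()
  t3 <- table3_profiles()
  pbda <- t3[t3$label == "pbda_total", ]
  expect_equal(base$energy, 2 * 92.96, tolerance = 1e-12)

  s1 <- substitute_intake(base, pbda, 1)
  expect_equal(s1$energy, 2 * 52.93, tolerance = 1e-12)   # 105.86 kcal/day
  s05 <- substitute_intake(base, pbda, 0.5)
  expect_equal(s05$energy, (2 * 92.96 + 2 * 52.93) / 2, tolerance = 1e-12)  # 145.89

  # environmental indicators: 0.56 kgCO2eq/day baseline -> 0.10 at full substitution
  expect_equal(base$ghge_day, 2 * 0.28, tolerance = 1e-12)
  expect_equal(s1$ghge_day, 2 * 0.05, tolerance = 1e-12)
})

test_that("level 0 is the baseline, bitwise", {
  cat <- as_catalogue(rand_catalogue(12, seed = 51))
  intake <- compute_daily_intake(rand_records(cat, 15, seed = 52), cat)
  repl <- table3_profiles()[2, ]
  s0 <- substitute_intake(intake, repl, 0)
  for (comp in c(nv, "ghge_day", "lu_day", "total_grams")) {
    expect_identical(s0[[comp]], intake[[comp]])
  }
})

test_that("the scenario result is linear in the substitution level", {
  cat <- as_catalogue(rand_catalogue(12, seed = 53))
  intake <- compute_daily_intake(rand_records(cat, 20, seed = 54), cat)
  repl <- table3_profiles()[2, ]
  s0 <- substitute_intake(intake, repl, 0)
  s1 <- substitute_intake(intake, repl, 1)
  for (lam in c(0.25, 0.5, 0.75)) {
    sl <- substitute_intake(intake, repl, lam)
    for (comp in c(nv, "ghge_day", "lu_day")) {
      mix <- (1 - lam) * s0[[comp]] + lam * s1[[comp]]
      expect_equal(sl[[comp]], mix, tolerance = 1e-12, info = comp)
    }
    expect_identical(sl$total_grams, intake$total_grams)  # gram conservation
  }
})

test_that("the engine agrees with an item-by-item reconstruction oracle", {
  cat <- rand_catalogue(14, seed = 61)
  rec <- rand_records(cat, 10, seed = 62)
  intake <- compute_daily_intake(rec, as_catalogue(cat))
  t3 <- table3_profiles()
  repl <- t3[t3$label == "pbda_total", ]
  # oracle: scale every dairy entry by (1 - lambda) and append a pseudo-item
  # carrying the replacement profile, lambda x that day's dairy grams
  pseudo <- cat[1, ]
  pseudo$item_id <- "PSEUDO_REPL"; pseudo$group <- "other"
  pseudo$main_ingredient <- "not_applicable"
  for (comp in nv) pseudo[[comp]] <- repl[[comp]]
  pseudo$ghge <- repl$ghge_100g * 10; pseudo$lu <- repl$lu_100g * 10
  aug <- as_catalogue(dplyr::bind_rows(cat, pseudo))
  is_dairy <- cat$group[match(rec$item_id, cat$item_id)] == "dairy"
  for (lam in c(0.25, 0.5, 0.75, 1)) {
    mod <- rec
    mod$grams[is_dairy] <- mod$grams[is_dairy] * (1 - lam)
    day_dairy <- rec[is_dairy, ] |>
      dplyr::group_by(record_id, participant_id, sex, age_years, day) |>
      dplyr::summarise(grams = sum(grams) * lam, .groups = "drop")
    day_dairy$item_id <- "PSEUDO_REPL"
    oracle <- compute_daily_intake(dplyr::bind_rows(mod, day_dairy), aug)
    got <- substitute_intake(intake, repl, lam)
    oracle <- oracle[match(got$record_id, oracle$record_id), ]
    for (comp in c(nv, "ghge_day", "lu_day", "total_grams")) {
      denom <- pmax(abs(oracle[[comp]]), 1e-6)
      expect_lt(max(abs(got[[comp]] - oracle[[comp]]) / denom), 1e-9)
    }
  }
})

test_that("invalid levels, missing indicators and zero-dairy baselines are rejected", {
  base <- dairy_only_baseline()
  repl <- table3_profiles()[2, ]
  expect_error(substitute_intake(base, repl, 1.2), "lambda")
  expect_error(substitute_intake(base, repl, -0.1), "lambda")
  bare <- table3_profiles(fill_indicators = FALSE)
  expect_error(substitute_intake(base, bare[bare$label == "pbda_soy", ], 0.5),
               "ghge_100g")
  zero <- base; zero$dairy_grams <- 0
  expect_error(substitute_intake(zero, repl, 0.5), "zero dairy")
})

test_that("the mean-profile subtraction variant coincides when dairy is homogeneous", {
  base <- dairy_only_baseline()
  t3 <- table3_profiles()
  repl <- t3[t3$label == "pbda_total", ]
  dairy_prof <- t3[t3$label == "dairy", ]
  a <- substitute_intake(base, repl, 0.75)
  b <- substitute_intake(base, repl, 0.75, subtract = "mean_profile",
                         dairy_profile = dairy_prof)
  for (comp in c(nv, "ghge_day", "lu_day")) {
    expect_equal(a[[comp]], b[[comp]], tolerance = 1e-10)
  }
  expect_error(substitute_intake(base, repl, 0.5, subtract = "mean_profile"),
               "dairy_profile")
})

test_that("the scenario grid has baseline plus models x levels cardinality", {
  cat <- tiny_catalogue()
  rec <- make_record("r1", list(list(1, "milk", 200), list(2, "bread", 100)))
  intake <- compute_daily_intake(rec, cat)
  prof <- table3_profiles()
  g1 <- run_scenario_grid(intake, prof, models = "model1_total_pbda")
  # per quantity: 1 baseline row + 4 level rows
  expect_equal(nrow(g1), 15 * (1 + 4))
  g4 <- run_scenario_grid(intake, prof)
  expect_equal(nrow(g4), 15 * (1 + 4 * 4))
  expect_setequal(unique(g4$model), c("baseline", names(pbdasub:::scenario_models())))
  # energy decreases strictly with the level when the replacement is lighter
  en <- g4[g4$quantity == "energy" & g4$model == "model1_total_pbda", ]
  en <- en[order(en$level), ]
  expect_true(all(diff(en$value) < 0))
})

test_that("grid errors propagate for empty input and missing profiles", {
  prof <- table3_profiles()
  expect_error(run_scenario_grid(prof[0, ], prof), "empty analysis set")
  cat <- tiny_catalogue()
  rec <- make_record("r1", list(list(1, "milk", 200)))
  intake <- compute_daily_intake(rec, cat)
  expect_error(
    run_scenario_grid(intake, prof[prof$label != "pbda_soy", ]),
    "pbda_soy"
  )
})
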