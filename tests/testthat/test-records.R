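test_that("daily intake is the 3-day mean of per-entry sums", {
  cat <- tiny_catalogue()
  # same 100 g of milk (93 kcal/100 g) on each of 3 days -> 93 kcal/day
  r1 <- make_record("r1", list(list(1, "milk", 100), list(2, "milk", 100),
                               list(3, "milk", 100)))
  out <- compute_daily_intake(r1, cat)
  expect_equal(out$energy, 93)
  expect_equal(out$dairy_grams, 100)
  expect_equal(out$total_grams, 100)

  # day grams 100/200/300 at 50 kcal/100 g -> (50+100+150)/3 = 100 kcal/day
  cat50 <- cat; cat50$energy[cat50$item_id == "milk"] <- 50
  r2 <- make_record("r2", list(list(1, "milk", 100), list(2, "milk", 200),
                               list(3, "milk", 300)))
  expect_equal(compute_daily_intake(r2, cat50)$energy, 100)

  # 257 g/day at 2.8 kgCO2eq/kg -> 0.257 x 2.8 = 0.7196 kgCO2eq/day
  r3 <- make_record("r3", list(list(1, "milk", 257), list(2, "milk", 257),
                               list(3, "milk", 257)))
  expect_equal(compute_daily_intake(r3, cat)$ghge_day, 0.7196, tolerance = 1e-12)

  # an empty record (only zero-gram entries) -> all-zero intake
  r0 <- make_record("r0", list(list(1, "milk", 0)))
  out0 <- compute_daily_intake(r0, cat)
  for (comp in c(nv, "total_grams", "ghge_day", "lu_day", "dairy_grams")) {
    expect_equal(out0[[comp]], 0)
  }

  # a day with no rows counts as a zero day (divisor stays 3)
  r4 <- make_record("r4", list(list(1, "milk", 300)))
  expect_equal(compute_daily_intake(r4, cat)$energy, 93)
})

test_that("unknown items and unassigned indicators are reported with context", {
  cat <- tiny_catalogue()
  bad <- make_record("r1", list(list(2, "ghost", 100)))
  expect_error(compute_daily_intake(bad, cat), "ghost.*day 2")
  cat$ghge[cat$item_id == "milk"] <- NA
  r <- make_record("r1", list(list(1, "milk", 100)))
  expect_error(compute_daily_intake(r, cat), "milk.*assign_similar_indicator")
})

test_that("intake matches a brute-force per-entry oracle and is order-invariant", {
  cat <- as_catalogue(rand_catalogue(12, seed = 7))
  rec <- rand_records(cat, 8, seed = 8)
  got <- compute_daily_intake(rec, cat)
  want <- brute_force_intake(rec, cat)
  for (comp in c(nv, paste0("dairy_", nv), "total_grams", "ghge_day", "lu_day",
                 "dairy_grams", "dairy_ghge_day", "dairy_lu_day")) {
    expect_equal(got[[comp]][order(got$record_id)],
                 want[[comp]][order(want$record_id)],
                 tolerance = 1e-12, info = comp)
  }
  # permuting entry rows and relabeling days changes nothing
  set.seed(9)
  shuf <- rec[sample(nrow(rec)), ]
  shuf$day <- c(3, 1, 2)[shuf$day]
  got2 <- compute_daily_intake(shuf, cat)
  expect_equal(got2[order(got2$record_id), ], got[order(got$record_id), ],
               tolerance = 1e-12)
})

test_that("intake is additive over concatenated day-lists", {
  cat <- as_catalogue(rand_catalogue(10, seed = 11))
  a <- rand_records(cat, 1, seed = 12)
  b <- rand_records(cat, 1, seed = 13)
  b$record_id <- b$participant_id <- "rec0001"
  b$sex <- a$sex[1]; b$age_years <- a$age_years[1]
  both <- dplyr::bind_rows(a, b)
  ia <- compute_daily_intake(a, cat)
  ib <- compute_daily_intake(b, cat)
  iboth <- compute_daily_intake(both, cat)
  for (comp in c(nv, "total_grams", "ghge_day", "dairy_grams")) {
    expect_equal(iboth[[comp]], ia[[comp]] + ib[[comp]], tolerance = 1e-12)
  }
})

test_that("dairy contribution equals totals iff all items are dairy", {
  cat <- tiny_catalogue()
  all_dairy <- make_record("r1", list(list(1, "milk", 150), list(2, "cheese", 40),
                                      list(3, "yoghurt", 120)))
  out <- compute_daily_intake(all_dairy, cat)
  for (comp in nv) expect_equal(out[[paste0("dairy_", comp)]], out[[comp]])
  expect_equal(out$dairy_grams, out$total_grams)

  none <- make_record("r2", list(list(1, "bread", 90), list(2, "oat_drink", 200)))
  out2 <- compute_daily_intake(none, cat)
  for (comp in nv) expect_equal(out2[[paste0("dairy_", comp)]], 0)
  expect_equal(out2$dairy_grams, 0)
})

test_that("record selection follows the flow precedence (PBDA first, then zero dairy)", {
  cat <- tiny_catalogue()
  rec <- dplyr::bind_rows(
    make_record("keep", list(list(1, "milk", 200), list(2, "bread", 80))),
    make_record("nodairy", list(list(1, "bread", 80))),
    make_record("pbda", list(list(1, "milk", 100), list(2, "soy_drink_f", 150))),
    make_record("pbda_nodairy", list(list(1, "oat_drink", 250)))
  )
  part <- partition_records(rec, cat)
  expect_setequal(unique(part$analysis_set$record_id), "keep")
  expect_setequal(unique(part$excluded_no_dairy$record_id), "nodairy")
  # a record with PBDA and no dairy still goes to the profile set
  expect_setequal(unique(part$pbda_profile_set$record_id), c("pbda", "pbda_nodairy"))
  counts <- setNames(part$counts$n_records, part$counts$set)
  expect_equal(unname(counts["total"]),
               unname(sum(counts[c("analysis_set", "pbda_profile_set",
                                   "excluded_no_dairy")])))
})
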