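test_that("profiles are intake-weighted means over consumption entries", {
  cat <- tiny_catalogue()
  cat$energy[cat$item_id == "milk"] <- 40
  cat$energy[cat$item_id == "yoghurt"] <- 80
  rec <- make_record("r1", list(list(1, "milk", 100), list(1, "yoghurt", 300)))
  prof <- estimate_profile(rec, cat, "dairy")
  expect_equal(prof$energy, (100 * 40 + 300 * 80) / 400)  # 70 kcal/100 g
  expect_equal(prof$n_products, 2)
  expect_equal(prof$total_grams, 400)

  # a single consumed item reproduces that item's composition exactly
  one <- make_record("r2", list(list(2, "cheese", 75)))
  pc <- estimate_profile(one, cat, "dairy")
  it <- cat[cat$item_id == "cheese", ]
  for (comp in nv) expect_equal(pc[[comp]], it[[comp]])
  expect_equal(pc$ghge_100g, it$ghge / 10)

  # equal grams of two items -> componentwise midpoint
  eq <- make_record("r3", list(list(1, "milk", 150), list(2, "yoghurt", 150)))
  pm <- estimate_profile(eq, cat, "dairy")
  m <- cat[cat$item_id == "milk", ]; y <- cat[cat$item_id == "yoghurt", ]
  for (comp in nv) expect_equal(pm[[comp]], (m[[comp]] + y[[comp]]) / 2)
})

test_that("profile components stay in the contributing items' envelope and scale-invariance holds", {
  cat <- as_catalogue(rand_catalogue(15, seed = 21))
  rec <- rand_records(cat, 10, seed = 22)
  prof <- estimate_profile(rec, cat, "dairy")
  used <- cat[cat$group == "dairy" & cat$item_id %in% rec$item_id, ]
  for (comp in nv) {
    expect_gte(prof[[comp]], min(used[[comp]]) - 1e-12)
    expect_lte(prof[[comp]], max(used[[comp]]) + 1e-12)
  }
  rec2 <- rec; rec2$grams <- rec2$grams * 7.3
  prof2 <- estimate_profile(rec2, cat, "dairy")
  for (comp in c(nv, "ghge_100g", "lu_100g")) {
    expect_equal(prof2[[comp]], prof[[comp]], tolerance = 1e-12)
  }
})

test_that("total PBDA profile decomposes into the gram-weighted subgroup mixture", {
  cat <- as_catalogue(rand_catalogue(20, seed = 31))
  rec <- rand_records(cat, 12, seed = 32, require_dairy = FALSE)
  # guarantee at least one fortified and one non-fortified PBDA entry
  fn <- lengths(cat$fortified_nutrients)
  extra <- make_record("rextra", list(
    list(1, cat$item_id[cat$group == "pbda" & fn > 0][1], 120),
    list(2, cat$item_id[cat$group == "pbda" & fn == 0][1], 180)
  ))
  rec <- dplyr::bind_rows(rec, extra)
  tot <- estimate_profile(rec, cat, "pbda_total")
  f <- estimate_profile(rec, cat, "pbda_fortified")
  n <- estimate_profile(rec, cat, "pbda_nonfortified")
  w <- f$total_grams / (f$total_grams + n$total_grams)
  for (comp in nv) {
    expect_equal(tot[[comp]], w * f[[comp]] + (1 - w) * n[[comp]],
                 tolerance = 1e-12)
  }
})

test_that("the per-product (unweighted) option averages distinct products", {
  cat <- tiny_catalogue()
  rec <- make_record("r1", list(list(1, "milk", 10), list(2, "milk", 990),
                                list(3, "yoghurt", 10)))
  p <- estimate_profile(rec, cat, "dairy", weighted = FALSE)
  m <- cat[cat$item_id == "milk", ]; y <- cat[cat$item_id == "yoghurt", ]
  expect_equal(p$energy, (m$energy + y$energy) / 2)
})

test_that("the profile suite omits unobserved subgroups with a warning", {
  cat <- tiny_catalogue()
  rec <- dplyr::bind_rows(
    make_record("a", list(list(1, "milk", 200))),
    make_record("b", list(list(1, "milk", 150), list(2, "soy_drink_f", 180)))
  )
  w <- testthat::capture_warnings(prof <- profile_suite(rec, cat))
  expect_match(w, "pbda_oat", all = FALSE)
  expect_match(w, "pbda_nonfortified", all = FALSE)
  expect_false("pbda_oat" %in% prof$label)
  expect_true(all(c("dairy", "pbda_total", "pbda_fortified", "pbda_soy") %in% prof$label))
  # subgroup scenarios reuse the total-PBDA indicator values
  expect_equal(prof$ghge_100g[prof$label == "pbda_fortified"],
               prof$ghge_100g[prof$label == "pbda_total"])
  expect_equal(prof$indicator_source[prof$label == "pbda_fortified"], "pbda_total")
})

test_that("the packaged published profiles load verbatim", {
  t3 <- table3_profiles(fill_indicators = FALSE)
  expect_setequal(t3$label, c("dairy", "pbda_total", "pbda_fortified",
                              "pbda_nonfortified", "pbda_soy", "pbda_oat"))
  g <- function(lbl, comp) t3[[comp]][t3$label == lbl]
  expect_equal(g("dairy", "energy"), 92.96)
  expect_equal(g("pbda_total", "energy"), 52.93)
  expect_equal(g("pbda_fortified", "vitamin_b12"), 0.29)
  expect_equal(g("pbda_oat", "iodine"), 2.52)
  expect_equal(g("dairy", "ghge_100g"), 0.28)
  expect_equal(g("pbda_total", "lu_100g"), 0.10)
  expect_true(is.na(g("pbda_soy", "ghge_100g")))
  filled <- table3_profiles(fill_indicators = TRUE)
  expect_equal(filled$ghge_100g[filled$label == "pbda_soy"], 0.05)
})

test_that("empty selections and cross-group selectors are errors", {
  cat <- tiny_catalogue()
  rec <- make_record("r1", list(list(1, "bread", 100)))
  expect_error(estimate_profile(rec, cat, "dairy"), "no consumption entries")
  expect_error(estimate_profile(rec, cat, "pbda_total", items = c("milk")),
               "non-PBDA")
})
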