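test_that("median and quartiles follow the pinned type-7 rule", {
  s <- summarize_quartiles(c(1, 2, 3, 4, 5))
  expect_equal(c(s$q1, s$median, s$q3), c(2, 3, 4))
  s2 <- summarize_quartiles(rep(7.5, 3))
  expect_equal(c(s2$q1, s2$median, s2$q3), c(7.5, 7.5, 7.5))
  s3 <- summarize_quartiles(42)
  expect_equal(c(s3$q1, s3$median, s3$q3), c(42, 42, 42))
  expect_error(summarize_quartiles(numeric(0)), "no finite values")

  # sort-based interpolation oracle on random vectors
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(2:40, 1))
    s <- summarize_quartiles(x)
    expect_equal(s$q1, quantile7_oracle(x, 0.25), tolerance = 1e-12)
    expect_equal(s$median, quantile7_oracle(x, 0.5), tolerance = 1e-12)
    expect_equal(s$q3, quantile7_oracle(x, 0.75), tolerance = 1e-12)
  }
})

null_two_group <- function(n = 20, seed = 1) {
  set.seed(seed)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  band <- sample(c("[4,7)", "[7,10)"), n, replace = TRUE)
  base <- 100 + 3 * (sex == "male") + 5 * (band == "[7,10)") + rnorm(n, sd = 4)
  tibble::tibble(
    value = c(base, base + rnorm(n, sd = 4) - rnorm(n, sd = 4)),
    model = rep(c("baseline", "scenario"), each = n),
    sex = rep(sex, 2), age_band = rep(band, 2)
  )
}

test_that("identical scenario and baseline values give a zero contrast and p ~ 1", {
  d <- null_two_group(seed = 72)
  d$value[d$model == "scenario"] <- d$value[d$model == "baseline"]
  cmp <- compare_to_baseline(d)
  td <- tidy(cmp)
  expect_equal(td$estimate, 0, tolerance = 1e-12)
  expect_gt(td$p_adj, 0.999)
  expect_false(td$significant)
})

test_that("the two-group case without covariate variation matches the closed-form F test", {
  # 10-point fixture, balanced two groups, constant covariates
  y <- c(5.1, 4.8, 5.6, 5.0, 4.9, 6.2, 6.0, 5.8, 6.5, 6.1)
  d <- tibble::tibble(
    value = y,
    model = rep(c("baseline", "scen"), each = 5),
    sex = "male", age_band = "[7,10)"
  )
  expect_message(cmp <- compare_to_baseline(d), "single level")
  # closed-form one-way ANOVA F statistic and p-value
  g1 <- y[1:5]; g2 <- y[6:10]
  gm <- mean(y)
  ssb <- 5 * (mean(g1) - gm)^2 + 5 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_stat <- (ssb / 1) / (ssw / 8)
  p_oracle <- 1 - pf(f_stat, 1, 8)
  expect_equal(tidy(cmp)$p_adj, p_oracle, tolerance = 1e-8)
  expect_equal(tidy(cmp)$estimate, mean(g2) - mean(g1), tolerance = 1e-10)
})

test_that("the comparison is invariant to row order and covariate recoding", {
  d <- null_two_group(n = 30, seed = 73)
  p1 <- tidy(compare_to_baseline(d))$p_adj
  set.seed(74)
  p2 <- tidy(compare_to_baseline(d[sample(nrow(d)), ]))$p_adj
  expect_equal(p1, p2, tolerance = 1e-10)
  d2 <- d
  d2$sex <- c(male = "group_A", female = "group_B")[d2$sex]
  d2$age_band <- c("[4,7)" = "young", "[7,10)" = "old")[d2$age_band]
  p3 <- tidy(compare_to_baseline(d2))$p_adj
  expect_equal(p1, p3, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with diagnostics", {
  d <- null_two_group(n = 20, seed = 75)
  expect_error(compare_to_baseline(d[c(1, 21:40), ]), "< 2 records")
  # a covariate collinear with another is aliased
  d$dup <- d$sex
  expect_error(compare_to_baseline(d, covariates = c("sex", "dup")), "collinear")
})

test_that("multi-level Tukey contrasts report every level against baseline", {
  set.seed(76)
  n <- 40
  base <- rnorm(n, 100, 5)
  d <- tibble::tibble(
    value = c(base, base - 2, base - 4),
    model = rep(c("baseline", "lev50", "lev100"), each = n),
    sex = sample(c("male", "female"), 3 * n, replace = TRUE),
    age_band = sample(c("a", "b"), 3 * n, replace = TRUE)
  )
  cmp <- compare_to_baseline(d)
  td <- tidy(cmp)
  expect_setequal(td$scenario, c("lev50", "lev100"))
  expect_lt(td$estimate[td$scenario == "lev100"], td$estimate[td$scenario == "lev50"])
  expect_equal(glance(cmp)$family_size, 3)  # all pairwise contrasts among 3 cells
  expect_equal(glance(cmp)$n, 3 * n)
})

test_that("grid-level comparisons cover every model, quantity and level", {
  cat <- as_catalogue(rand_catalogue(12, seed = 81))
  rec <- rand_records(cat, 12, seed = 82)
  intake <- compute_daily_intake(rec, cat)
  grid <- run_scenario_grid(intake, table3_profiles(),
                            models = c("model1_total_pbda", "model3_oat_pbda"),
                            levels = c(0.5, 1))
  cmp <- compare_scenarios(grid)
  expect_equal(nrow(cmp), 2 * 15 * 2)  # models x quantities x levels
  expect_true(all(cmp$p_adj >= 0 & cmp$p_adj <= 1))
  full <- cmp[cmp$quantity == "energy" & cmp$model == "model1_total_pbda", ]
  expect_lt(full$estimate[full$level == 1], full$estimate[full$level == 0.5])
})

test_that("p-values print in the tables' display convention", {
  expect_equal(format_pvalue(c(0.5, 0.023, 9e-5)), c("0.5000", "0.0230", "<0.0001"))
})
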