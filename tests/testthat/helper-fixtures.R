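# Small in-code fixtures and independent oracles shared across test files.

nv <- pbdasub::nutrient_names()

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-written six-item catalogue: three dairy items, a fortified soy and a
# non-fortified oat PBDA, one background food. Composition invariants hold by
# construction; realistic per-kg indicators.
tiny_catalogue <- function() {
  mk <- function(item_id, group, ingredient, fortified, energy, protein, fat, sfa,
                 pufa, carb, tsug, asug, b2, b12, ca, fe, iod, ghge, lu) {
    tibble::tibble(
      item_id = item_id, name = paste("fixture", item_id), group = group,
      main_ingredient = ingredient, fortified_nutrients = list(fortified),
      energy = energy, protein = protein, fat = fat, sfa = sfa, pufa = pufa,
      carbohydrate = carb, total_sugar = tsug, added_sugar = asug,
      vitamin_b2 = b2, vitamin_b12 = b12, calcium = ca, iron = fe, iodine = iod,
      ghge = ghge, lu = lu
    )
  }
  dplyr::bind_rows(
    mk("milk", "dairy", "not_applicable", character(0),
       93, 4.6, 5.0, 3.2, 0.1, 6.0, 5.8, 0.0, 0.18, 0.46, 120, 0.12, 10.6, 2.8, 2.7),
    mk("yoghurt", "dairy", "not_applicable", character(0),
       70, 4.0, 3.5, 2.2, 0.1, 5.0, 4.9, 1.0, 0.16, 0.40, 115, 0.10, 8.0, 2.0, 2.2),
    mk("cheese", "dairy", "not_applicable", character(0),
       350, 25.0, 28.0, 18.0, 0.8, 1.0, 0.5, 0.0, 0.35, 2.1, 800, 0.3, 35, 8.5, 7.9),
    mk("soy_drink_f", "pbda", "soy", c("vitamin_b12", "calcium"),
       52, 3.3, 1.9, 0.3, 1.1, 4.0, 3.0, 2.5, 0.05, 0.30, 120, 0.8, 0.6, 0.5, 1.0),
    mk("oat_drink", "pbda", "oat", character(0),
       48, 1.2, 1.3, 0.2, 0.6, 8.0, 3.7, 0.0, 0.01, 0.0, 5, 0.5, 2.5, 0.4, 0.9),
    mk("bread", "other", "not_applicable", character(0),
       250, 8.0, 3.0, 0.6, 1.2, 48.0, 4.0, 1.0, 0.1, 0.0, 30, 1.5, 4.0, 0.8, 1.5)
  )
}

# One long-format entry row.
entry <- function(pid, rid, sex, age, day, item, grams) {
  tibble::tibble(participant_id = pid, record_id = rid, sex = sex,
                 age_years = age, day = day, item_id = item, grams = grams)
}

# A record made of (day, item, grams) triples with shared metadata.
make_record <- function(rid, triples, pid = rid, sex = "male", age = 8) {
  dplyr::bind_rows(lapply(triples, function(tr) {
    entry(pid, rid, sex, age, tr[[1]], tr[[2]], as.numeric(tr[[3]]))
  }))
}

# Random valid catalogue: invariant-safe compositions (sugar chain nested in
# carbohydrate, sfa+pufa nested in fat), always-assigned indicators.
rand_catalogue <- function(n, seed, group = NULL) {
  set.seed(seed)
  stopifnot(n >= 4)
  groups <- group %||% c("dairy", "pbda", "pbda", "other",
                         sample(c("dairy", "pbda", "other"), n - 4, replace = TRUE))
  ing <- ifelse(groups == "pbda",
                sample(c("soy", "oat", "coconut"), n, replace = TRUE),
                "not_applicable")
  carb <- runif(n, 1, 50)
  tsug <- carb * runif(n)
  fat <- runif(n, 0.5, 30)
  sfa <- fat * runif(n, 0, 0.6)
  tibble::tibble(
    item_id = sprintf("it%03d", seq_len(n)),
    name = sprintf("random item %d", seq_len(n)),
    group = groups,
    main_ingredient = ing,
    fortified_nutrients = lapply(seq_len(n), function(i) {
      # item 2 is always a fortified PBDA, item 3 always non-fortified
      if (groups[i] == "pbda" && (i == 2 || (i != 3 && runif(1) < 0.5))) {
        c("calcium")
      } else {
        character(0)
      }
    }),
    energy = runif(n, 20, 400),
    protein = runif(n, 0.5, 25),
    fat = fat, sfa = sfa, pufa = fat * runif(n, 0, 0.3),
    carbohydrate = carb, total_sugar = tsug, added_sugar = tsug * runif(n),
    vitamin_b2 = runif(n, 0, 0.5), vitamin_b12 = runif(n, 0, 2),
    calcium = runif(n, 1, 800), iron = runif(n, 0, 10), iodine = runif(n, 0, 40),
    ghge = runif(n, 0.1, 10), lu = runif(n, 0.1, 10)
  )
}

# Random records over a catalogue; every record gets >= 1 dairy entry when
# require_dairy = TRUE so substitution preconditions hold.
rand_records <- function(catalogue, n_records, seed, require_dairy = TRUE,
                         entries_per_day = 3) {
  set.seed(seed)
  dairy_ids <- catalogue$item_id[catalogue$group == "dairy"]
  rows <- lapply(seq_len(n_records), function(r) {
    rid <- sprintf("rec%04d", r)
    sex <- sample(c("male", "female"), 1)
    age <- sample(3:18, 1)
    dplyr::bind_rows(lapply(1:3, function(d) {
      ids <- sample(catalogue$item_id, entries_per_day, replace = TRUE)
      if (require_dairy) ids[1] <- sample(dairy_ids, 1)
      entry(rid, rid, sex, age, d, ids, round(runif(length(ids), 10, 400), 1))
    }))
  })
  dplyr::bind_rows(rows)
}

# Brute-force daily-intake oracle: plain loops over records, days and entries,
# independent of the dplyr implementation path.
brute_force_intake <- function(records, catalogue) {
  out <- list()
  for (rid in unique(records$record_id)) {
    rr <- records[records$record_id == rid, ]
    tot <- setNames(numeric(length(nv) + 4), c(nv, "total_grams", "ghge_day",
                                               "lu_day", "dairy_grams"))
    dairy <- setNames(numeric(length(nv) + 2), c(nv, "ghge_day", "lu_day"))
    for (i in seq_len(nrow(rr))) {
      it <- catalogue[catalogue$item_id == rr$item_id[i], ]
      g <- rr$grams[i]
      for (comp in nv) tot[comp] <- tot[comp] + g / 100 * it[[comp]]
      tot["total_grams"] <- tot["total_grams"] + g
      tot["ghge_day"] <- tot["ghge_day"] + g / 1000 * it$ghge
      tot["lu_day"] <- tot["lu_day"] + g / 1000 * it$lu
      if (it$group == "dairy") {
        tot["dairy_grams"] <- tot["dairy_grams"] + g
        for (comp in nv) dairy[comp] <- dairy[comp] + g / 100 * it[[comp]]
        dairy["ghge_day"] <- dairy["ghge_day"] + g / 1000 * it$ghge
        dairy["lu_day"] <- dairy["lu_day"] + g / 1000 * it$lu
      }
    }
    row <- tibble::as_tibble(as.list(tot / 3))
    names(row)[names(row) %in% nv] <- nv
    for (comp in nv) row[[paste0("dairy_", comp)]] <- dairy[[comp]] / 3
    row$dairy_ghge_day <- dairy[["ghge_day"]] / 3
    row$dairy_lu_day <- dairy[["lu_day"]] / 3
    row$record_id <- rid
    out[[rid]] <- row
  }
  dplyr::bind_rows(out)
}

# Type-7 quantile oracle: direct linear interpolation between order statistics.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
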