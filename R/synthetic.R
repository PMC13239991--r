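#' Default composition targets for the synthetic cohort generator
#'
#' Sampling truth for the generator: the packaged published per-100 g profiles
#' for dairy and for fortified / non-fortified PBDA (see [table3_profiles()]),
#' plus a background "other foods" profile chosen so that a default cohort's
#' total daily intake lands near the published current-intake medians (energy
#' ~1620 kcal/day of which dairy ~250, total ~1900 g/day). Environmental
#' indicators are per kg of item (per-100 g published values x 10).
#'
#' The published total-PBDA column is not an exact gram-weighted mixture of
#' its fortified and non-fortified columns, so the generator samples from the
#' two subgroup targets and its implied total-PBDA truth is the expected
#' mixture at the fortified consumption share (see [generator_truth()]).
#'
#' @return Tibble with rows `dairy`, `pbda_fortified`, `pbda_nonfortified`,
#'   `other`: the 13 composition columns plus `ghge_kg`, `lu_kg`.
#' @export
default_generator_targets <- function() {
  t3 <- table3_profiles(fill_indicators = FALSE)
  nv <- nutrient_names()
  pick <- function(lbl) t3[t3$label == lbl, nv]
  other <- tibble::as_tibble(as.list(setNames(
    c(83, 2.4, 2.84, 1.14, 0.44, 11.6, 5.2, 2.64, 0.05, 0.127, 18.4, 0.506, 2.31),
    nv
  )))
  out <- dplyr::bind_rows(pick("dairy"), pick("pbda_fortified"),
                          pick("pbda_nonfortified"), other)
  out <- dplyr::mutate(out,
    label = c("dairy", "pbda_fortified", "pbda_nonfortified", "other"),
    ghge_kg = c(2.8, 0.5, 0.5, 1.77),
    lu_kg = c(2.7, 1.0, 1.0, 2.26),
    .before = 1
  )
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a dynamic 3-day
#' weighed-record cohort of 3- to 18-year-olds with a median of 6 records per
#' participant (1-16), 52% boys, dairy present in nearly all records, a small
#' minority (~4%) of records containing PBDA, ~1% of non-PBDA records with
#' zero dairy, and a catalogue of 107 PBDA products (~51% fortified, soy and
#' oat dominant) alongside dairy and background items.
#'
#' @param seed Integer seed (mandatory; all generation is reproducible given
#'   the seed).
#' @param n_participants Number of participants (cohort default 1072).
#' @param targets Composition-target tibble as
#'   [default_generator_targets()].
#' @param spread Half-width of the per-item multiplicative composition jitter
#'   (uniform on `1 +/- spread`; one shared factor across the fat chain and
#'   one across the sugar chain preserve the composition orderings exactly,
#'   and the gram-weighted expectation equals the target).
#' @param n_dairy_items,n_other_items Catalogue sizes for dairy and background
#'   foods.
#' @param pbda_counts Tibble with columns `base`, `n_fortified`,
#'   `n_nonfortified` (defaults: soy 34/17, oat 11/12, coconut 3/7, rice 3/7,
#'   almond 2/6, other 2/3 = 107 items, 55 fortified).
#' @param records_prob Probability weights for the number of records per
#'   participant (1-16); default truncated-geometric weights with median 6.
#' @param sex_ratio_male Probability a participant is male (0.52).
#' @param pbda_consumer_fraction Fraction of records containing PBDA
#'   (record-level assignment; default 326/8002).
#' @param zero_dairy_fraction Fraction of non-PBDA records with zero dairy
#'   (default 75/7751).
#' @param dairy_entries_extra,other_entries_base,other_entries_extra,pbda_entries_per_day
#'   Entry-count parameters per record-day: dairy draws `1 + Poisson(extra)`,
#'   other foods `base + Poisson(extra)`, PBDA days a fixed count.
#' @param grams_meanlog,grams_sdlog Named numeric vectors (names `dairy`,
#'   `other`, `pbda`) of the log-normal gram distribution per entry; grams are
#'   rounded to 0.1 g (weighed-record realism).
#' @param preference_concentration Gamma shape of the per-participant Dirichlet
#'   preference over dairy/other items (induces within-participant item
#'   correlation across days and records).
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(seed,
                             n_participants = 1072,
                             targets = default_generator_targets(),
                             spread = 0.04,
                             n_dairy_items = 30,
                             n_other_items = 60,
                             pbda_counts = tibble::tibble(
                               base = c("soy", "oat", "coconut", "rice", "almond", "other"),
                               n_fortified = c(34, 11, 3, 3, 2, 2),
                               n_nonfortified = c(17, 12, 7, 7, 6, 3)
                             ),
                             records_prob = 0.92^(1:16),
                             sex_ratio_male = 0.52,
                             pbda_consumer_fraction = 326 / 8002,
                             zero_dairy_fraction = 75 / 7751,
                             dairy_entries_extra = 1.5,
                             other_entries_base = 2,
                             other_entries_extra = 4,
                             pbda_entries_per_day = 4,
                             grams_meanlog = c(dairy = log(85), other = log(240), pbda = log(80)),
                             grams_sdlog = c(dairy = 0.6, other = 0.5, pbda = 0.25),
                             preference_concentration = 0.5) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("generator_config: an integer seed is mandatory")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    targets = tibble::as_tibble(targets),
    spread = spread,
    n_dairy_items = as.integer(n_dairy_items),
    n_other_items = as.integer(n_other_items),
    pbda_counts = tibble::as_tibble(pbda_counts),
    records_prob = records_prob / sum(records_prob),
    sex_ratio_male = sex_ratio_male,
    pbda_consumer_fraction = pbda_consumer_fraction,
    zero_dairy_fraction = zero_dairy_fraction,
    dairy_entries_extra = dairy_entries_extra,
    other_entries_base = other_entries_base,
    other_entries_extra = other_entries_extra,
    pbda_entries_per_day = as.integer(pbda_entries_per_day),
    grams_meanlog = grams_meanlog,
    grams_sdlog = grams_sdlog,
    preference_concentration = preference_concentration
  )
  probs <- c(cfg$sex_ratio_male, cfg$pbda_consumer_fraction, cfg$zero_dairy_fraction)
  if (any(probs < 0 | probs > 1)) abort("generator_config: probabilities must be in [0, 1]")
  if (cfg$spread < 0 || cfg$spread >= 1) abort("generator_config: spread must be in [0, 1)")
  if (!all(c("label", nutrient_names(), "ghge_kg", "lu_kg") %in% names(cfg$targets))) {
    abort("generator_config: targets must have label, the 13 components, ghge_kg, lu_kg")
  }
  needed <- c("dairy", "pbda_fortified", "pbda_nonfortified", "other")
  if (!all(needed %in% cfg$targets$label)) {
    abort(paste0("generator_config: targets must include rows: ",
                 paste(needed, collapse = ", ")))
  }
  for (comp in c(nutrient_names(), "ghge_kg", "lu_kg")) {
    if (any(!is.finite(cfg$targets[[comp]]) | cfg$targets[[comp]] < 0)) {
      abort(paste0("generator_config: infeasible target: negative or non-finite '",
                   comp, "'"))
    }
  }
  check_nutrient_values(cfg$targets, where = "generator targets")
  class(cfg) <- "generator_config"
  cfg
}

# Internal: expected fortified share of PBDA grams under the default intake
# model (deterministic entry allocation by item-count fraction, identical gram
# distributions for fortified and non-fortified entries).
fortified_gram_share <- function(config) {
  nf <- sum(config$pbda_counts$n_fortified)
  nn <- sum(config$pbda_counts$n_nonfortified)
  nf / (nf + nn)
}

#' Ground-truth group profiles implied by a generator configuration
#'
#' The generator samples item compositions around the configured targets with
#' mean-one jitter, so the gram-weighted expectation of each sampled group's
#' profile equals its target. The total-PBDA truth is the expected
#' gram-weighted mixture of the fortified and non-fortified targets at the
#' fortified consumption share the intake model induces.
#'
#' @param config A `generator_config`.
#' @return Profile tibble (rows `dairy`, `pbda_fortified`, `pbda_nonfortified`,
#'   `pbda_total`, `other`) with per-100 g compositions and `ghge_100g`,
#'   `lu_100g`.
#' @export
generator_truth <- function(config) {
  tg <- config$targets
  nv <- nutrient_names()
  w <- fortified_gram_share(config)
  rows <- list()
  for (lbl in c("dairy", "pbda_fortified", "pbda_nonfortified", "other")) {
    r <- tg[tg$label == lbl, ]
    row <- tibble::tibble(label = lbl)
    for (comp in nv) row[[comp]] <- r[[comp]]
    row$ghge_100g <- r$ghge_kg / 10
    row$lu_100g <- r$lu_kg / 10
    rows[[lbl]] <- row
  }
  f <- tg[tg$label == "pbda_fortified", ]
  n <- tg[tg$label == "pbda_nonfortified", ]
  tot <- tibble::tibble(label = "pbda_total")
  for (comp in nv) tot[[comp]] <- w * f[[comp]] + (1 - w) * n[[comp]]
  tot$ghge_100g <- (w * f$ghge_kg + (1 - w) * n$ghge_kg) / 10
  tot$lu_100g <- (w * f$lu_kg + (1 - w) * n$lu_kg) / 10
  dplyr::bind_rows(rows$dairy, rows$pbda_fortified, rows$pbda_nonfortified,
                   tot, rows$other)
}

# Internal: sample one item block around a target row. Composition jitter uses
# one shared multiplicative factor for the fat chain (fat, sfa, pufa) and one
# for the sugar chain (carbohydrate, total_sugar, added_sugar) so the
# composition orderings hold exactly for every sampled item; remaining
# components and the indicators get independent mean-one factors.
sample_items <- function(n, target, spread, prefix) {
  if (n == 0) {
    return(tibble::tibble(item_id = character(0)))
  }
  jit <- function() 1 + runif(n, -spread, spread)
  out <- tibble::tibble(item_id = sprintf("%s_%03d", prefix, seq_len(n)))
  f_fat <- jit(); f_sugar <- jit()
  for (comp in nutrient_names()) {
    fac <- switch(comp,
      fat = , sfa = , pufa = f_fat,
      carbohydrate = , total_sugar = , added_sugar = f_sugar,
      jit()
    )
    out[[comp]] <- target[[comp]] * fac
  }
  out$ghge <- target$ghge_kg * jit()
  out$lu <- target$lu_kg * jit()
  out
}

#' Generate a synthetic food catalogue
#'
#' Draws dairy, PBDA (by base and fortification status) and background items
#' whose compositions scatter around the configured group targets with
#' mean-one jitter, so consumption-weighted group profiles recover the targets
#' in expectation. Fortified PBDA items carry a non-empty set of added
#' micronutrients and their compositions come from the (micronutrient-rich)
#' fortified target; the fortification flag set is sampled per item.
#'
#' @param config A `generator_config`.
#' @param seed Seed for this step (default: the config seed).
#' @return A validated catalogue tibble.
#' @export
generate_catalogue <- function(config, seed = config$seed) {
  set.seed(seed)
  tg <- config$targets
  trow <- function(lbl) tg[tg$label == lbl, ]
  micros <- c("vitamin_b2", "vitamin_b12", "calcium", "iron", "iodine")

  dairy <- sample_items(config$n_dairy_items, trow("dairy"), config$spread, "dairy")
  dairy$group <- "dairy"; dairy$main_ingredient <- "not_applicable"
  other <- sample_items(config$n_other_items, trow("other"), config$spread, "other")
  other$group <- "other"; other$main_ingredient <- "not_applicable"

  pbda <- list()
  for (i in seq_len(nrow(config$pbda_counts))) {
    base <- config$pbda_counts$base[i]
    nf <- config$pbda_counts$n_fortified[i]
    nn <- config$pbda_counts$n_nonfortified[i]
    f <- sample_items(nf, trow("pbda_fortified"), config$spread,
                      paste0("pbda_", base, "_f"))
    if (nf > 0) {
      f$group <- "pbda"; f$main_ingredient <- base
      f$fortified_nutrients <- lapply(seq_len(nf), function(j) {
        sort(sample(micros, sample.int(length(micros), 1)))
      })
    }
    n <- sample_items(nn, trow("pbda_nonfortified"), config$spread,
                      paste0("pbda_", base, "_n"))
    if (nn > 0) {
      n$group <- "pbda"; n$main_ingredient <- base
      n$fortified_nutrients <- replicate(nn, character(0), simplify = FALSE)
    }
    pbda[[base]] <- dplyr::bind_rows(if (nf > 0) f, if (nn > 0) n)
  }
  dairy$fortified_nutrients <- replicate(nrow(dairy), character(0), simplify = FALSE)
  other$fortified_nutrients <- replicate(nrow(other), character(0), simplify = FALSE)

  cat <- dplyr::bind_rows(dairy, dplyr::bind_rows(pbda), other)
  cat$name <- paste("synthetic", cat$group, cat$item_id)
  as_catalogue(cat[, c("item_id", "name", "group", "main_ingredient",
                       "fortified_nutrients", nutrient_names(), "ghge", "lu")])
}

#' Generate synthetic 3-day weighed dietary records
#'
#' Builds participants (sex, ages, per-participant Dirichlet item preferences
#' inducing realistic day-to-day and record-to-record correlation), draws the
#' number of records per participant, flags a configured fraction of records
#' as PBDA-containing (record-level, so the record-selection flow is
#' exercised) and a small fraction of the remainder as zero-dairy, and fills
#' each record-day with consumption entries whose grams are log-normal,
#' rounded to 0.1 g. Fortified vs non-fortified PBDA entries are allocated by
#' a deterministic global fraction equal to the fortified item share, which
#' pins the expected fortified consumption share used by [generator_truth()].
#'
#' @param config A `generator_config`.
#' @param catalogue Catalogue from [generate_catalogue()].
#' @param seed Seed for this step (default: config seed + 1, kept below 2^31).
#' @return A validated records tibble (long format).
#' @export
generate_records <- function(config, catalogue,
                             seed = (config$seed + 1L) %% .Machine$integer.max) {
  set.seed(seed)
  cat <- as_catalogue(catalogue)
  dairy_ids <- cat$item_id[cat$group == "dairy"]
  other_ids <- cat$item_id[cat$group == "other"]
  pbda_f_ids <- cat$item_id[cat$group == "pbda" & lengths(cat$fortified_nutrients) > 0]
  pbda_n_ids <- cat$item_id[cat$group == "pbda" & lengths(cat$fortified_nutrients) == 0]
  has_pbda <- length(pbda_f_ids) + length(pbda_n_ids) > 0

  np <- config$n_participants
  if (np == 0) {
    return(as_records(tibble::tibble(
      participant_id = character(0), record_id = character(0),
      sex = character(0), age_years = integer(0), day = integer(0),
      item_id = character(0), grams = numeric(0)
    )))
  }
  conc <- config$preference_concentration
  ml <- config$grams_meanlog; sl <- config$grams_sdlog
  grams_of <- function(n, grp) pmax(round(rlnorm(n, ml[[grp]], sl[[grp]]), 1), 0.1)

  rec_counter <- 0L
  parts <- vector("list", np)
  for (p in seq_len(np)) {
    pid <- sprintf("p%04d", p)
    sex <- if (runif(1) < config$sex_ratio_male) "male" else "female"
    n_rec <- sample.int(16L, 1L, prob = config$records_prob)
    ages <- sample(3:18, n_rec, replace = TRUE)
    is_pbda <- runif(n_rec) < config$pbda_consumer_fraction & has_pbda
    zero_dairy <- !is_pbda & runif(n_rec) < config$zero_dairy_fraction
    pref_dairy <- rgamma(length(dairy_ids), conc); pref_dairy <- pref_dairy / sum(pref_dairy)
    pref_other <- rgamma(length(other_ids), conc); pref_other <- pref_other / sum(pref_other)

    rec_ids <- sprintf("r%07d", rec_counter + seq_len(n_rec))
    rec_counter <- rec_counter + n_rec

    # one cell per record x day; entry counts drawn per cell, entries built
    # as flat vectors
    cell_rec <- rep(seq_len(n_rec), each = 3L)
    cell_day <- rep(1:3, times = n_rec)

    d_cells <- which(!zero_dairy[cell_rec])
    d_counts <- 1L + rpois(length(d_cells), config$dairy_entries_extra)
    d_n <- sum(d_counts)
    d_items <- sample(dairy_ids, d_n, replace = TRUE, prob = pref_dairy)
    d_grams <- grams_of(d_n, "dairy")

    o_counts <- config$other_entries_base + rpois(length(cell_rec), config$other_entries_extra)
    o_n <- sum(o_counts)
    o_items <- sample(other_ids, o_n, replace = TRUE, prob = pref_other)
    o_grams <- grams_of(o_n, "other")

    p_cells <- which(is_pbda[cell_rec])
    p_counts <- rep(config$pbda_entries_per_day, length(p_cells))
    p_n <- sum(p_counts)
    p_grams <- if (p_n > 0) grams_of(p_n, "pbda") else numeric(0)

    entry_rec <- c(rep(cell_rec[d_cells], d_counts),
                   rep(cell_rec, o_counts),
                   rep(cell_rec[p_cells], p_counts))
    entry_day <- c(rep(cell_day[d_cells], d_counts),
                   rep(cell_day, o_counts),
                   rep(cell_day[p_cells], p_counts))
    parts[[p]] <- tibble::tibble(
      participant_id = pid,
      record_id = rec_ids[entry_rec],
      sex = sex,
      age_years = ages[entry_rec],
      day = entry_day,
      item_id = c(d_items, o_items, rep(NA_character_, p_n)),  # PBDA assigned below
      grams = c(d_grams, o_grams, p_grams)
    )
  }
  rec <- dplyr::bind_rows(parts)

  # global deterministic fortified/non-fortified allocation for PBDA slots
  slot <- which(is.na(rec$item_id))
  if (length(slot) > 0) {
    w <- fortified_gram_share(config)
    i <- seq_along(slot)
    fortified_slot <- floor(i * w) - floor((i - 1) * w) > 0
    if (length(pbda_f_ids) == 0) fortified_slot[] <- FALSE
    if (length(pbda_n_ids) == 0) fortified_slot[] <- TRUE
    rec$item_id[slot[fortified_slot]] <-
      sample(pbda_f_ids, sum(fortified_slot), replace = TRUE)
    rec$item_id[slot[!fortified_slot]] <-
      sample(pbda_n_ids, sum(!fortified_slot), replace = TRUE)
  }
  as_records(rec[, c("participant_id", "record_id", "sex", "age_years",
                     "day", "item_id", "grams")])
}

#' Generate a complete synthetic cohort (catalogue + records)
#'
#' @param config A `generator_config` (or an integer, taken as the seed of a
#'   default configuration).
#' @return List with elements `catalogue`, `records`, `config`, `truth`
#'   (the implied ground-truth profiles).
#' @export
generate_cohort <- function(config) {
  if (is.numeric(config)) config <- generator_config(seed = config)
  cat <- generate_catalogue(config)
  rec <- generate_records(config, cat)
  list(catalogue = cat, records = rec, config = config,
       truth = generator_truth(config))
}

#' Write a synthetic cohort to disk with provenance
#'
#' Writes `catalogue.csv`, `records.csv` and a `provenance.json` carrying the
#' seed, the generator settings and the md5 checksums of the written files.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cat_path <- file.path(dir, "catalogue.csv")
  rec_path <- file.path(dir, "records.csv")
  write_catalogue(cohort$catalogue, cat_path)
  readr::write_csv(cohort$records, rec_path, progress = FALSE)
  cfg <- cohort$config
  cfg_json <- cfg[setdiff(names(cfg), c("targets", "pbda_counts"))]
  prov <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("pbdasub")),
    config = cfg_json,
    targets = cohort$config$targets,
    pbda_counts = cohort$config$pbda_counts,
    files = list(
      catalogue = list(path = "catalogue.csv",
                       md5 = unname(tools::md5sum(cat_path))),
      records = list(path = "records.csv",
                     md5 = unname(tools::md5sum(rec_path)))
    )
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
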