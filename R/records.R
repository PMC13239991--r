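#' Validate a long-format table of weighed dietary records
#'
#' One row per consumption entry: `participant_id`, `record_id` (unique per
#' 3-day record across the whole table), `sex` (`male`/`female`), `age_years`
#' (completed years at recording, >= 3), `day` (1-3) and `item_id`, `grams`.
#' Each record spans exactly 3 days; a day with no entries is legal (its rows
#' are simply absent) and contributes zero to the 3-day mean. An item may
#' appear multiple times per day.
#'
#' @param records A data frame as described.
#' @return The validated records tibble.
#' @export
as_records <- function(records) {
  rec <- tibble::as_tibble(records)
  required <- c("participant_id", "record_id", "sex", "age_years", "day", "item_id", "grams")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    abort(paste0("records: missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  rec$participant_id <- as.character(rec$participant_id)
  rec$record_id <- as.character(rec$record_id)
  rec$item_id <- as.character(rec$item_id)
  bad <- !rec$sex %in% c("male", "female")
  if (any(bad)) abort(paste0("records: invalid sex in row(s) ", paste(which(bad), collapse = ", ")))
  bad <- !is.finite(rec$age_years) | rec$age_years < 3 | rec$age_years != floor(rec$age_years)
  if (any(bad)) {
    abort(paste0("records: age_years must be an integer >= 3; row(s) ",
                 paste(which(bad), collapse = ", ")))
  }
  bad <- !rec$day %in% 1:3
  if (any(bad)) abort(paste0("records: day must be 1, 2 or 3; row(s) ", paste(which(bad), collapse = ", ")))
  bad <- !is.finite(rec$grams) | rec$grams < 0
  if (any(bad)) {
    abort(paste0("records: grams must be finite and non-negative; row(s) ",
                 paste(which(bad), collapse = ", ")))
  }
  # sex/age must be constant within a record
  meta <- dplyr::distinct(rec, .data$record_id, .data$participant_id, .data$sex, .data$age_years)
  dup <- duplicated(meta$record_id)
  if (any(dup)) {
    abort(paste0("records: inconsistent participant/sex/age within record(s): ",
                 paste(unique(meta$record_id[dup]), collapse = ", ")))
  }
  rec
}

#' Read weighed dietary records from CSV
#'
#' @param path Path to a long-format CSV (see [as_records()] for columns).
#' @return A validated records tibble.
#' @export
read_records <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_records(raw)
}

#' Partition dietary records for the substitution analysis
#'
#' Records containing at least one PBDA entry are diverted to the PBDA
#' profile-estimation set (their consumption defines the PBDA composition
#' profiles); of the remainder, records with zero dairy grams are excluded (a
#' substitution model is undefined when dairy intake is zero); the rest form
#' the analysis set. PBDA presence takes precedence over zero dairy, mirroring
#' the order of the study's record-selection flow.
#'
#' @param records A validated records tibble.
#' @param catalogue A validated catalogue tibble covering all consumed items.
#' @return An object of class `record_partition`: a list with tibbles
#'   `analysis_set`, `pbda_profile_set`, `excluded_no_dairy` (same long format
#'   as the input) and a `counts` tibble (records per set).
#' @export
partition_records <- function(records, catalogue) {
  rec <- as_records(records)
  cat <- as_catalogue(catalogue)
  unknown <- setdiff(unique(rec$item_id), cat$item_id)
  if (length(unknown) > 0) {
    abort(paste0("records refer to unknown item_id(s): ", paste(unknown, collapse = ", ")))
  }
  grp <- cat$group[match(rec$item_id, cat$item_id)]
  by_rec <- tibble::tibble(
    record_id = rec$record_id,
    pbda = grp == "pbda" & rec$grams >= 0,
    dairy_g = ifelse(grp == "dairy", rec$grams, 0)
  ) |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(
      has_pbda = any(.data$pbda),
      dairy_g = sum(.data$dairy_g),
      .groups = "drop"
    )
  set_of <- ifelse(by_rec$has_pbda, "pbda_profile_set",
                   ifelse(by_rec$dairy_g <= 0, "excluded_no_dairy", "analysis_set"))
  assignment <- setNames(set_of, by_rec$record_id)
  split_ids <- function(set) by_rec$record_id[set_of == set]
  out <- list(
    analysis_set = rec[rec$record_id %in% split_ids("analysis_set"), ],
    pbda_profile_set = rec[rec$record_id %in% split_ids("pbda_profile_set"), ],
    excluded_no_dairy = rec[rec$record_id %in% split_ids("excluded_no_dairy"), ],
    counts = tibble::tibble(
      set = c("total", "pbda_profile_set", "excluded_no_dairy", "analysis_set"),
      n_records = c(
        nrow(by_rec),
        sum(set_of == "pbda_profile_set"),
        sum(set_of == "excluded_no_dairy"),
        sum(set_of == "analysis_set")
      )
    )
  )
  class(out) <- c("record_partition", class(out))
  out
}

#' @export
print.record_partition <- function(x, ...) {
  cat("Record partition (PBDA presence takes precedence over zero dairy):\n")
  print(x$counts)
  invisible(x)
}

#' Compute per-record total daily intake as the 3-day mean
#'
#' For each record, daily intake of every nutrient component is the mean over
#' the 3 recording days of the sum over entries of `grams/100 x` the item's
#' per-100 g composition. Environmental indicators use per-kg values:
#' `grams/1000 x ghge` (and `lu`). The dairy contribution is the same
#' computation restricted to `group == "dairy"` items. Days without entries
#' count as zero-intake days; the divisor is always 3.
#'
#' @param records A validated records tibble.
#' @param catalogue A validated catalogue; every consumed item must exist and
#'   have `ghge`/`lu` assigned.
#' @return A tibble with one row per record: `record_id`, `participant_id`,
#'   `sex`, `age_years`, `total_grams`, the 13 nutrient totals per day (columns
#'   named as [nutrient_names()]), `ghge_day`, `lu_day`, `dairy_grams`, the
#'   13 dairy contributions prefixed `dairy_`, and `dairy_ghge_day`,
#'   `dairy_lu_day`.
#' @export
compute_daily_intake <- function(records, catalogue) {
  rec <- as_records(records)
  cat <- as_catalogue(catalogue)
  nv <- nutrient_names()

  idx <- match(rec$item_id, cat$item_id)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    msg <- paste0(rec$item_id[bad], " (record ", rec$record_id[bad], ", day ", rec$day[bad], ")")
    abort(paste0("unknown item_id(s): ", paste(unique(msg), collapse = "; ")))
  }
  ghge_item <- cat$ghge[idx]
  lu_item <- cat$lu[idx]
  consumed <- rec$grams > 0
  if (any(consumed & (is.na(ghge_item) | is.na(lu_item)))) {
    bad_ids <- unique(rec$item_id[consumed & (is.na(ghge_item) | is.na(lu_item))])
    abort(paste0("item(s) without assigned ghge/lu: ", paste(bad_ids, collapse = ", "),
                 " (use assign_similar_indicator() first)"))
  }

  is_dairy <- as.numeric(cat$group[idx] == "dairy")
  contrib <- rec[c("record_id", "grams")]
  for (comp in nv) {
    contrib[[comp]] <- rec$grams / 100 * cat[[comp]][idx]
  }
  contrib$ghge_day <- rec$grams / 1000 * ghge_item
  contrib$lu_day <- rec$grams / 1000 * lu_item
  contrib$dairy_grams <- rec$grams * is_dairy
  for (comp in nv) {
    contrib[[paste0("dairy_", comp)]] <- contrib[[comp]] * is_dairy
  }
  contrib$dairy_ghge_day <- contrib$ghge_day * is_dairy
  contrib$dairy_lu_day <- contrib$lu_day * is_dairy

  value_cols <- setdiff(names(contrib), "record_id")
  totals <- contrib |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), ~ sum(.x) / 3), .groups = "drop") |>
    dplyr::rename(total_grams = "grams")

  meta <- dplyr::distinct(rec, .data$record_id, .data$participant_id, .data$sex, .data$age_years)
  dplyr::left_join(meta, totals, by = "record_id")
}
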