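#' Validate a food-composition catalogue
#'
#' A catalogue is a tibble with one row per food item:
#' `item_id` (unique), `name`, `group` (`dairy`, `pbda` or `other`),
#' `main_ingredient` (`soy`, `oat`, `coconut`, `rice`, `almond`, `other`, or
#' `not_applicable` for non-PBDA items), `fortified_nutrients` (list-column of
#' character vectors naming the added micronutrients; empty = non-fortified),
#' the 13 per-100 g composition columns (see [nutrient_names()]), and the
#' environmental indicators `ghge` (kgCO2eq per kg of item) and `lu`
#' (m2·year per kg), which may be `NA` until assigned.
#'
#' Indicators are stored per kg (the convention of European LCA indicator
#' tables) and converted to per-100 g only where profiles are reported; the
#' conversion factor is exactly 10.
#'
#' @param catalogue A data frame as described above; `fortified_nutrients` may
#'   also be a character column with semicolon-separated names.
#' @return The validated catalogue as a tibble (invariant violations abort with
#'   row numbers).
#' @export
as_catalogue <- function(catalogue) {
  cat <- tibble::as_tibble(catalogue)
  required <- c("item_id", "name", "group", "main_ingredient", "fortified_nutrients",
                nutrient_names(), "ghge", "lu")
  missing_cols <- setdiff(required, names(cat))
  if (length(missing_cols) > 0) {
    abort(paste0("catalogue: missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  cat$item_id <- as.character(cat$item_id)
  dup <- duplicated(cat$item_id)
  if (any(dup)) {
    abort(paste0("catalogue: duplicate item_id in row(s) ",
                 paste(which(dup), collapse = ", "), ": ",
                 paste(unique(cat$item_id[dup]), collapse = ", ")))
  }
  bad <- !cat$group %in% c("dairy", "pbda", "other")
  if (any(bad)) {
    abort(paste0("catalogue: invalid group in row(s) ", paste(which(bad), collapse = ", ")))
  }
  ingredients <- c("soy", "oat", "coconut", "rice", "almond", "other", "not_applicable")
  bad <- !cat$main_ingredient %in% ingredients
  if (any(bad)) {
    abort(paste0("catalogue: invalid main_ingredient in row(s) ",
                 paste(which(bad), collapse = ", ")))
  }
  # group = pbda <=> main_ingredient != not_applicable
  bad <- (cat$group == "pbda") != (cat$main_ingredient != "not_applicable")
  if (any(bad)) {
    abort(paste0(
      "catalogue: main_ingredient must be set for PBDA items and 'not_applicable' ",
      "otherwise; violated in row(s) ", paste(which(bad), collapse = ", ")
    ))
  }
  if (!is.list(cat$fortified_nutrients)) {
    cat$fortified_nutrients <- parse_fortified(cat$fortified_nutrients)
  }
  cat$fortified_nutrients <- lapply(cat$fortified_nutrients, function(x) {
    x <- as.character(x)
    x[nzchar(x)]
  })
  check_nutrient_values(cat, where = "catalogue")
  for (ind in c("ghge", "lu")) {
    x <- cat[[ind]]
    if (!is.numeric(x)) abort(paste0("catalogue: column '", ind, "' must be numeric"))
    bad <- !is.na(x) & x < 0
    if (any(bad)) {
      abort(paste0("catalogue: negative ", ind, " in row(s) ", paste(which(bad), collapse = ", ")))
    }
  }
  cat
}

parse_fortified <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE) |>
    lapply(function(v) trimws(v)[nzchar(trimws(v))])
}

#' Read a food-composition catalogue from CSV
#'
#' One row per item; `fortified_nutrients` as a semicolon-separated list
#' (empty cell = non-fortified); empty `ghge`/`lu` cells are legal and read as
#' unassigned (`NA`). See [as_catalogue()] for the full column contract.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A validated catalogue tibble.
#' @export
read_catalogue <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_catalogue(raw)
}

#' Write a catalogue to CSV
#'
#' Inverse of [read_catalogue()]; the round-trip is lossless at full double
#' precision (list-column `fortified_nutrients` is serialised
#' semicolon-separated).
#'
#' @param catalogue A validated catalogue tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  cat <- as_catalogue(catalogue)
  cat$fortified_nutrients <- vapply(
    cat$fortified_nutrients, paste, character(1), collapse = ";"
  )
  readr::write_csv(cat, path, progress = FALSE)
  invisible(path)
}

#' Classify PBDA items as fortified
#'
#' A plant-based dairy alternative counts as fortified when at least one
#' micronutrient was added to it. The rule is defined for PBDA only; applying
#' it to dairy or other items is an error. Macronutrient additions (oils,
#' sugars) never make an item fortified: `fortified_nutrients` carries
#' micronutrient names only.
#'
#' @param catalogue A catalogue tibble containing only `group == "pbda"` rows
#'   (e.g. `dplyr::filter(catalogue, group == "pbda")`).
#' @return The input with a logical `fortified` column appended.
#' @export
classify_fortified <- function(catalogue) {
  cat <- tibble::as_tibble(catalogue)
  if (!all(c("group", "fortified_nutrients") %in% names(cat))) {
    abort("classify_fortified: need 'group' and 'fortified_nutrients' columns")
  }
  non_pbda <- cat$group != "pbda"
  if (any(non_pbda)) {
    abort(paste0(
      "classify_fortified: the fortification rule applies to PBDA items only; ",
      "non-PBDA item(s): ", paste(cat$item_id[non_pbda], collapse = ", ")
    ))
  }
  fn <- cat$fortified_nutrients
  if (!is.list(fn)) fn <- parse_fortified(fn)
  dplyr::mutate(cat, fortified = lengths(fn) > 0)
}

#' Fill missing environmental indicators from similar items
#'
#' Items absent from the indicator database are assigned the greenhouse-gas
#' and land-use values of an explicitly mapped similar entry. The mapping is
#' user-supplied editorial judgement, never inferred by the package. Items
#' whose `ghge`/`lu` are already set are left untouched.
#'
#' @param catalogue A catalogue tibble (possibly with `NA` `ghge`/`lu`).
#' @param indicator_table Tibble with columns `indicator_id`, `ghge`, `lu`
#'   (per kg of food).
#' @param mapping Tibble with columns `item_id`, `indicator_id` mapping each
#'   unassigned item to its most similar indicator entry.
#' @return The catalogue with `ghge`/`lu` filled; aborts listing any item that
#'   is both unassigned and unmapped.
#' @export
assign_similar_indicator <- function(catalogue, indicator_table, mapping) {
  cat <- as_catalogue(catalogue)
  ind <- tibble::as_tibble(indicator_table)
  map <- tibble::as_tibble(mapping)
  if (!all(c("indicator_id", "ghge", "lu") %in% names(ind))) {
    abort("indicator_table must have columns indicator_id, ghge, lu")
  }
  if (!all(c("item_id", "indicator_id") %in% names(map))) {
    abort("mapping must have columns item_id, indicator_id")
  }
  map <- dplyr::left_join(map, ind, by = "indicator_id")
  if (anyNA(map$ghge) || anyNA(map$lu)) {
    bad <- map$indicator_id[is.na(map$ghge) | is.na(map$lu)]
    abort(paste0("mapping refers to unknown/incomplete indicator entries: ",
                 paste(unique(bad), collapse = ", ")))
  }
  needs <- is.na(cat$ghge) | is.na(cat$lu)
  unmapped <- cat$item_id[needs & !cat$item_id %in% map$item_id]
  if (length(unmapped) > 0) {
    abort(paste0(
      "items lacking both a direct indicator entry and a similarity mapping: ",
      paste(unmapped, collapse = ", ")
    ))
  }
  idx <- match(cat$item_id, map$item_id)
  fill_ghge <- is.na(cat$ghge) & !is.na(idx)
  fill_lu <- is.na(cat$lu) & !is.na(idx)
  cat$ghge[fill_ghge] <- map$ghge[idx[fill_ghge]]
  cat$lu[fill_lu] <- map$lu[idx[fill_lu]]
  cat
}
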