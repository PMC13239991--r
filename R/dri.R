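#' Read a dietary-reference-intake (DRI) table
#'
#' The DRI table is input data, never hard-coded: one row per
#' (sex, age band, quantity), with half-open age bands `[age_low, age_high)`
#' in completed years, a reference value per day in the quantity's absolute
#' unit, and for energy rows a physical-activity level (`pal`:
#' `low`/`moderate`/`high`; empty for non-energy rows). Bands for a given sex
#' and quantity must be non-overlapping and cover ages 3 to <19.
#'
#' @param path CSV with columns
#'   `sex,age_low,age_high,quantity,pal,reference_value,unit`.
#' @return A validated DRI tibble.
#' @export
read_dri <- function(path) {
  dri <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(pal = readr::col_character()))
  as_dri(dri)
}

#' @rdname read_dri
#' @param dri A data frame in the `read_dri()` layout, to validate.
#' @export
as_dri <- function(dri) {
  dri <- tibble::as_tibble(dri)
  required <- c("sex", "age_low", "age_high", "quantity", "pal", "reference_value", "unit")
  missing_cols <- setdiff(required, names(dri))
  if (length(missing_cols) > 0) {
    abort(paste0("dri: missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(dri$reference_value) | dri$reference_value <= 0)) {
    abort("dri: reference values must be positive")
  }
  if (any(dri$age_low >= dri$age_high)) abort("dri: age_low must be < age_high")
  dri$pal <- ifelse(is.na(dri$pal), "", dri$pal)
  # coverage & overlap per sex x quantity (x pal for energy)
  grp <- split(dri, paste(dri$sex, dri$quantity, dri$pal))
  for (g in grp) {
    g <- g[order(g$age_low), ]
    if (nrow(g) > 1 && any(g$age_low[-1] < g$age_high[-nrow(g)])) {
      abort(paste0("dri: overlapping age bands for ", g$sex[1], "/", g$quantity[1]))
    }
    if (g$age_low[1] > 3 || g$age_high[nrow(g)] < 19 ||
        (nrow(g) > 1 && any(g$age_low[-1] != g$age_high[-nrow(g)]))) {
      abort(paste0("dri: age bands for ", g$sex[1], "/", g$quantity[1],
                   " do not cover [3, 19) without gaps"))
    }
  }
  dri
}

#' Packaged representative D-A-CH-style DRI table
#'
#' A representative reference-intake table in the style of the 2018 D-A-CH
#' (German/Austrian/Swiss) values for ages 3 to <19: energy (by low physical
#' activity level), protein, vitamins B2 and B12, calcium, iron and iodine, by
#' sex and half-open age band. These values are shipped as editable input data
#' (reference values are periodically revised); the energy rows in particular
#' are placeholders that users should replace with the edition they work with.
#'
#' @return A validated DRI tibble.
#' @export
default_dri <- function() {
  read_dri(system.file("extdata", "dri_dach2018_representative.csv",
                       package = "pbdasub", mustWork = TRUE))
}

# Internal: reference value lookup, vectorized over queries. Energy uses the
# given PAL; band membership is half-open [age_low, age_high).
dri_reference <- function(dri, sex, age_years, quantity, pal = "low") {
  n <- max(length(sex), length(age_years), length(quantity))
  sex <- rep_len(sex, n); age_years <- rep_len(age_years, n)
  quantity <- rep_len(quantity, n)
  pal_used <- ifelse(quantity == "energy", pal, "")
  qkey <- paste(sex, quantity, pal_used)
  tkey <- paste(dri$sex, dri$quantity, dri$pal)
  out <- rep(NA_real_, n)
  for (k in unique(qkey)) {
    sel <- qkey == k
    rows <- dri[tkey == k, ]
    if (nrow(rows) == 0) {
      abort(paste0("dri: no entries matching (sex quantity pal) = (", k, ")"))
    }
    rows <- rows[order(rows$age_low), ]
    pos <- findInterval(age_years[sel], rows$age_low)
    ok <- pos >= 1 & age_years[sel] < rows$age_high[pmax(pos, 1L)]
    if (any(!ok)) {
      abort(paste0("dri: age(s) ", paste(unique(age_years[sel][!ok]), collapse = ", "),
                   " outside covered bands for (", k, ")"))
    }
    out[sel] <- rows$reference_value[pos]
  }
  out
}

#' Age band label for a given age
#'
#' Labels ages by the DRI table's half-open bands (e.g. `"[7,10)"`); this is
#' also the age grouping used as an adjustment covariate in scenario
#' comparisons.
#'
#' @param age_years Integer ages in completed years.
#' @param dri DRI tibble (default: packaged table).
#' @return Character vector of band labels.
#' @export
age_band <- function(age_years, dri = default_dri()) {
  bands <- dri |>
    dplyr::distinct(.data$age_low, .data$age_high) |>
    dplyr::arrange(.data$age_low)
  out <- rep(NA_character_, length(age_years))
  for (i in seq_len(nrow(bands))) {
    hit <- age_years >= bands$age_low[i] & age_years < bands$age_high[i]
    out[hit] <- paste0("[", bands$age_low[i], ",", bands$age_high[i], ")")
  }
  if (anyNA(out)) {
    abort(paste0("age_band: age(s) outside covered bands: ",
                 paste(unique(age_years[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Percent of the dietary reference intake (%DRI)
#'
#' `100 x intake / reference(sex, age band, quantity)`. Energy is scored
#' against the low physical-activity reference.
#'
#' @param intake_amount Daily intake in the quantity's absolute unit
#'   (vectorized).
#' @param sex `"male"`/`"female"` (recycled).
#' @param age_years Completed years (recycled); band lookup is half-open
#'   `[low, high)`.
#' @param quantity Quantity name present in the DRI table (recycled).
#' @param dri DRI tibble (default: packaged table).
#' @param pal Physical-activity level used for energy (default `"low"`).
#' @return A tibble with columns `quantity`, `mode` (`"percent_dri"`) and
#'   `value` (percent).
#' @export
percent_dri <- function(intake_amount, sex, age_years, quantity, dri = default_dri(),
                        pal = "low") {
  if (any(intake_amount < 0)) abort("percent_dri: intake must be non-negative")
  ref <- dri_reference(dri, sex, age_years, quantity, pal = pal)
  n <- length(ref)
  tibble::tibble(
    quantity = rep_len(quantity, n),
    mode = "percent_dri",
    value = 100 * rep_len(intake_amount, n) / ref
  )
}

#' Percent of total daily energy intake (%E)
#'
#' `100 x grams x Atwater(component) / energy`, with 9 kcal/g for fat-type and
#' 4 kcal/g for carbohydrate-type components. Protein is scored as %DRI, not
#' %E, and is rejected here. The denominator is the energy intake of the same
#' diet (for a substitution scenario: the post-substitution energy).
#'
#' @param component_grams Daily grams of the component (vectorized).
#' @param energy_kcal_day Total daily energy intake, must be positive
#'   (recycled).
#' @param component One of `fat`, `sfa`, `pufa`, `carbohydrate`, `total_sugar`,
#'   `added_sugar` (recycled).
#' @return A tibble with columns `quantity`, `mode` (`"percent_energy"`),
#'   `value`.
#' @export
percent_energy <- function(component_grams, energy_kcal_day, component) {
  if (any(component %in% c("protein", "energy"))) {
    abort("percent_energy: protein and energy are scored as %DRI, not %E")
  }
  fac <- atwater_factor(component)
  if (any(!is.finite(energy_kcal_day) | energy_kcal_day <= 0)) {
    abort("percent_energy: energy_kcal_day must be positive")
  }
  if (any(component_grams < 0)) abort("percent_energy: grams must be non-negative")
  n <- max(length(component_grams), length(energy_kcal_day), length(component))
  tibble::tibble(
    quantity = rep_len(component, n),
    mode = "percent_energy",
    value = 100 * rep_len(component_grams, n) * rep_len(fac, n) / rep_len(energy_kcal_day, n)
  )
}

#' Score a daily-intake table as %DRI / %E plus absolute indicators
#'
#' Converts the wide per-record intake of [compute_daily_intake()] (or a
#' scenario result) into the long adequacy layout: energy, protein and the
#' micronutrients as %DRI; the other macronutrients as %E of the same diet's
#' energy; greenhouse-gas emission and land use as absolute kgCO2eq/day and
#' m2·year/day.
#'
#' @param intake Wide intake tibble with `record_id`, `sex`, `age_years`, the
#'   13 nutrient columns and `ghge_day`, `lu_day`.
#' @param dri DRI tibble.
#' @param pal Physical-activity level for the energy reference.
#' @return Long tibble: `record_id`, `quantity`, `mode`
#'   (`percent_dri`/`percent_energy`/`absolute`), `value`.
#' @export
score_adequacy <- function(intake, dri = default_dri(), pal = "low") {
  info <- nutrient_info()
  out <- vector("list", nrow(info) + 2L)
  for (i in seq_len(nrow(info))) {
    comp <- info$component[i]
    if (info$mode[i] == "percent_dri") {
      sc <- percent_dri(intake[[comp]], intake$sex, intake$age_years, comp,
                        dri = dri, pal = pal)
    } else {
      sc <- percent_energy(intake[[comp]], intake$energy, comp)
    }
    sc$record_id <- intake$record_id
    out[[i]] <- sc
  }
  out[[nrow(info) + 1L]] <- tibble::tibble(
    quantity = "ghge", mode = "absolute", value = intake$ghge_day,
    record_id = intake$record_id
  )
  out[[nrow(info) + 2L]] <- tibble::tibble(
    quantity = "lu", mode = "absolute", value = intake$lu_day,
    record_id = intake$record_id
  )
  dplyr::bind_rows(out)[, c("record_id", "quantity", "mode", "value")]
}
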