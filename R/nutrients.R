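#' Nutrient components tracked by the pipeline
#'
#' The composition of every food item, group profile and daily intake is a
#' 13-component vector: energy plus the nutrients that dairy foods supply in
#' substantial amounts and that are potentially critical in childhood and
#' adolescence (protein; fat with its saturated and polyunsaturated fractions;
#' carbohydrates with total and added sugars; vitamins B2 and B12; calcium,
#' iron and iodine).
#'
#' @return Character vector of the 13 component names, in canonical order.
#' @export
#' @examples
#' nutrient_names()
nutrient_names <- function() {
  c(
    "energy", "protein", "fat", "sfa", "pufa",
    "carbohydrate", "total_sugar", "added_sugar",
    "vitamin_b2", "vitamin_b12", "calcium", "iron", "iodine"
  )
}

#' Metadata for the nutrient components
#'
#' Units, adequacy-scoring mode and Atwater energy factors for each component.
#' Macronutrients other than protein are scored as percent of total daily
#' energy intake (%E, Atwater 9 kcal/g for fat-type, 4 kcal/g for
#' carbohydrate-type components); energy, protein and the micronutrients are
#' scored against a dietary reference intake (%DRI).
#'
#' @return A tibble with columns `component`, `unit_100g` (unit of the per-100 g
#'   composition), `unit_day` (unit of daily intake), `mode`
#'   (`"percent_dri"` or `"percent_energy"`) and `atwater` (kcal/g, `NA` where
#'   %E does not apply).
#' @export
nutrient_info <- function() {
  tibble::tibble(
    component = nutrient_names(),
    unit_100g = c(
      "kcal/100g", "g/100g", "g/100g", "g/100g", "g/100g",
      "g/100g", "g/100g", "g/100g",
      "mg/100g", "ug/100g", "mg/100g", "mg/100g", "ug/100g"
    ),
    unit_day = c(
      "kcal/day", "g/day", "g/day", "g/day", "g/day",
      "g/day", "g/day", "g/day",
      "mg/day", "ug/day", "mg/day", "mg/day", "ug/day"
    ),
    mode = c(
      "percent_dri", "percent_dri",
      "percent_energy", "percent_energy", "percent_energy",
      "percent_energy", "percent_energy", "percent_energy",
      "percent_dri", "percent_dri", "percent_dri", "percent_dri", "percent_dri"
    ),
    atwater = c(NA, NA, 9, 9, 9, 4, 4, 4, NA, NA, NA, NA, NA)
  )
}

#' Atwater energy-conversion factors
#'
#' @param component One of the %E-eligible components (`fat`, `sfa`, `pufa`,
#'   `carbohydrate`, `total_sugar`, `added_sugar`).
#' @return kcal per gram (9 for fat-type, 4 for carbohydrate-type components).
#' @export
atwater_factor <- function(component) {
  info <- nutrient_info()
  idx <- match(component, info$component)
  if (anyNA(idx)) {
    abort(paste0("Unknown component(s): ", paste(component[is.na(idx)], collapse = ", ")))
  }
  fac <- info$atwater[idx]
  if (anyNA(fac)) {
    abort(paste0(
      "No Atwater factor for: ", paste(component[is.na(fac)], collapse = ", "),
      " (energy and protein/micronutrients are scored as %DRI, not %E)"
    ))
  }
  fac
}

# Internal: check a data frame of per-100 g (or per-day) nutrient values for
# the composition invariants. Returns invisibly; aborts with row numbers.
check_nutrient_values <- function(df, where = "data", rows = seq_len(nrow(df)),
                                  tol = 1e-9) {
  nv <- nutrient_names()
  missing_cols <- setdiff(nv, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(where, ": missing nutrient column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad_row <- function(flag) paste(rows[which(flag)], collapse = ", ")
  for (comp in nv) {
    x <- df[[comp]]
    if (!is.numeric(x)) abort(paste0(where, ": column '", comp, "' must be numeric"))
    bad <- !is.finite(x) | x < 0
    if (any(bad)) {
      abort(paste0(where, ": negative or non-finite '", comp, "' in row(s) ", bad_row(bad)))
    }
  }
  bad <- df$added_sugar > df$total_sugar + tol
  if (any(bad)) {
    abort(paste0(where, ": added_sugar > total_sugar in row(s) ", bad_row(bad)))
  }
  bad <- df$total_sugar > df$carbohydrate + tol
  if (any(bad)) {
    abort(paste0(where, ": total_sugar > carbohydrate in row(s) ", bad_row(bad)))
  }
  bad <- df$sfa + df$pufa > df$fat + tol
  if (any(bad)) {
    abort(paste0(where, ": sfa + pufa > fat in row(s) ", bad_row(bad)))
  }
  invisible(df)
}
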