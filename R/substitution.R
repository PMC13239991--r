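scenario_models <- function() {
  c(model1_total_pbda = "pbda_total",
    model2_fortified_pbda = "pbda_fortified",
    model3_soy_pbda = "pbda_soy",
    model3_oat_pbda = "pbda_oat")
}

#' Gram-for-gram substitution of dairy intake with a replacement profile
#'
#' Replaces a fraction `lambda` of each record's dairy grams with the same
#' quantity of a PBDA group profile. For each nutrient component c:
#'
#' `result_c = total_c - lambda * dairy_contribution_c
#'             + lambda * dairy_grams/100 * replacement_c`
#'
#' and analogously for the daily environmental indicators with the
#' replacement's per-100 g values. Total grams are unchanged (gram-for-gram),
#' energy is not held constant, and only items of the dairy group are ever
#' replaced — composite foods with dairy ingredients are untouched because the
#' dairy contribution is computed from `group == "dairy"` items only.
#'
#' By default the subtracted term is the record's own dairy contribution
#' (each record's actual dairy composition); `subtract = "mean_profile"`
#' subtracts `lambda * dairy_grams/100 x` a mean dairy profile instead
#' (sensitivity variant; requires `dairy_profile`).
#'
#' @param baseline Wide intake tibble from [compute_daily_intake()]; every row
#'   must have `dairy_grams > 0` (zero-dairy records are excluded upstream).
#' @param replacement One-row profile tibble (from [estimate_profile()],
#'   [profile_suite()] or [table3_profiles()]).
#' @param lambda Substitution level in `[0, 1]` (0 = baseline; the study
#'   levels are 0.25, 0.5, 0.75, 1).
#' @param model Scenario label stored in the output (default: the replacement
#'   profile's label).
#' @param subtract `"record"` (default) or `"mean_profile"`.
#' @param dairy_profile One-row dairy profile, required for
#'   `subtract = "mean_profile"`.
#' @return A tibble shaped like `baseline` (same `record_id`, metadata and
#'   `total_grams`) with substituted nutrient and indicator columns, plus
#'   `model`, `level` and `subtract` metadata columns.
#' @export
substitute_intake <- function(baseline, replacement, lambda,
                              model = replacement$label,
                              subtract = c("record", "mean_profile"),
                              dairy_profile = NULL) {
  subtract <- match.arg(subtract)
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("substitute_intake: lambda must be a single number in [0, 1]")
  }
  if (nrow(replacement) != 1) abort("substitute_intake: replacement must be a one-row profile")
  if (any(baseline$dairy_grams <= 0)) {
    abort(paste0(
      "substitute_intake: record(s) with zero dairy intake: ",
      paste(head(baseline$record_id[baseline$dairy_grams <= 0], 5), collapse = ", "),
      " (a substitution model is undefined when dairy intake is zero; ",
      "exclude them with partition_records())"
    ))
  }
  nv <- nutrient_names()
  want_indicators <- all(c("ghge_day", "lu_day") %in% names(baseline))
  if (want_indicators && (is.na(replacement$ghge_100g) || is.na(replacement$lu_100g))) {
    abort(paste0("substitute_intake: replacement profile '", replacement$label,
                 "' has no ghge_100g/lu_100g (baseline carries indicators)"))
  }
  out <- baseline
  g100 <- baseline$dairy_grams / 100
  for (comp in nv) {
    out[[comp]] <- baseline[[comp]] - lambda * baseline[[paste0("dairy_", comp)]] +
      lambda * g100 * replacement[[comp]]
  }
  if (want_indicators) {
    out$ghge_day <- baseline$ghge_day - lambda * baseline$dairy_ghge_day +
      lambda * g100 * replacement$ghge_100g
    out$lu_day <- baseline$lu_day - lambda * baseline$dairy_lu_day +
      lambda * g100 * replacement$lu_100g
  }
  if (subtract == "mean_profile") {
    if (is.null(dairy_profile)) {
      abort("substitute_intake: subtract = 'mean_profile' requires dairy_profile")
    }
    for (comp in nv) {
      out[[comp]] <- baseline[[comp]] - lambda * g100 * dairy_profile[[comp]] +
        lambda * g100 * replacement[[comp]]
    }
    if (want_indicators) {
      out$ghge_day <- baseline$ghge_day - lambda * g100 * dairy_profile$ghge_100g +
        lambda * g100 * replacement$ghge_100g
      out$lu_day <- baseline$lu_day - lambda * g100 * dairy_profile$lu_100g +
        lambda * g100 * replacement$lu_100g
    }
  }
  out$model <- model
  out$level <- lambda
  out$subtract <- subtract
  out
}

#' Run the scenario grid: records x models x substitution levels
#'
#' For every analysis-set record, every requested model and every substitution
#' level, substitutes dairy intake with the model's replacement profile and
#' scores the result as %DRI/%E (with the %E denominator following the
#' scenario's own energy) plus absolute daily greenhouse-gas emission and land
#' use. Baseline (level 0, current intake) rows are included once under
#' `model = "baseline"`.
#'
#' @param intake Wide intake tibble of the analysis set
#'   ([compute_daily_intake()] on the analysis records).
#' @param profiles Profile tibble with a row for every replacement profile the
#'   requested models need (`pbda_total`, `pbda_fortified`, `pbda_soy`,
#'   `pbda_oat`), e.g. [profile_suite()] output or [table3_profiles()].
#' @param dri DRI tibble for adequacy scoring.
#' @param models Character subset of `model1_total_pbda`,
#'   `model2_fortified_pbda`, `model3_soy_pbda`, `model3_oat_pbda`.
#' @param levels Substitution levels (default 0.25, 0.5, 0.75, 1).
#' @param subtract,dairy_profile Passed to [substitute_intake()].
#' @param pal Physical-activity level for the energy DRI.
#' @return Long tibble: `record_id`, `sex`, `age_band`, `model`, `level`,
#'   `quantity`, `mode`, `value`.
#' @export
run_scenario_grid <- function(intake, profiles, dri = default_dri(),
                              models = names(scenario_models()),
                              levels = c(0.25, 0.5, 0.75, 1),
                              subtract = "record", dairy_profile = NULL,
                              pal = "low") {
  if (nrow(intake) == 0) abort("run_scenario_grid: empty analysis set")
  unknown <- setdiff(models, names(scenario_models()))
  if (length(unknown) > 0) {
    abort(paste0("run_scenario_grid: unknown model(s): ", paste(unknown, collapse = ", ")))
  }
  needed <- unname(scenario_models()[models])
  missing_prof <- setdiff(needed, profiles$label)
  if (length(missing_prof) > 0) {
    abort(paste0("run_scenario_grid: profiles missing for: ",
                 paste(missing_prof, collapse = ", ")))
  }
  meta <- tibble::tibble(
    record_id = intake$record_id,
    sex = intake$sex,
    age_band = age_band(intake$age_years, dri)
  )
  score_one <- function(wide, model, level) {
    score_adequacy(wide, dri = dri, pal = pal) |>
      dplyr::left_join(meta, by = "record_id") |>
      dplyr::mutate(model = model, level = level) |>
      dplyr::select("record_id", "sex", "age_band", "model", "level",
                    "quantity", "mode", "value")
  }
  out <- list(score_one(intake, "baseline", 0))
  for (m in models) {
    repl <- profiles[profiles$label == scenario_models()[[m]], ][1, ]
    for (lam in levels) {
      wide <- substitute_intake(intake, repl, lam, model = m,
                                subtract = subtract, dairy_profile = dairy_profile)
      out[[length(out) + 1L]] <- score_one(wide, m, lam)
    }
  }
  dplyr::bind_rows(out)
}
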