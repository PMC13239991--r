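#' Baseline (current-intake) summary table
#'
#' Medians and quartiles of total daily intake and of the dairy contribution
#' for every nutrient component, total grams and the environmental indicators,
#' plus the median per-record dairy share of each quantity (computed per
#' record, then summarised — shares of medians are not reported).
#'
#' @param intake Wide intake tibble from [compute_daily_intake()].
#' @return Tibble with one row per quantity: medians/quartiles of total and
#'   dairy intake and `dairy_share_pct` (median per-record percent of total).
#' @export
baseline_summary <- function(intake) {
  quantities <- c("total_grams", nutrient_names(), "ghge_day", "lu_day")
  dairy_of <- c(total_grams = "dairy_grams",
                setNames(paste0("dairy_", nutrient_names()), nutrient_names()),
                ghge_day = "dairy_ghge_day", lu_day = "dairy_lu_day")
  rows <- lapply(quantities, function(qt) {
    tot <- intake[[qt]]
    da <- intake[[dairy_of[[qt]]]]
    share <- ifelse(tot > 0, 100 * da / tot, NA_real_)
    t_q <- unname(quantile(tot, c(0.25, 0.5, 0.75), type = 7))
    d_q <- unname(quantile(da, c(0.25, 0.5, 0.75), type = 7))
    tibble::tibble(
      quantity = qt, n = length(tot),
      total_median = t_q[2], total_q1 = t_q[1], total_q3 = t_q[3],
      dairy_median = d_q[2], dairy_q1 = d_q[1], dairy_q3 = d_q[3],
      dairy_share_pct = median(share, na.rm = TRUE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Scenario report table for one substitution model
#'
#' Lays out one model's results the way the published scenario tables do:
#' one row per quantity, with the median at each substitution level and the
#' Tukey-adjusted p-value of the comparison with current intake.
#'
#' @param grid Long scenario tibble from [run_scenario_grid()].
#' @param comparisons Output of [compare_scenarios()] on the same grid.
#' @param model One model label present in the grid.
#' @return A tibble with columns `quantity`, `mode`, `baseline_median`, then
#'   `median_<level>` and `p_<level>` per substitution level.
#' @export
scenario_table <- function(grid, comparisons, model) {
  if (!model %in% grid$model) abort(paste0("scenario_table: model '", model, "' not in grid"))
  sm <- scenario_summary(grid)
  base <- sm[sm$model == "baseline", c("quantity", "mode", "median")]
  names(base)[3] <- "baseline_median"
  msm <- sm[sm$model == model, ]
  cmp <- comparisons[comparisons$model == model, ]
  out <- base
  for (lam in sort(unique(msm$level))) {
    med <- msm[msm$level == lam, c("quantity", "median")]
    names(med)[2] <- sprintf("median_%d", as.integer(round(lam * 100)))
    pv <- cmp[cmp$level == lam, c("quantity", "p_adj")]
    names(pv)[2] <- sprintf("p_%d", as.integer(round(lam * 100)))
    out <- dplyr::left_join(out, med, by = "quantity")
    out <- dplyr::left_join(out, pv, by = "quantity")
  }
  ord <- c(nutrient_names(), "ghge", "lu")
  out[order(match(out$quantity, ord)), ]
}

#' Run the full substitution pipeline
#'
#' Orchestrates record selection, baseline intake, profile estimation, the
#' scenario grid, the scenario-vs-baseline comparisons and all report
#' artifacts, with a run manifest for provenance. Internal computation is in
#' full floating point; rounding happens only at serialisation.
#'
#' @param records Records tibble or path to a records CSV.
#' @param catalogue Catalogue tibble or path to a catalogue CSV.
#' @param dri DRI tibble or path to a DRI CSV (default: packaged table).
#' @param out_dir Output directory (created if missing).
#' @param models,levels Scenario grid to run.
#' @param profile_source `"estimated"` (consumption-weighted profiles from the
#'   data) or `"table3"` (the packaged published profiles).
#' @param subtract Dairy-subtraction variant, see [substitute_intake()].
#' @param alpha Significance level for the comparisons.
#' @param pal Physical-activity level for the energy DRI.
#' @param seed Optional seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param verbose Emit one structured message per stage with row counts.
#' @return Invisibly, a list with the in-memory results (`partition`,
#'   `intake`, `profiles`, `grid`, `comparisons`, `tables`, `manifest`) and
#'   the written file paths.
#' @export
run_pipeline <- function(records, catalogue, dri = default_dri(), out_dir,
                         models = names(scenario_models()),
                         levels = c(0.25, 0.5, 0.75, 1),
                         profile_source = c("estimated", "table3"),
                         subtract = "record", alpha = 0.05, pal = "low",
                         seed = NULL, verbose = TRUE) {
  profile_source <- match.arg(profile_source)
  say <- function(...) if (verbose) inform(paste0("[pbdasub] ", ...))
  if (is.character(records)) records <- read_records(records)
  if (is.character(catalogue)) catalogue <- read_catalogue(catalogue)
  if (is.character(dri)) dri <- read_dri(dri)
  records <- as_records(records)
  catalogue <- as_catalogue(catalogue)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  part <- partition_records(records, catalogue)
  say("partition: ", paste(part$counts$set, part$counts$n_records,
                           sep = "=", collapse = ", "))
  if (nrow(part$analysis_set) == 0) abort("run_pipeline: empty analysis set")

  intake <- compute_daily_intake(part$analysis_set, catalogue)
  say("daily intake: ", nrow(intake), " records")

  warnings_log <- character(0)
  profiles <- if (profile_source == "estimated") {
    withCallingHandlers(
      profile_suite(part, catalogue),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  } else {
    table3_profiles(fill_indicators = TRUE)
  }
  say("profiles: ", paste(profiles$label, collapse = ", "))
  models <- models[scenario_models()[models] %in% profiles$label]
  if (length(models) == 0) abort("run_pipeline: no runnable model (missing profiles)")

  dairy_prof <- if (subtract == "mean_profile") {
    profiles[profiles$label == "dairy", ]
  } else NULL
  grid <- run_scenario_grid(intake, profiles, dri = dri, models = models,
                            levels = levels, subtract = subtract,
                            dairy_profile = dairy_prof, pal = pal)
  say("scenario grid: ", nrow(grid), " rows (",
      length(models), " models x ", length(levels), " levels)")

  comparisons <- compare_scenarios(grid, alpha = alpha)
  say("comparisons: ", nrow(comparisons), " contrasts")

  # ---- artifacts (rounding at serialisation only) ----
  paths <- list()
  w <- function(df, name, digits = NULL) {
    path <- file.path(out_dir, name)
    if (!is.null(digits)) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], round, digits = digits)
    }
    readr::write_csv(df, path, progress = FALSE)
    paths[[name]] <<- path
    path
  }
  part_path <- file.path(out_dir, "partition_report.json")
  jsonlite::write_json(
    setNames(as.list(part$counts$n_records), part$counts$set),
    part_path, auto_unbox = TRUE
  )
  paths[["partition_report.json"]] <- part_path
  w(baseline_summary(intake), "baseline_summary.csv", digits = 4)
  prof_out <- profiles
  w(prof_out, "profiles.csv", digits = 2)
  tables <- list()
  for (m in models) {
    tb <- scenario_table(grid, comparisons, m)
    tables[[m]] <- tb
    num <- vapply(tb, is.numeric, logical(1)) & startsWith(names(tb), "median")
    tb[num] <- lapply(tb[num], round, digits = 1)
    tb$baseline_median <- round(tb$baseline_median, 1)
    for (pc in grep("^p_", names(tb), value = TRUE)) {
      tb[[pc]] <- format_pvalue(tb[[pc]])
    }
    w(tb, paste0("scenario_", m, ".csv"))
  }
  w(grid, "scenario_grid.csv", digits = 6)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pbdasub")),
    seed = seed,
    settings = list(models = models, levels = levels,
                    profile_source = profile_source, subtract = subtract,
                    alpha = alpha, pal = pal),
    counts = setNames(as.list(part$counts$n_records), part$counts$set),
    n_analysis_records = nrow(intake),
    n_grid_rows = nrow(grid),
    warnings = warnings_log,
    note = paste("Records are treated as independent observations;",
                 "scenario p-values are descriptive (scenario values are",
                 "deterministic transforms of baseline intake)."),
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("manifest: ", manifest_path)

  invisible(list(partition = part, intake = intake, profiles = profiles,
                 grid = grid, comparisons = comparisons, tables = tables,
                 manifest = manifest, paths = c(paths, manifest = manifest_path)))
}
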