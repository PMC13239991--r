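#' Plot adequacy medians across substitution levels
#'
#' One line per substitution model, faceted by quantity: the median %DRI/%E
#' (or absolute indicator) against the substitution level, with the baseline
#' at level 0 and a reference line at 100 for %DRI panels.
#'
#' @param grid Long scenario tibble from [run_scenario_grid()].
#' @param quantities Quantities to facet (default: all in the grid).
#' @return A ggplot object.
#' @export
plot_scenario_adequacy <- function(grid, quantities = unique(grid$quantity)) {
  sm <- scenario_summary(grid)
  sm <- sm[sm$quantity %in% quantities, ]
  base <- sm[sm$model == "baseline", ]
  models <- setdiff(unique(sm$model), "baseline")
  lines <- dplyr::bind_rows(lapply(models, function(m) {
    dplyr::bind_rows(dplyr::mutate(base, model = m), sm[sm$model == m, ])
  }))
  ref <- dplyr::distinct(lines, .data$quantity, .data$mode) |>
    dplyr::filter(.data$mode == "percent_dri") |>
    dplyr::mutate(yint = 100)
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$level, y = .data$median,
                                      colour = .data$model)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$yint),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "substitution level (fraction of dairy grams replaced)",
                  y = "median adequacy (%DRI / %E) or daily indicator",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Compare per-100 g group profiles graphically
#'
#' @param profiles Profile tibble ([profile_suite()] or [table3_profiles()]).
#' @param components Components to show (default: all 13).
#' @return A ggplot object (bars per group, faceted by component, free scales
#'   because units differ).
#' @export
plot_profile_comparison <- function(profiles, components = nutrient_names()) {
  long <- tidyr::pivot_longer(profiles, dplyr::all_of(components),
                              names_to = "component", values_to = "per_100g")
  long$component <- factor(long$component, levels = components)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$per_100g,
                                     fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "content per 100 g") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot scenario-vs-baseline contrasts with simultaneous Tukey intervals
#'
#' @param object A `pbda_comparison` object from [compare_to_baseline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pbda_comparison
autoplot.pbda_comparison <- function(object, ...) {
  ci <- stats::confint(object$glht)$confint
  keep <- rownames(ci) %in% paste0(object$contrasts$scenario, " - ", object$baseline) |
    rownames(ci) %in% paste0(object$baseline, " - ", object$contrasts$scenario)
  df <- tibble::tibble(
    contrast = rownames(ci)[keep],
    estimate = ci[keep, "Estimate"],
    lwr = ci[keep, "lwr"],
    upr = ci[keep, "upr"]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lwr, xmax = .data$upr)) +
    ggplot2::labs(x = "difference to current intake (simultaneous 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
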