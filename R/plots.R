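# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_errorbar labs theme_minimal facet_wrap position_dodge geom_col
NULL

#' Plot a usual-intake distribution's percentile curve
#'
#' @param object A [estimate_usual_intake()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nutshift_usual_intake <- function(object, ...) {
  ggplot(object$percentiles, aes(x = .data$p, y = .data$value)) +
    geom_line(color = "#2c7fb8") +
    labs(x = "population percentile",
         y = paste("usual intake of", object$nutrient),
         title = sprintf("Usual-intake distribution (mean %.3g, 95%% CI %.3g-%.3g)",
                         object$mean$estimate, object$mean$lower,
                         object$mean$upper)) +
    theme_minimal()
}

#' Dose-response plot for usual-intake means
#'
#' @param usual_intake The `usual_intake` table from [run_pipeline()] (or
#'   any tibble with `nutrient`, `group`, `dose`, `estimate`, `lower`,
#'   `upper`).
#' @return A ggplot faceted by nutrient.
#' @export
plot_dose_response <- function(usual_intake) {
  ggplot(usual_intake,
         aes(x = .data$dose, y = .data$estimate, color = .data$group)) +
    geom_line() +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.1) +
    facet_wrap(~nutrient, scales = "free_y") +
    labs(x = "meat replaced (oz eq/day)", y = "usual intake mean (95% CI)",
         color = NULL) +
    theme_minimal()
}

#' Plot the HEI-2015 dose-response by reporting group
#'
#' @param table3 The `table3` tibble from [hei_dose_table()].
#' @param groups Optional subset of groups to show.
#' @return A ggplot.
#' @export
plot_hei_dose <- function(table3, groups = NULL) {
  if (!is.null(groups)) table3 <- table3 %>% filter(.data$group %in% groups)
  ggplot(table3, aes(x = .data$dose, y = .data$estimate,
                     color = .data$group)) +
    geom_line() +
    geom_point(aes(shape = dplyr::coalesce(.data$significant, FALSE))) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.1) +
    labs(x = "meat replaced (oz eq/day)", y = "HEI-2015 total (95% CI)",
         shape = "non-overlapping CI", color = NULL) +
    theme_minimal()
}
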