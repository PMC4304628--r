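outcome_colors <- c(insignificant = "grey60", harmful = "#d62728",
                    beneficial = "#1f77b4")

#' Dose-response curves colored by trial outcome
#'
#' The ensemble's relative-mutation-rate curves versus selenium level:
#' grey for insignificant, red for harmful, blue for beneficial sets.
#' All curves pass through 1 at the baseline selenium level by
#' construction.
#'
#' @param records ensemble tibble with `set_id`, a `dose_response`
#'   list-column and (optionally) a `label` column.
#' @return a ggplot object.
#' @export
plot_dose_response <- function(records) {
  curves <- dplyr::bind_rows(
    purrr::map2(records$set_id, records$dose_response,
                ~ dplyr::bind_cols(tibble::tibble(set_id = .x), .y)))
  if ("label" %in% names(records)) {
    curves <- dplyr::left_join(
      curves, records[, c("set_id", "label")], by = "set_id")
  } else curves$label <- "insignificant"
  curves$label <- factor(curves$label, names(outcome_colors))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$selenium_mM,
                               y = .data$relative_mutation_rate,
                               group = .data$set_id,
                               color = .data$label)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = outcome_colors, drop = FALSE,
                                name = "trial outcome") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "selenium (mM)",
                  y = "mutation rate relative to baseline") +
    ggplot2::theme_minimal()
}

#' Relative-influence bar chart
#'
#' @param influence tibble from [relative_influence()].
#' @return a ggplot object.
#' @export
plot_influence <- function(influence) {
  influence$parameter <- stats::reorder(influence$parameter,
                                        influence$relative_influence_pct)
  ggplot2::ggplot(influence,
                  ggplot2::aes(x = .data$relative_influence_pct,
                               y = .data$parameter)) +
    ggplot2::geom_col(fill = "#1f77b4") +
    ggplot2::labs(x = "relative influence (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hazard curve
#'
#' @param object a `hazard_curve`.
#' @param ... unused.
#' @return a ggplot object with hazard and survival panels.
#' @export
autoplot.hazard_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("hazard", "survival"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line(color = "#1f77b4") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an incidence fit
#'
#' Observed versus fitted age-specific rates.
#'
#' @param object an `onset_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.onset_fit <- function(object, ...) {
  df <- object$residuals
  df$age_mid <- (df$age_low + df$age_high) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        color = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       color = "#1f77b4") +
    ggplot2::labs(x = "age (years)",
                  y = "incidence per 100,000 person-years") +
    ggplot2::theme_minimal()
}
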