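#' Plot a life table
#'
#' Survivorship on a log scale, the standard cohort survival display.
#'
#' @param object a [build_life_table()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cp_life_table
#' @export
autoplot.cp_life_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$age_week, y = .data$survivorship)) +
    ggplot2::geom_step(linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (weeks)", y = "Survivorship l(x) (log scale)") +
    ggplot2::theme_minimal()
}

#' Plot a mean-standardized trajectory
#'
#' Relative values with the reference line at 1 (the post-maturation
#' mean) and a span-0.75 weighted LOESS smooth.
#'
#' @param object a [mean_standardize()] result.
#' @param span smoothing span.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cp_trajectory
#' @export
autoplot.cp_trajectory <- function(object, span = 0.75, ...) {
  sm <- loess_smooth(object$age_week, object$relative_value, span = span,
                     degree = 2, weights = object$weight)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_week, y = .data$relative_value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(
      data = tibble(age_week = sm$age, relative_value = sm$fitted),
      colour = "steelblue", linewidth = 1
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "Age (weeks)",
      y = paste0("Relative ", attr(object, "source") %||% "value")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fecundity schedule
#'
#' @param object a [fecundity_schedule()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cp_schedule
#' @export
autoplot.cp_schedule <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$age_week, y = .data$mean_per_queen)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_queens_alive), alpha = 0.4) +
    ggplot2::scale_size_continuous(name = "queens alive") +
    ggplot2::labs(
      x = "Age (weeks)",
      y = paste0("Mean ", attr(object, "measure") %||% "output", " per queen")
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of lifetime production by treatment
#'
#' @param summaries a [lifetime_totals()] tibble.
#' @param measures which totals to show.
#' @return A ggplot.
#' @export
plot_investment <- function(summaries,
                            measures = c("eggs", "worker_pupae",
                                         "queen_pupae")) {
  df <- as_tibble(summaries) %>%
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$treatment_workers),
                                   y = .data$count)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Workers per colony", y = "Lifetime total") +
    ggplot2::theme_minimal()
}

#' Plot weekly caste-ratio curves
#'
#' @param curve a [caste_ratio_curve()] tibble.
#' @return A ggplot.
#' @export
plot_caste_ratio <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$age_week, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "firebrick",
                       na.rm = TRUE) +
    ggplot2::facet_wrap(~lifespan_class) +
    ggplot2::labs(x = "Age (weeks)", y = "Queen / (queen + worker) pupae") +
    ggplot2::theme_minimal()
}
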