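#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Pareto front
#'
#' Stage-1 fronts are drawn as delay index against occupancy rate, coloured
#' by the emergency admission rate; stage-2 fronts as added beds against
#' similarity.
#'
#' @param object An `icu_front`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icu_front <- function(object, ...) {
  if (attr(object, "stage") == 1L) {
    ggplot2::ggplot(tidy(object),
                    ggplot2::aes(x = .data$f12, y = .data$f11,
                                 colour = .data$f13)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(x = "delay index (f12)", y = "occupancy rate (f11)",
                    colour = "emergency\nrate (f13)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tidy(object),
                    ggplot2::aes(x = .data$f22, y = .data$f21)) +
      ggplot2::geom_step(direction = "vh", linetype = 3) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(x = "added beds (f22)", y = "similarity (f21)") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-day occupancy distributions
#'
#' @param object An `icu_occupancy` from [occupancy_report()].
#' @param solutions Optional subset of solution indices.
#' @param ... Unused.
#' @return A ggplot object, faceted by day.
#' @export
autoplot.icu_occupancy <- function(object, solutions = NULL, ...) {
  d <- if (is.null(solutions)) object else {
    dplyr::filter(object, .data$solution %in% solutions)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beds, y = .data$prob,
                                  colour = factor(.data$solution))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~day, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "occupied beds", y = "probability", colour = "solution") +
    ggplot2::theme_minimal()
}

#' Bed-layout tile plot of one schedule
#'
#' @param s An `icu_schedule`.
#' @param inst The `icu_instance`.
#' @return A ggplot object: days on the x axis, beds on the y axis, tiles
#'   coloured by patient category and labelled with patient ids.
#' @export
plot_schedule <- function(s, inst) {
  tab <- schedule_table(s, inst)
  tab$bed <- factor(tab$bed, levels = unique(tab$bed[order(
    as.integer(sub("^B", "", tab$bed)))]))
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$day), y = .data$bed,
                                    fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$patient_id), size = 2.5) +
    ggplot2::labs(x = "day", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scenario sweep
#'
#' @param object An `icu_sweep` from [scenario_sweep()].
#' @param ... Unused.
#' @return A ggplot of mean added beds and similarity per scenario and
#'   strategy.
#' @export
autoplot.icu_sweep <- function(object, ...) {
  d <- object |>
    dplyr::group_by(.data$scenario, .data$strategy) |>
    dplyr::summarise(f21 = mean(.data$f21), f22 = mean(.data$f22),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("f21", "f22"), names_to = "objective")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario, y = .data$value,
                                  colour = .data$strategy,
                                  group = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~objective, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
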