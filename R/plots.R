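#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a category structure and a decision boundary
#'
#' Scatter of a sampled exemplar set colored by category, with component
#' means marked and an optional linear boundary overlaid (by default the
#' optimal boundary).
#'
#' @param object A [category_structure()].
#' @param n_per_category Exemplars per category to display.
#' @param boundary A [linear_boundary()], `NULL` to compute the optimal
#'   boundary, or `NA` to omit.
#' @param seed Seed for the displayed sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.category_structure <- function(object, n_per_category = 150,
                                        boundary = NULL, seed = 1, ...) {
  ex <- sample_exemplars(object, n_per_category, seed = seed, normalize = FALSE)
  p <- ggplot2::ggplot(ex, ggplot2::aes(x = .data$x_level, y = .data$y_level,
                                        colour = .data$category,
                                        shape = .data$category)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(
      data = object$components,
      ggplot2::aes(x = .data$mu_x, y = .data$mu_y),
      inherit.aes = FALSE, shape = 3, size = 3, stroke = 1.2
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "pixel-density level (x)", y = "tone-frequency level (y)",
      colour = "category", shape = "category"
    ) +
    ggplot2::theme_minimal()
  if (is.null(boundary)) boundary <- optimal_boundary(object)
  if (inherits(boundary, "linear_boundary")) {
    s <- sin(boundary$angle)
    if (abs(s) > 1e-8) {
      ig <- as_intercept_gradient(boundary)
      p <- p + ggplot2::geom_abline(intercept = ig$intercept,
                                    slope = ig$gradient, linetype = 2)
    } else {
      p <- p + ggplot2::geom_vline(
        xintercept = boundary$offset / cos(boundary$angle), linetype = 2
      )
    }
  }
  p
}

#' Plot the group-by-phase accuracy trajectory of a simulated experiment
#'
#' @param object An `experiment_dataset` from [simulate_experiment()].
#' @param ... Unused.
#' @return A ggplot object showing mean proportion correct (with standard
#'   errors) per group across the seven phases.
#' @export
autoplot.experiment_dataset <- function(object, ...) {
  acc <- summarize_accuracy(object)
  means <- dplyr::summarise(
    dplyr::group_by(acc, .data$group, .data$phase),
    mean = mean(.data$proportion_correct),
    se = sd(.data$proportion_correct) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(means, ggplot2::aes(x = .data$phase, y = .data$mean,
                                      colour = .data$group,
                                      group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = NULL, y = "proportion correct", colour = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot strategy-classification proportions across the tests
#'
#' @param table A [classification_table()].
#' @param family Family whose prevalence to plot (default `"glc"`), or
#'   `NULL` to facet all families.
#' @return A ggplot object.
#' @export
plot_strategy_proportions <- function(table, family = "glc") {
  stopifnot(is.data.frame(table))
  d <- if (is.null(family)) table else dplyr::filter(table, .data$family == !!family)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$phase, y = .data$proportion,
                                       colour = .data$group,
                                       group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion of participants",
                  colour = "group") +
    ggplot2::theme_minimal()
  if (is.null(family)) p + ggplot2::facet_wrap(~family) else p
}
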