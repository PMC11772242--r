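#' @importFrom ggplot2 ggplot aes geom_step geom_col geom_point geom_line
#'   labs facet_wrap theme_minimal autoplot scale_y_continuous
NULL

#' Plot supply cost curves
#'
#' Cumulative import share against ascending landed cost, one panel per
#' commodity (and one line per extra grouping column when present).
#'
#' @param curve A [supply_cost_curve()] result.
#' @return A ggplot object.
#' @export
plot_supply_curve <- function(curve) {
  p <- ggplot(curve, aes(x = .data$total, y = .data$cum_share)) +
    geom_step() +
    labs(x = "Landed cost (USD/t)", y = "Cumulative import share") +
    theme_minimal()
  if ("commodity" %in% names(curve)) {
    p <- p + facet_wrap(~commodity, scales = "free_x")
  }
  p
}

#' @export
autoplot.glcm_supply_curve <- function(object, ...) plot_supply_curve(object)

#' Plot the nine-component cost breakdown
#'
#' Stacked shares of the weighted average landed cost per group.
#'
#' @param shares A [breakdown_shares()] result.
#' @param x Name of the column used on the x axis (default "commodity").
#' @return A ggplot object.
#' @export
plot_breakdown <- function(shares, x = "commodity") {
  ggplot(shares, aes(x = .data[[x]], y = .data$share,
                     fill = factor(.data$component, levels = GLCM_COMPONENTS))) +
    geom_col() +
    labs(x = NULL, y = "Share of landed cost", fill = "Component") +
    theme_minimal()
}

#' Plot the ATC distance regression
#'
#' Country-pair average transport costs per tonne-km against distance on
#' log-log axes with the fitted benchmark line per mode.
#'
#' @param object A `glcm_atc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glcm_atc_fit <- function(object, ...) {
  pred <- object$pairs |>
    left_join(object$coefficients, by = "mode") |>
    mutate(fit = exp(.data$beta0 + .data$beta1 * log(.data$d)))
  ggplot(object$pairs, aes(x = .data$d, y = .data$atc)) +
    geom_point(alpha = 0.5) +
    geom_line(data = pred, aes(y = .data$fit), colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    facet_wrap(~mode, scales = "free") +
    labs(x = "Distance (km)", y = "ATC (USD/t/km)") +
    theme_minimal()
}

#' Plot cluster strategy profiles
#'
#' Mean savings-share profile of each strategy cluster.
#'
#' @param object A `glcm_clusters` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glcm_clusters <- function(object, ...) {
  centers <- attr(object, "centers") |>
    tidyr::pivot_longer(-"cluster", names_to = "component",
                        values_to = "share") |>
    mutate(component = sub("^share_", "", .data$component))
  ggplot(centers, aes(x = factor(.data$cluster), y = .data$share,
                      fill = .data$component)) +
    geom_col(position = "dodge") +
    labs(x = "Cluster", y = "Mean share of cost reduction",
         fill = "Component") +
    theme_minimal()
}
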