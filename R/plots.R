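#' Plot progress curves
#'
#' Concentration versus time, one colour per series, faceted by species.
#'
#' @param curves Progress-curve tibble.
#' @return A ggplot object.
#' @export
plot_progress <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time_s, y = .data$conc_uM,
                               colour = .data$series_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "concentration (uM)",
                  colour = "series") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a threshold curve
#'
#' @param object A [threshold_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_curve
#' @export
autoplot.threshold_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$activity_drop_pct,
                               y = .data$flux_drop_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(
      x = sprintf("%% decrease in %s activity (via %s)",
                  attr(object, "complex"), attr(object, "param")),
      y = "% decrease in steady-state flux",
      title = sprintf("area under retained-flux curve: %.2f",
                      attr(object, "area"))) +
    ggplot2::theme_minimal()
}

#' Plot a flux-control-coefficient table
#'
#' @param object An [fcc_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fcc_table
#' @export
autoplot.fcc_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[, setdiff(names(object), "sum")],
    -"param", names_to = "complex", values_to = "fcc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$param, y = .data$fcc,
                                     fill = .data$complex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "perturbed parameter", y = "flux control coefficient",
                  fill = "complex") +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison result
#'
#' Observed curve (if attached) against the three fitted trajectories.
#'
#' @param object A [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  tr <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    d <- object$trajectory[[i]]
    y <- if ("conc_uM" %in% names(d)) d$conc_uM else d$Dred
    tibble::tibble(model = object$model[i], time_s = d$time_s, conc_uM = y)
  }))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$conc_uM,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "reduced donor (uM)") +
    ggplot2::theme_minimal()
}
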