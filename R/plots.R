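#' Plot a screening result
#'
#' Mean displacement variance per landmark in rank order, with the
#' selected landmarks highlighted — the scree-style view used to judge
#' where the mobility cut-off falls.
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, ...) {
  dat <- tidy.screening_result(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$mean_variance,
                                    colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d1352b",
                                            `FALSE` = "grey55")) +
    ggplot2::labs(
      x = "landmark rank (by mean displacement variance)",
      y = expression(paste("mean displacement variance (", m^2, ")")),
      colour = "selected",
      title = "Landmark mobility screening"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Validation Pearson r per dimension, faceted by mean-filter width,
#' one colour per algorithm.
#'
#' @param object A `style_report`.
#' @param metric Which metric column to plot (default `"pearson_r"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot style_report
#' @export
autoplot.style_report <- function(object, metric = "pearson_r", ...) {
  dat <- object$results
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dimension,
                                    y = .data[[metric]],
                                    fill = .data$algorithm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~filter_window,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric,
                  title = "Validation performance by dimension") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Predicted-versus-actual scatter for a report
#'
#' @param report A `style_report`.
#' @param algorithm,filter_window Which model's validation predictions
#'   to show.
#' @return A ggplot object faceted by dimension.
#' @export
plot_predictions <- function(report, algorithm = "lr", filter_window = 3) {
  dat <- dplyr::filter(report$predictions,
                       .data$algorithm == !!algorithm,
                       .data$filter_window == !!filter_window)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~dimension, scales = "free") +
    ggplot2::labs(x = "actual GDMS score", y = "predicted score",
                  title = sprintf("Validation predictions (%s, W = %d)",
                                  algorithm, filter_window)) +
    ggplot2::theme_minimal()
}
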