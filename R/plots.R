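# ggplot2 display methods for the package's result objects.

#' @export
autoplot.trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "time", "voltage", "cai"),
    -"time", names_to = "signal", values_to = "value")
  df <- dplyr::filter(df, !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.trace <- function(x, ...) print(autoplot.trace(x, ...))

#' Heat map of a regression coefficient matrix
#'
#' Displays the forward matrix `B`, reverse matrix `B'`, or inverse matrix
#' as a signed heat map (white near zero), the standard way of reading
#' which parameters drive which outputs and vice versa.
#'
#' @param object A `sens_regression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sens_regression <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$estimate))
  ggplot2::ggplot(df, ggplot2::aes(.data$response, .data$predictor,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", limits = c(-lim, lim)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "coefficient",
                  title = paste0(object$direction, " regression matrix")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Conditioning histograms of a Bayesian constraint analysis
#'
#' One panel per conditioning stage and parameter; each histogram is
#' normalized to the surviving subset, so progressive narrowing is directly
#' visible.
#'
#' @param object A `bayes_analysis`.
#' @param parameters Optional subset of parameters to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bayes_analysis <- function(object, parameters = NULL, ...) {
  df <- object$histograms
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  df$stage <- factor(df$stage, levels = object$stage_labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid, .data$prob)) +
    ggplot2::geom_col(width = NA, fill = "grey30") +
    ggplot2::facet_grid(parameter ~ stage, scales = "free") +
    ggplot2::labs(x = "parameter value (log scale factor)",
                  y = "probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.elimination_history <- function(object, ...) {
  ggplot2::ggplot(object$steps, ggplot2::aes(.data$step,
                                             .data$score_after)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "outputs removed",
                  y = paste0(object$criterion,
                             " parameter R² after removal")) +
    ggplot2::theme_minimal()
}
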