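#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @method autoplot percept_timeline
autoplot.percept_timeline <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$onset,
                                    xmax = .data$onset + .data$duration,
                                    ymin = 0, ymax = 1,
                                    fill = .data$state)) +
    ggplot2::scale_fill_manual(values = c(LINE = "grey70",
                                          OBJECT = "steelblue")) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "percept") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Decision-value time course of a decoded run
#'
#' Distance to the separating hyperplane per volume, coloured by whether
#' the percept was decoded correctly, with the reported percept as
#' background shading.
#'
#' @param result A `decoding_result` or `online_result`.
#' @param run Which run to show.
#' @return A ggplot object.
#' @export
plot_decision_course <- function(result, run = unique(result$run)[1]) {
  tab <- dplyr::filter(tibble::as_tibble(result), .data$run == !!run,
                       !is.na(.data$truth))
  tab$correct <- tab$predicted == tab$truth
  ggplot2::ggplot(tab, ggplot2::aes(.data$volume, .data$decision)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct,
                                     colour = .data$truth)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "volume", y = "distance to hyperplane",
                  colour = "reported percept", shape = "correct") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot gamma_fit
autoplot.gamma_fit <- function(object, durations = NULL, bin_width = 3, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(durations))
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(d = durations),
      ggplot2::aes(.data$d, ggplot2::after_stat(density)),
      binwidth = bin_width, fill = "grey80", colour = "white")
  grid <- tibble::tibble(
    t = seq(0.01, max(4 * object$shape * object$scale, 60), length.out = 400))
  grid$density <- stats::dgamma(grid$t, shape = object$shape,
                                scale = object$scale)
  p + ggplot2::geom_line(data = grid,
                         ggplot2::aes(.data$t, .data$density),
                         colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "dwell time (s)", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot permutation_null
autoplot.permutation_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(accuracy = object$null),
                  ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$statistic,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "accuracy under block-permuted labels", y = "count") +
    ggplot2::theme_minimal()
}
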