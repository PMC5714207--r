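#' Plot the fragment-count / score trade-off across size windows
#'
#' One point per candidate size window: the number of selected fragments
#' (x, thousands) against the recovery score (y), coloured by whether the
#' window passes both thresholds. The optimal window minimises EV within
#' the passing set — visually, high on the score axis while far left on
#' the fragment axis.
#'
#' @param metrics Output of [range_metrics()].
#' @return A ggplot object.
#' @export
plot_size_tradeoff <- function(metrics) {
  ggplot2::ggplot(
    metrics,
    ggplot2::aes(
      x = .data$nf / 1000, y = .data$score,
      colour = .data$pass
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
      name = "passes thresholds"
    ) +
    ggplot2::labs(
      x = "selected fragments (thousands)",
      y = "Score",
      title = "Size-window trade-off"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the EV landscape over the size-window grid
#'
#' Tile plot of EV as a function of window lower limit and breadth, the
#' landscape on which robustness is evaluated: a protocol sitting in a
#' flat region of low EV tolerates gel-excision error.
#'
#' @param metrics Output of [range_metrics()] over a full grid.
#' @param optimum Optional list/row with `lower` and `breadth` to mark.
#' @return A ggplot object.
#' @export
plot_ev_landscape <- function(metrics, optimum = NULL) {
  p <- ggplot2::ggplot(
    metrics,
    ggplot2::aes(x = .data$lower, y = .data$breadth, fill = .data$ev)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "EV") +
    ggplot2::labs(
      x = "window lower limit (bp)",
      y = "window breadth (bp)",
      title = "Enrichment-value landscape"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(optimum)) {
    p <- p + ggplot2::annotate(
      "point",
      x = optimum$lower, y = optimum$breadth,
      shape = 8, size = 3, colour = "white"
    )
  }
  p
}

#' Plot ranked protocols from a search
#'
#' @param object An `rrbs_search` object.
#' @param ... Unused.
#' @return A ggplot of EV by rank, point size showing CRF and colour the
#'   robustness.
#' @method autoplot rrbs_search
#' @export
autoplot.rrbs_search <- function(object, ...) {
  p <- object$protocols
  ggplot2::ggplot(
    p,
    ggplot2::aes(
      x = .data$rank, y = .data$ev,
      size = .data$crf, colour = .data$robustness
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = "robustness") +
    ggplot2::scale_size_continuous(name = "CRF") +
    ggplot2::labs(
      x = "protocol rank", y = "EV (lower is better)",
      title = "Ranked candidate protocols"
    ) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity and specificity against coverage threshold
#'
#' @param curve Output of [metric_curve()].
#' @return A ggplot object.
#' @export
plot_metric_curve <- function(curve) {
  long <- tidyr::pivot_longer(
    curve[c("min_depth", "sensitivity", "specificity")],
    c("sensitivity", "specificity"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$min_depth, y = .data$value, colour = .data$metric
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "depth-of-coverage threshold",
      y = "percentage"
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
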