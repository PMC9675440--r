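#' Plot a population response heatmap
#'
#' Tile plot of per-bin z-scores (or rate changes), one row per neuron in
#' the stable display order, with epoch boundaries marked.
#'
#' @param object An `arc_heatmap` from [response_heatmap_table()].
#' @param value `"z"` or `"delta_hz"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot arc_heatmap
#' @export
autoplot.arc_heatmap <- function(object, value = c("z", "delta_hz"), ...) {
  value <- match.arg(value)
  protocol <- attr(object, "protocol")
  lim <- max(abs(object[[value]]), na.rm = TRUE)
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$t_mid_s / 60, y = .data$neuron_id,
    fill = .data[[value]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-lim, lim)) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  fill = if (value == "z") "z" else expression(Delta ~ "Hz")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(protocol)) {
    p <- p + ggplot2::geom_vline(xintercept = protocol$t_start_s / 60,
                                 linewidth = 0.2, colour = "grey40")
  }
  p
}

#' Plot per-concentration response proportions
#'
#' Stacked bar chart of excited / not responsive / inhibited percentages
#' per agent and concentration.
#'
#' @param object An `arc_popsummary` from [summarize_population()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot arc_popsummary
#' @export
autoplot.arc_popsummary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object,
    c("pct_excited", "pct_not_responsive", "pct_inhibited"),
    names_to = "class", values_to = "pct", names_prefix = "pct_"
  )
  long$class <- factor(long$class,
                       levels = c("excited", "not_responsive", "inhibited"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$concentration_uM), y = .data$pct, fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$agent), scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(excited = "#b2182b",
                                          not_responsive = "grey80",
                                          inhibited = "#2166ac")) +
    ggplot2::labs(x = "concentration (uM)", y = "% of neurons",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot coexpression percentages
#'
#' @param object An `arc_coexpression` from [coexpression_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot arc_coexpression
#' @export
autoplot.arc_coexpression <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$query, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = NULL, y = paste0("% of ", object$reference[1], "+ cells"),
      title = paste0("n = ", object$n_reference[1], " reference cells")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
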