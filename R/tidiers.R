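#' Tidy an event map
#'
#' One row per species-tree node with event totals and the reconstructed
#' ancestral proteome size.
#'
#' @param x an [aggregate_events()] result.
#' @param ... unused.
#' @return a tibble `node`, `gains`, `duplications`, `losses`, `copies`,
#'   `net_change`.
#' @export
tidy.event_map <- function(x, ...) {
  x$by_node |>
    mutate(net_change = net_change(.data$gains + .data$duplications,
                                   .data$losses))
}

#' @rdname tidy.event_map
#' @return `glance()` returns a one-row summary.
#' @export
glance.event_map <- function(x, ...) {
  tibble(
    n_families = length(x$gain_node),
    total_gains = sum(x$by_node$gains),
    total_duplications = sum(x$by_node$duplications),
    total_losses = sum(x$by_node$losses),
    mode = x$mode
  )
}

#' Tidy a principal coordinate ordination
#'
#' @param x a [gc_pcoa()] result.
#' @param ... unused.
#' @return tibble of point coordinates (`label`, `axis1`, ...).
#' @export
tidy.gc_pcoa <- function(x, ...) x$points

#' @rdname tidy.gc_pcoa
#' @export
glance.gc_pcoa <- function(x, ...) {
  tibble(
    n_points = nrow(x$points),
    n_positive_axes = ncol(x$coordinates_full),
    var_axis1 = x$prop_variance[1],
    var_axis2 = if (length(x$prop_variance) > 1) x$prop_variance[2] else NA_real_
  )
}

#' Plot a gene-content ordination with its minimum spanning tree
#'
#' @param object a [gc_pcoa()] result (with >= 2 axes).
#' @param label label the points (default `TRUE`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gc_pcoa <- function(object, label = TRUE, ...) {
  pts <- object$points
  if (!all(c("axis1", "axis2") %in% names(pts))) {
    abort("need >= 2 positive axes to plot")
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$axis1, .data$axis2))
  if (!is.null(object$mst)) {
    seg <- object$mst |>
      left_join(pts, by = c(from = "label")) |>
      left_join(pts, by = c(to = "label"), suffix = c("", "_to"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$axis1, y = .data$axis2,
                   xend = .data$axis1_to, yend = .data$axis2_to),
      linetype = "dashed", colour = "grey60"
    )
  }
  p <- p + ggplot2::geom_point(size = 2)
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$label),
                                vjust = -0.8, size = 3)
  }
  p + ggplot2::labs(
    x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_variance[1]),
    y = sprintf("PCo2 (%.1f%%)", 100 * object$prop_variance[2])
  ) + ggplot2::theme_minimal()
}

#' Plot per-node gain and loss totals of an event map
#'
#' Gains (positive) and losses (negative) per species-tree node, ordered by
#' node id; the classic expansion/contraction bar view.
#'
#' @param object an [aggregate_events()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.event_map <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("gains", "duplications", "losses"),
                        names_to = "event", values_to = "n") |>
    mutate(n = ifelse(.data$event == "losses", -.data$n, .data$n))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$node), .data$n,
                                   fill = .data$event)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "species-tree node", y = "events (losses negative)") +
    ggplot2::theme_minimal()
}
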