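#' Tidy and summarize differential-expression results
#'
#' `tidy()` returns the per-feature table as a plain tibble; `glance()`
#' returns a one-row summary with the feature count, significant/up/down
#' totals, the dispersion used and the thresholds applied.
#'
#' @param x A `cernet_de` object from [call_de()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cernet_de <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.cernet_de
#' @export
glance.cernet_de <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    phi = attr(x, "phi") %||% NA_real_,
    lfc_threshold = unname(thr["lfc"]),
    p_threshold = unname(thr["p"])
  )
}

#' Tidy and summarize a ceRNA network
#'
#' `tidy()` returns the edge table (joined with node attributes of both
#' endpoints); `glance()` returns one row with node/edge counts and the
#' per-class composition.
#'
#' @param x A `cerna_network` from [assemble_network()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cerna_network <- function(x, ...) {
  x$edges |>
    left_join(rename(x$nodes, source = "id", source_class = "class",
                     source_regulation = "regulation"), by = "source") |>
    left_join(rename(x$nodes, target = "id", target_class = "class",
                     target_regulation = "regulation"), by = "target")
}

#' @rdname tidy.cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  comp <- x$nodes |>
    count(.data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  bind_cols(tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges)), comp)
}

#' @rdname tidy.cernet_de
#' @export
glance.cerna_triads <- function(x, ...) {
  tibble(
    n_triads = nrow(x),
    n_lncrna = dplyr::n_distinct(x$lncrna_id),
    n_mirna = dplyr::n_distinct(x$mirna_id),
    n_mrna = dplyr::n_distinct(x$mrna_id),
    n_candidates = attr(x, "n_candidates") %||% NA_integer_
  )
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `cernet_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cernet_de <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(.data$p_value),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thr["lfc"],
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(thr["p"]),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cernet_de
#' @export
plot_volcano <- function(object, ...) autoplot.cernet_de(object, ...)

#' Plot a ceRNA network
#'
#' Fruchterman-Reingold layout with nodes coloured by class and shaped
#' by regulation direction.
#'
#' @param object A `cerna_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_network <- function(object, seed = 1L, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- igraph::graph_from_data_frame(
    object$edges[, c("source", "target")], directed = FALSE,
    vertices = object$nodes)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  lay <- tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(object$nodes, by = "id")
  seg <- object$edges |>
    left_join(rename(lay[, c("id", "x", "y")], source = "id"),
              by = "source") |>
    left_join(rename(lay[, c("id", "x", "y")], target = "id",
                     xend = "x", yend = "y"),
              by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "grey75", linewidth = 0.25) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$class,
                   shape = ifelse(is.na(.data$regulation), "none",
                                  .data$regulation)), size = 2) +
    ggplot2::labs(colour = "class", shape = "regulation") +
    ggplot2::theme_void()
}
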