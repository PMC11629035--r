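# ggplot2 visualizations of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the recommendation distribution against actual prescriptions
#'
#' Side-by-side bars of the share of patients recommended each drug class
#' versus the share actually prescribed it.
#'
#' @param object A `pwv_recommendations` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pwv_recommendations <- function(object, ...) {
  rec <- recommendation_distribution(object) |>
    dplyr::mutate(source = "recommended")
  plot_df <- rec
  if ("actual_drug" %in% names(object)) {
    act <- tibble::tibble(drug = drug_classes()) |>
      dplyr::left_join(dplyr::count(object, drug = .data$actual_drug),
                       by = "drug") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                    share = .data$n / nrow(object), source = "actual")
    plot_df <- dplyr::bind_rows(rec, act)
  }
  ggplot2::ggplot(plot_df,
                  ggplot2::aes(x = factor(.data$drug, drug_classes()),
                               y = .data$share, fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "drug class", y = "share of patients",
                  fill = NULL,
                  title = "Recommended vs. actual drug distribution") +
    ggplot2::theme_minimal()
}

#' Plot per-arm validation metrics
#'
#' @param object A `pwv_validation_report`.
#' @param ... Unused.
#' @return A ggplot object with one panel per metric.
#' @export
autoplot.pwv_validation_report <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("r2", "mse"), names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$drug, drug_classes()),
                                 y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "drug class", y = NULL,
                  title = paste(attr(object, "scheme"),
                                "validation of the per-arm models")) +
    ggplot2::theme_minimal()
}

#' Plot the top features of each arm model
#'
#' Lollipop chart of the consensus-top features per drug class, ordered by
#' consensus rank.
#'
#' @param object A `pwv_bundles` object.
#' @param k Features shown per arm (default 10).
#' @param ... Unused.
#' @return A ggplot object faceted by drug class.
#' @export
autoplot.pwv_bundles <- function(object, k = 10, ...) {
  tidy(object) |>
    dplyr::filter(.data$consensus_rank <= k) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$mdi_score,
      y = stats::reorder(paste(.data$drug, .data$feature, sep = ":"),
                         -.data$consensus_rank))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0,
                                       yend = paste(.data$drug,
                                                    .data$feature,
                                                    sep = ":"))) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::facet_wrap(~drug, scales = "free_y") +
    ggplot2::scale_y_discrete(
      labels = function(l) sub("^[^:]+:", "", l)) +
    ggplot2::labs(x = "normalized impurity importance", y = NULL,
                  title = "Top features per arm model") +
    ggplot2::theme_minimal()
}

#' Plot a surrogate decision tree
#'
#' Draws the tree as a node-link diagram down to `levels` levels: split
#' rules in internal nodes, majority drug in leaves. Leaf x-positions
#' follow left-to-right order; y is the node depth.
#'
#' @param object A `pwv_surrogate`.
#' @param levels Levels to draw (root = level 1); default 5.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pwv_surrogate <- function(object, levels = 5, ...) {
  nodes <- object$nodes
  pos <- new.env()
  leaf_x <- 0
  layout <- function(id, depth) {
    nd <- nodes[nodes$node_id == id, ]
    if (nd$is_leaf || depth >= levels) {
      leaf_x <<- leaf_x + 1
      assign(as.character(id), leaf_x, envir = pos)
      return(leaf_x)
    }
    x <- (layout(nd$left_id, depth + 1) +
            layout(nd$right_id, depth + 1)) / 2
    assign(as.character(id), x, envir = pos)
    x
  }
  layout(1L, 0L)
  shown <- nodes[!is.na(match(as.character(nodes$node_id), ls(pos))), ]
  shown$x <- purrr::map_dbl(as.character(shown$node_id),
                            ~ get(.x, envir = pos))
  shown$label <- ifelse(
    shown$is_leaf | shown$depth >= levels,
    paste0(shown$majority, "\nn=", shown$n),
    paste0(shown$split_feature, " <= ", signif(shown$threshold, 3)))
  edges <- shown |>
    dplyr::filter(!.data$is_leaf, .data$depth < levels) |>
    (\(df) dplyr::bind_rows(
      dplyr::transmute(df, x = .data$x, y = -.data$depth,
                       xend = purrr::map_dbl(as.character(.data$left_id),
                                             ~ get(.x, envir = pos)),
                       yend = -(.data$depth + 1)),
      dplyr::transmute(df, x = .data$x, y = -.data$depth,
                       xend = purrr::map_dbl(as.character(.data$right_id),
                                             ~ get(.x, envir = pos)),
                       yend = -(.data$depth + 1))
    ))()
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey60") +
    ggplot2::geom_label(data = shown,
                        ggplot2::aes(x = .data$x, y = -.data$depth,
                                     label = .data$label),
                        size = 2.6) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Surrogate recommendation tree")
}
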