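# segment coordinates of an hclust tree for ggplot rendering
dendro_segments <- function(tree) {
  n <- length(tree$order)
  leaf_x <- numeric(n)
  leaf_x[tree$order] <- seq_len(n)
  node_x <- node_y <- numeric(n - 1L)
  seg <- vector("list", n - 1L)
  coord <- function(code) {
    if (code < 0) c(leaf_x[-code], 0) else c(node_x[code], node_y[code])
  }
  for (s in seq_len(n - 1L)) {
    a <- coord(tree$merge[s, 1L]); b <- coord(tree$merge[s, 2L])
    h <- tree$height[s]
    node_x[s] <- mean(c(a[1L], b[1L])); node_y[s] <- h
    seg[[s]] <- tibble::tibble(
      x = c(a[1L], a[1L], b[1L]), xend = c(a[1L], b[1L], b[1L]),
      y = c(a[2L], h, h), yend = c(h, h, b[2L]))
  }
  dplyr::bind_rows(seg)
}

#' Plot a criterion series
#'
#' Criterion score against the number of clusters, with the selected
#' `k_hat` highlighted.
#'
#' @param object A `criterion_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot criterion_series
#' @export
autoplot.criterion_series <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$selected, ], colour = "red", size = 3) +
    ggplot2::labs(title = object$method,
                  x = "number of clusters k", y = "criterion score") +
    ggplot2::theme_minimal()
}

#' Plot all criterion series of an estimate
#'
#' @param object A `k_estimate`.
#' @param ... Unused.
#' @method autoplot k_estimate
#' @export
autoplot.k_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = df[df$selected, ], colour = "red", size = 2) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = "criterion score") +
    ggplot2::theme_minimal()
}

#' Plot a gDGC dendrogram with its critical cut height
#'
#' Dendrogram of the Mahalanobis tree with the critical height drawn as a
#' dotted line; leaves are labelled with their group letters (genes with
#' different letters differ significantly at the test's level).
#'
#' @param object A `gdgc_result`.
#' @param label_size Leaf label size (points).
#' @param ... Unused.
#' @method autoplot gdgc_result
#' @export
autoplot.gdgc_result <- function(object, label_size = 2, ...) {
  seg <- dendro_segments(object$tree)
  n <- length(object$tree$order)
  leaves <- tibble::tibble(
    x = seq_len(n),
    gene = (object$tree$labels %||% as.character(seq_len(n)))[object$tree$order],
    letter = unname(object$letters[object$tree$order]))
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_hline(yintercept = object$Q_critical, linetype = "dotted",
                        colour = "red") +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02 * object$Q_observed,
                                    label = .data$letter),
                       size = label_size, vjust = 1) +
    ggplot2::labs(y = "merge height (Mahalanobis)", x = NULL,
                  title = sprintf("gDGC cut: Q = %.3f, Q_crit = %.3f, %d group(s)",
                                  object$Q_observed, object$Q_critical,
                                  object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
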