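# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group summary
#'
#' One row per (group, cell class) with the cell count and the group median
#' of per-cell median IGFBP7 intensity.
#'
#' @param x An `islet_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy islet_summary
#' @export
tidy.islet_summary <- function(x, ...) {
  x$summary
}

#' One-line summary of a group comparison
#'
#' @param x An `islet_summary`.
#' @param ... Unused.
#' @return A one-row tibble with totals, the per-class T2D/ND median ratios
#'   and Mann-Whitney p-values.
#' @method glance islet_summary
#' @export
glance.islet_summary <- function(x, ...) {
  ratio_of <- function(cls) {
    s <- x$summary
    nd <- s$median_igfbp7[s$cell_class == cls & s$group == "ND"]
    t2d <- s$median_igfbp7[s$cell_class == cls & s$group == "T2D"]
    if (length(nd) == 1 && length(t2d) == 1 && nd > 0) t2d / nd else NA_real_
  }
  p_of <- function(cls) {
    p <- x$tests$p_value[x$tests$cell_class == cls]
    if (length(p) == 1) p else NA_real_
  }
  tibble::tibble(
    n_cells = x$n_total,
    n_unclassified = x$n_unclassified,
    alpha_t2d_nd_ratio = ratio_of("alpha"),
    beta_t2d_nd_ratio = ratio_of("beta"),
    alpha_p_value = p_of("alpha"),
    beta_p_value = p_of("beta")
  )
}

#' Tidy a pipeline run into its pooled cell table
#'
#' @param x An `islet_run`.
#' @param ... Unused.
#' @return The pooled classified cell tibble.
#' @method tidy islet_run
#' @export
tidy.islet_run <- function(x, ...) x$cells

#' One-line summary of a pipeline run
#'
#' @param x An `islet_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance islet_run
#' @export
glance.islet_run <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_fields = length(x$fields)),
                   glance(x$summary))
}

#' Plot per-cell IGFBP7 intensity by group and class
#'
#' Boxplots of per-cell median IGFBP7 intensity for alpha- and beta-cells in
#' each donor group.
#'
#' @param cells A classified cell table (e.g. `run$cells`).
#' @param value Column to plot (default `median_igfbp7`).
#' @return A ggplot object.
#' @export
plot_igfbp7 <- function(cells, value = "median_igfbp7") {
  d <- dplyr::filter(cells, .data$cell_class %in% c("alpha", "beta"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[value]],
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~cell_class) +
    ggplot2::labs(x = NULL, y = "per-cell median IGFBP7 intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname plot_igfbp7
#' @param object An `islet_run`.
#' @param ... Unused.
#' @method autoplot islet_run
#' @export
autoplot.islet_run <- function(object, ...) {
  plot_igfbp7(object$cells)
}

#' Plot a segmented field's cell map coloured by class
#'
#' @param field A `field_result` (one element of `run$fields`).
#' @return A ggplot object.
#' @export
plot_cell_map <- function(field) {
  lab <- field$cells
  pix <- which(lab > 0)
  d <- tibble::tibble(
    row = ((pix - 1) %% nrow(lab)),
    col = ((pix - 1) %/% nrow(lab)),
    cell_id = lab[pix]
  )
  cls <- stats::setNames(field$table$cell_class, field$table$cell_id)
  d$cell_class <- unname(cls[as.character(d$cell_id)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$cell_class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_void()
}

#' @rdname plot_cell_map
#' @param object A `field_result`.
#' @param ... Unused.
#' @method autoplot field_result
#' @export
autoplot.field_result <- function(object, ...) {
  plot_cell_map(object)
}
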