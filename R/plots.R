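matrix_plot_df <- function(m) {
  grid <- m$grid
  v <- m$values
  idx <- which(!is.na(v), arr.ind = TRUE)
  tibble(
    x = (idx[, 2] - 0.5) * grid$bin_size,
    y = (idx[, 1] - 0.5) * grid$bin_size,
    value = v[idx]
  )
}

#' @describeIn autoplot_astadr Heatmap of a contact matrix (log10 scale).
#' @export
autoplot.contact_matrix <- function(object, ...) {
  df <- matrix_plot_df(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = log10(1 + .data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "log10(1 + value)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = object$grid$chrom, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot_astadr Diverging heatmap of a subtraction matrix
#'   (red = A2 enrichment, blue = A1 enrichment).
#' @export
autoplot.subtraction_matrix <- function(object, ...) {
  df <- matrix_plot_df(object)
  lim <- max(abs(df$value), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim), name = "A2 - A1") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = object$grid$chrom, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot methods for astadr result objects
#'
#' `autoplot()` methods render each result type with ggplot2: contact and
#' subtraction matrices as heatmaps, viewpoint traces as per-allele line
#' plots, and ASTAD calls as a Z-score profile along the chromosome with the
#' calling threshold.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_astadr
NULL

#' @describeIn autoplot_astadr Per-allele viewpoint interaction traces.
#' @export
autoplot.viewpoint_trace <- function(object, ...) {
  vp <- attr(object, "viewpoint")
  df <- object[!is.na(object$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$start, .data$value,
                                   color = .data$allele)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = vp$start, xmax = vp$end,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::labs(x = vp$chrom, y = "contact frequency",
                  title = "viewpoint trace") +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot_astadr Domain Z-scores with the ASTAD threshold.
#' @export
autoplot.astad_calls <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 2
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$z, color = .data$is_astad)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$z), linewidth = 2) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = unique(object$chrom)[1], y = "Z-score",
                  color = "ASTAD") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
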