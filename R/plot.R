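#' Plot a segmentation result
#'
#' Shows the 4-level map as a grayscale raster (level 3 = bright skin) with
#' the traced lesion border overlaid in red, row 1 at the top.
#'
#' @param object A `lesion_segmentation` from [segment_lesion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.lesion_segmentation <- function(object, ...) {
  lev <- object$levels
  df <- tibble::tibble(
    row = rep(seq_len(nrow(lev)), times = ncol(lev)),
    col = rep(seq_len(ncol(lev)), each = nrow(lev)),
    level = as.vector(lev)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$level)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 3), name = "level") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, title = "4-level segmentation map")
  if (nrow(object$contour)) {
    cdf <- tidy(object)
    p <- p + ggplot2::geom_path(
      data = rbind(cdf, cdf[1L, ]),
      ggplot2::aes(x = .data$col, y = .data$row),
      color = "red", linewidth = 0.4, inherit.aes = FALSE
    )
  }
  p
}

#' Plot an RGB image
#'
#' @param object An [rgb_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.rgb_image <- function(object, ...) {
  a <- unclass(object)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(a)), times = ncol(a)),
    col = rep(seq_len(ncol(a)), each = nrow(a)),
    fill = grDevices::rgb(as.vector(a[, , 1L]), as.vector(a[, , 2L]),
                          as.vector(a[, , 3L]), maxColorValue = 255)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot per-image evaluation accuracies
#'
#' @param object A `lesion_eval` from [evaluate_dataset()].
#' @param ... Unused.
#' @return A ggplot object: per-image accuracy with the dataset mean as a
#'   dashed line.
#' @exportS3Method
autoplot.lesion_eval <- function(object, ...) {
  df <- object$per_image
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "pixel accuracy")
}

#' Plot region color histograms
#'
#' @param histograms Tibble from [region_color_histograms()].
#' @return A ggplot object, faceted by region, one line per channel.
#' @export
plot_region_histograms <- function(histograms) {
  ggplot2::ggplot(histograms,
                  ggplot2::aes(x = .data$intensity, y = .data$count,
                               color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_color_manual(values = c(R = "red3", G = "green4",
                                           B = "blue3")) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "intensity (0-255)", y = "pixel count")
}
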