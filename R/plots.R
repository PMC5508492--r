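# ggplot2 rendering of the tabular result types.

#' Plot a threshold sweep
#'
#' Mean TPR and TNR against the classification threshold, with the
#' optimal-threshold rule's TPR floor drawn as a reference line.
#'
#' @param object A [threshold_sweep()].
#' @param tpr_floor Reference TPR floor (percent).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, tpr_floor = 90, ...) {
  df <- rbind(
    data.frame(threshold = object$threshold, value = object$mean_tpr,
               metric = "mean TPR"),
    data.frame(threshold = object$threshold, value = object$mean_tnr,
               metric = "mean TNR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = tpr_floor, linetype = "dashed") +
    ggplot2::labs(x = "threshold", y = "percent", colour = NULL) +
    ggplot2::ylim(0, 100)
}

#' Render a grayplot
#'
#' Voxels-by-time heatmap with the gray/white tissue boundary annotated;
#' global artefacts appear as vertical bands crossing both tissues.
#'
#' @param object A [grayplot()] matrix.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot grayplot_matrix
#' @export
autoplot.grayplot_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- data.frame(
    time = rep(seq_len(ncol(m)), each = nrow(m)),
    voxel = rep(seq_len(nrow(m)), times = ncol(m)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$voxel,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white", limits = c(-3, 3),
                                  oob = scales_squish) +
    ggplot2::geom_hline(yintercept = attr(object, "n_gray") + 0.5,
                        colour = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "volume", y = "voxel (gray above line, white below)",
                  fill = "z")
}

# minimal squish (avoids a scales dependency)
scales_squish <- function(x, range = c(-3, 3)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
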