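#' Plot an axial slice of a volume, optionally with cluster overlay
#'
#' Quick-look ggplot of one z-slice of a scalar volume; cluster voxels from a
#' labelled cluster volume (see [extract_clusters()]) are overdrawn in red,
#' the usual display convention for abnormally-low-FA clusters.
#'
#' @param vol An `sq_volume`.
#' @param z Slice index (default: middle slice).
#' @param clusters Optional cluster tibble with a `label_volume` attribute.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, z = NULL, clusters = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_bad_arg("plot_slice() needs the ggplot2 package")
  }
  dims <- dim(vol$data)
  z <- z %||% ceiling(dims[3] / 2)
  sl <- vol$data[, , z]
  df <- data.frame(x = rep(seq_len(dims[1]), dims[2]),
                   y = rep(seq_len(dims[2]), each = dims[1]),
                   value = as.vector(sl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                        fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z), fill = "value") +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    lab <- attr(clusters, "label_volume")
    if (!is.null(lab)) {
      ls <- lab$data[, , z]
      sel <- which(ls > 0)
      if (length(sel)) {
        cl <- data.frame(x = ((sel - 1) %% dims[1]) + 1,
                         y = ((sel - 1) %/% dims[1]) + 1)
        p <- p + ggplot2::geom_tile(data = cl,
                                    ggplot2::aes(x = x, y = y),
                                    fill = "red", inherit.aes = FALSE)
      }
    }
  }
  p
}

utils::globalVariables(c("x", "y", "value"))
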