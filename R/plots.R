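#' Plot one axial slice of a map
#'
#' @param map A [scalar_map()] or `stat_map`.
#' @param slice 1-based z index (defaults to the middle slice).
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, slice = NULL) {
  if (inherits(map, "stat_map")) {
    arr <- map$t
    arr[!map$mask] <- NA
    lab <- "t"
  } else {
    stopifnot(inherits(map, "scalar_map"))
    arr <- map$data
    lab <- map$label
  }
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", slice)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr,
                                             y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.svm_loocv <- function(object, ...) {
  autoplot(object$roc, ...)
}

#' @export
autoplot.group_inference <- function(object, slice = NULL, ...) {
  plot_map_slice(object$stat, slice = slice)
}
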