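# broom-style accessors and ggplot2 autoplot methods.

#' Tidy a sweep result
#'
#' Returns the feature table as a plain tibble.
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sweep_result <- function(x, ...) {
  tibble::as_tibble(unclass2(x))
}

#' One-line summary of a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble with scenario, orientation, number of sweep
#'   values and the Vpp range.
#' @export
glance.sweep_result <- function(x, ...) {
  df <- tibble::as_tibble(unclass2(x))
  tibble::tibble(
    scenario = attr(x, "scenario"),
    orientation = attr(x, "orientation"),
    n_values = length(unique(df$parameter)),
    n_traces = nrow(df),
    v_pp_min_mV = min(df$v_pp_mV),
    v_pp_max_mV = max(df$v_pp_mV))
}

unclass2 <- function(x) {
  class(x) <- setdiff(class(x), "sweep_result")
  attr(x, "traces") <- NULL
  x
}

#' Plot relative Vpp over a sweep
#'
#' Relative peak-to-peak voltage of the unipolar electrograms against the
#' sweep parameter, one line per electrode.
#'
#' @param object A `sweep_result`.
#' @param kind Trace kind to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, kind = "unipolar", ...) {
  df <- dplyr::filter(tibble::as_tibble(unclass2(object)),
                      .data$kind == !!kind)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$rel_vpp_pct,
                                   colour = .data$electrode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "scenario"),
                  y = "relative Vpp (%)",
                  title = paste0(attr(object, "scenario"), " (",
                                 attr(object, "orientation"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot an electrogram trace
#'
#' @param object An `egm_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.egm_trace <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ms)", y = "potential (mV)",
                  title = paste(object$kind, df$electrode[1],
                                if (object$filtered) "(filtered)")) +
    ggplot2::theme_minimal()
}

#' Plot a z-slice of a labeled grid
#'
#' Material labels of one horizontal voxel layer, for quick geometry
#' inspection.
#'
#' @param object A `labeled_grid`.
#' @param k z-layer index (default: the top tissue layer).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.labeled_grid <- function(object, k = NULL, ...) {
  if (is.null(k)) k <- object$k_tissue[length(object$k_tissue)]
  sl <- object$label[, , k]
  df <- expand.grid(x = axis_centers(object$dims[1], object$h),
                    y = axis_centers(object$dims[2], object$h))
  df$label <- factor(as.vector(sl), levels = egm_labels(),
                     labels = names(egm_labels()))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("z-layer %d", k)) +
    ggplot2::theme_minimal()
}
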