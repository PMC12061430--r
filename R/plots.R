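#' @title Plotting
#' @description `autoplot()` methods for the package's result types:
#'   trajectory rasters (node activity over time, the standard yellow/blue
#'   ON/OFF view), per-window phenotype-fraction bars, and dose-response
#'   panels from grid tables.
#' @name plots
NULL

#' Plot a trajectory as a node-by-time raster
#'
#' @param object A `bn_trajectory`.
#' @param ... Unused.
#' @return A ggplot object (tiles: node x step, filled by ON/OFF).
#' @export
autoplot.bn_trajectory <- function(object, ...) {
  df <- as_tibble.bn_trajectory(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step,
                                   y = factor(.data$node,
                                              levels = rev(levels(.data$node))),
                                   fill = factor(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c("0" = "#27408B", "1" = "#FFD700"),
                               name = NULL, labels = c("OFF", "ON")) +
    ggplot2::labs(x = "update step", y = NULL,
                  title = paste("Trajectory:", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot per-window phenotype fractions
#'
#' @param object A `bn_ensemble`.
#' @param module Optional module filter.
#' @param ... Unused.
#' @return A ggplot object (stacked bars per window, facetted by module).
#' @export
autoplot.bn_ensemble <- function(object, module = NULL, ...) {
  df <- object$phenotype_fractions
  if (is.null(df)) stop("ensemble was run without signatures", call. = FALSE)
  if (!is.null(module)) df <- df[df$module %in% module, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$window),
                                   y = .data$fraction,
                                   fill = .data$phenotype)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = "window", y = "fraction of live steps",
                  title = paste("Ensemble:", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response series from a grid table
#'
#' @param grid_tbl The tibble returned by [run_grid()] (single axis).
#' @param module Module to display.
#' @return A ggplot object (phenotype fraction vs. swept level).
#' @export
plot_dose_response <- function(grid_tbl, module = "EMT") {
  df <- grid_tbl[grid_tbl$module == module, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level1, y = .data$fraction,
                                   colour = .data$phenotype)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$background),
                        ggplot2::vars(.data$window)) +
    ggplot2::labs(x = unique(df$axis1), y = "fraction of live steps") +
    ggplot2::theme_minimal()
}
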