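#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: kymographs
#' (position vs time raster), movement summaries (per-class bar charts with
#' SEM over animals), co-localization summaries (class distribution within
#' the co-localized and solo pools), dystrophy events (minimum distance and
#' baseline-normalized loading curves) and surface trends (per-animal
#' scatter with the OLS line).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name axoshed-plots
NULL

#' @rdname axoshed-plots
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- expand.grid(t_s = (seq_len(nrow(object$K)) - 1) * object$dt_s,
                    s_um = object$s_um)
  df$intensity <- as.numeric(object$K)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_um, y = .data$t_s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position (um, +s anterograde)", y = "time (s)",
                  fill = "I") +
    ggplot2::theme_minimal()
}

#' @rdname axoshed-plots
#' @export
autoplot.movement_summary <- function(object, ...) {
  g <- object$group
  ggplot2::ggplot(g, ggplot2::aes(x = .data$movement_class,
                                  y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                                        ymax = .data$mean_pct + .data$sem_pct),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "% of traces (mean +/- SEM over animals)") +
    ggplot2::theme_classic()
}

#' @rdname axoshed-plots
#' @export
autoplot.coloc_summary <- function(object, ...) {
  ggplot2::ggplot(object$pools,
                  ggplot2::aes(x = .data$pool, y = .data$pct,
                               fill = .data$movement_class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of pool", fill = "class") +
    ggplot2::theme_classic()
}

#' @rdname axoshed-plots
#' @export
autoplot.dystrophy_event <- function(object, ...) {
  tp <- tidyr::pivot_longer(object$timepoints,
                            c("i_protrusion", "i_axon_beneath"),
                            names_to = "roi", values_to = "intensity")
  ggplot2::ggplot(tp, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity,
                                    colour = .data$roi)) +
    ggplot2::geom_line(data = object$timepoints,
                       ggplot2::aes(y = .data$min_distance_um),
                       linetype = "dashed") +
    ggplot2::labs(x = "time (s)",
                  y = "normalized intensity / min distance (um, dashed)",
                  colour = NULL,
                  title = sprintf("event kind: %s", object$kind)) +
    ggplot2::theme_classic()
}

#' @rdname axoshed-plots
#' @export
autoplot.surface_trend <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "% of signal outside axons",
                  y = "% of signal on nerve surface",
                  title = sprintf("R^2 = %.3f (n = %d animals)",
                                  object$r_squared, object$n)) +
    ggplot2::theme_classic()
}
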