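#' Heatmap of a compression x availability sweep
#'
#' Tiles the maximum-ATP objective over the sweep grid on log-spaced axes;
#' infeasible cells are left blank (grey).
#'
#' @param object a `sweep_grid` from [sweep_atp()].
#' @param fill which column to map to fill: `"objective"`,
#'   `"glucose_uptake"` or `"atp_per_glucose"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_grid <- function(object, fill = "objective", ...) {
  stopifnot(fill %in% c("objective", "glucose_uptake", "atp_per_glucose"))
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$r), y = factor(.data$k),
                                       fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "availability ratio r", y = "compression k",
                  fill = fill) +
    ggplot2::theme_minimal()
}

#' Bar chart of an energy budget
#'
#' Per-class ATP/GTP flux, ordered by decreasing share, truncated at the
#' classes jointly covering `coverage` of the demand.
#'
#' @param object an `energy_budget`.
#' @param coverage cumulative-share cutoff (default 0.9).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.energy_budget <- function(object, coverage = 0.9, ...) {
  shown <- object[seq_len(min(nrow(object),
                              sum(object$cum_fraction <= coverage) + 1)), ]
  ggplot2::ggplot(shown,
                  ggplot2::aes(x = stats::reorder(.data$class_level1,
                                                  .data$flux),
                               y = .data$flux)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ATP flux (capacity units)") +
    ggplot2::theme_minimal()
}

#' Scatter of group sums before vs after imputation
#'
#' @param comparison output of [compare_prepost()].
#' @return a ggplot with the identity line.
#' @export
plot_imputation_compare <- function(comparison) {
  ggplot2::ggplot(comparison$sums,
                  ggplot2::aes(x = .data$before, y = .data$after)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "group sum before imputation",
                  y = "group sum after imputation") +
    ggplot2::theme_minimal()
}
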