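#' Actogram raster of an activity record
#'
#' Single-plotted raster: one row per day, clock time on the x axis, tile
#' fill by counts.
#'
#' @param rec An [activity_record()].
#' @return A ggplot object.
#' @export
plot_actogram <- function(rec) {
  long <- as_tibble(rec)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$clock_time_minutes / 60, y = .data$day, fill = .data$counts
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(x = "clock time (h)", y = "day", fill = "counts") +
    ggplot2::theme_minimal()
}

#' Mean daily activity profile plot
#'
#' @param profile Tibble from [activity_profile()].
#' @return A ggplot object.
#' @export
plot_activity_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$hour, .data$mean_counts)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "hour", y = "mean counts / h") +
    ggplot2::theme_minimal()
}

#' Periodogram plot
#'
#' @param object A `periodogram_result`.
#' @param ... Unused.
#' @return A ggplot object showing Qp against trial period with the
#'   chi-square significance line.
#' @export
autoplot.periodogram_result <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(.data$period_h, .data$Qp)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$sig_threshold),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "trial period (h)", y = "Qp") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression contrast
#'
#' Welch difference against `-log10(p)` with the combined cutoff drawn as
#' threshold lines: the horizontal line at the p cutoff, vertical lines at
#' the differences corresponding to `|z| = z_cut`.
#'
#' @param object A `dep_table` from [welch_contrast()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dep_table <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  z_cut <- attr(object, "z_cut") %||% 1
  m <- mean(object$d_log2)
  s <- sd(object$d_log2)
  df <- as_tibble(object)
  df$call <- ifelse(!object$significant, "ns",
                    ifelse(object$z > 0, "up", "down"))
  ggplot2::ggplot(df, ggplot2::aes(.data$d_log2, -log10(.data$p),
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = m + c(-1, 1) * z_cut * s,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(ns = "grey70", up = "firebrick", down = "steelblue")) +
    ggplot2::labs(x = "Welch difference (log2)", y = "-log10 p",
                  title = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}

#' Module–trait correlation heatmap
#'
#' @param object A `module_trait_corr`.
#' @param ... Unused.
#' @return A ggplot heatmap with the correlation coefficient and p-value
#'   printed in each cell.
#' @export
autoplot.module_trait_corr <- function(object, ...) {
  long <- tidy(object)
  long$label <- sprintf("%.2f\n(%.1g)", long$r, long$p)
  ggplot2::ggplot(long, ggplot2::aes(.data$trait, .data$module,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
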