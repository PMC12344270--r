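#' Plot a growth series with its spline smooth and thresholds
#'
#' @param series tibble with `doy` and `value`.
#' @param smooth optional `growth_spline`; fitted if `NULL`.
#' @param thresholds optional threshold tibble from [extract_thresholds()];
#'   drawn as vertical lines at t20/t80 when given.
#' @return A ggplot object.
#' @export
plot_growth_series <- function(series, smooth = NULL, thresholds = NULL) {
  smooth <- smooth %||% fit_growth_spline(series)
  fit <- tidy(smooth)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$doy, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fit,
                       ggplot2::aes(x = .data$doy, y = .data$fitted),
                       colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::labs(x = "Day of year", y = "Cumulative growth")
  if (!is.null(thresholds)) {
    v <- c(thresholds$t20_doy, thresholds$t80_doy)
    p <- p + ggplot2::geom_vline(xintercept = v[is.finite(v)],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Display a scan frame or mask as a ggplot raster
#'
#' @param frame a [scan_frame()] or [root_mask()].
#' @return A ggplot object in image orientation (row 1 on top).
#' @export
plot_frame <- function(frame) {
  m <- unclass_mat(frame)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot per-period net root-length changes by treatment
#'
#' @param periods the `periods` tibble from [cohort_period_changes()].
#' @return A ggplot bar chart of mean period deltas per drought level.
#' @export
plot_period_changes <- function(periods) {
  dat <- dplyr::summarise(
    dplyr::group_by(periods, .data$period, .data$drought),
    mean_delta = mean(.data$delta, na.rm = TRUE),
    se = sd(.data$delta, na.rm = TRUE) /
      sqrt(sum(is.finite(.data$delta))),
    .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$period, y = .data$mean_delta,
                                    fill = .data$drought)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_delta - .data$se,
                   ymax = .data$mean_delta + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "Period", y = "Net root length change (mm cm⁻²)",
                  fill = "Drought")
}
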