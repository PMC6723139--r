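#' Plot a scenario grid as trend lines
#'
#' Draws the grid's primary statistic against the column axis, one line per
#' row-axis value: for a correlation grid, the genetic correlation against
#' heritability with one line per CV; for a GCV grid, the GCV against CV with
#' one line per strength.
#'
#' @param object A `grid_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grid_table
#' @export
autoplot.grid_table <- function(object, ...) {
  stat <- attr(object, "statistic")
  row_name <- attr(object, "row_axis")$name
  col_name <- attr(object, "col_axis")$name
  df <- tidy(object)
  df$.row <- factor(df[[row_name]])
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[col_name]], y = .data[[stat]],
    colour = .data$.row, group = .data$.row
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = col_name,
      y = if (stat == "mean_rho") "mean genetic correlation" else "mean GCV",
      colour = row_name
    ) +
    ggplot2::theme_minimal()
}

#' Plot a quantile-bin summary
#'
#' Mean, standard deviation and CV of the sorted groups side by side, the
#' visual check for a scale effect in real records: under a constant-CV
#' effect the SD tracks the mean and the CV panel is flat.
#'
#' @param object A `bin_summary` from [quantile_bin_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bin_summary
#' @export
autoplot.bin_summary <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("mean", "sd", "cv"),
                        names_to = "statistic", values_to = "value")
  df$statistic <- factor(df$statistic, levels = c("mean", "sd", "cv"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "sorted group", y = NULL) +
    ggplot2::theme_minimal()
}
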