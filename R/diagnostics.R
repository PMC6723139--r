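#' Quantile-bin summary of trait records
#'
#' Descriptive check for a scale effect in real data: records are sorted and
#' split into contiguous groups of (near-)equal size, and the mean, standard
#' deviation and coefficient of variation are computed within each group. If
#' a trait has a constant-CV scale effect, the per-bin SD rises with the bin
#' mean while the per-bin CV stays flat; a falling CV indicates an attenuated
#' (strength < 1) effect.
#'
#' Ties are kept in input order (stable sort) and split by position. When the
#' record count is not divisible by `n_bins`, the remainder goes to the
#' lowest-index bins, so bin sizes differ by at most one.
#'
#' @param data A data frame containing the records, or a bare numeric vector.
#' @param col Column holding the trait values when `data` is a data frame:
#'   a name or a 1-based index. Ignored for vector input.
#' @param n_bins Number of sorted groups (>= 2). Default 5.
#'
#' @return A tibble with one row per bin: `bin_index`, `n`, `mean`, `sd`
#'   (n - 1 denominator) and `cv = sd / mean`, ordered by non-decreasing
#'   mean. Classed `bin_summary` so it can be fed to [autoplot()].
#'
#' @examples
#' quantile_bin_summary(data.frame(weight = c(1:10)), col = "weight")
#' quantile_bin_summary(rnorm(100, 100, 10), n_bins = 4)
#' @export
quantile_bin_summary <- function(data, col = 1L, n_bins = 5L) {
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  if (is.data.frame(data)) {
    x <- pull_column(data, col)
  } else {
    x <- data
  }
  if (!is.numeric(x)) stop_domain("trait records must be numeric.")
  if (anyNA(x) || any(!is.finite(x))) {
    stop_domain("trait records contain missing or non-finite values.")
  }
  if (length(x) < 2L * n_bins) {
    stop_domain(sprintf(
      "need at least 2 records per bin: %d records for %d bins.",
      length(x), n_bins
    ))
  }
  sorted <- x[order(x)]  # order() is stable: ties keep input order
  n <- length(sorted)
  base_size <- n %/% n_bins
  sizes <- rep(base_size, n_bins)
  remainder <- n %% n_bins
  if (remainder > 0L) sizes[seq_len(remainder)] <- base_size + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  out <- tibble(value = sorted, bin_index = bin) |>
    dplyr::group_by(.data$bin_index) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    )
  if (any(out$mean == 0)) {
    stop_domain("a bin mean is exactly 0; its CV is undefined.")
  }
  out$cv <- out$sd / out$mean
  class(out) <- c("bin_summary", class(out))
  out
}

pull_column <- function(data, col) {
  if (is.character(col)) {
    if (!col %in% names(data)) {
      stop_domain(sprintf(
        "column '%s' not found; available columns: %s.",
        col, paste(names(data), collapse = ", ")
      ))
    }
    return(data[[col]])
  }
  col <- check_count(col, "col", min = 1L)
  if (col > ncol(data)) {
    stop_domain(sprintf(
      "column index %d out of range; the table has %d column(s): %s.",
      col, ncol(data), paste(names(data), collapse = ", ")
    ))
  }
  data[[col]]
}

#' Read a single-column trait table and summarise it in quantile bins
#'
#' Thin CSV front-end over [quantile_bin_summary()], used by the `bins`
#' subcommand of the command-line interface.
#'
#' @param path CSV file with the trait records.
#' @param col Column name or 1-based index. Default: first column.
#' @param n_bins Number of sorted groups. Default 5.
#' @return A `bin_summary` tibble.
#' @export
bin_summary_csv <- function(path, col = 1L, n_bins = 5L) {
  if (!file.exists(path)) stop_domain(sprintf("input file '%s' not found.", path))
  data <- readr::read_csv(path, show_col_types = FALSE)
  quantile_bin_summary(data, col = col, n_bins = n_bins)
}
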