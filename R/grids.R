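new_grid_table <- function(cells, statistic, row_axis, col_axis, base) {
  structure(
    cells,
    statistic = statistic,
    row_axis = row_axis,
    col_axis = col_axis,
    base_config = base,
    class = c("grid_table", class(tibble()))
  )
}

default_base <- function(base, cv, h2) {
  if (is.null(base)) scenario_config(cv = cv, h2 = h2) else base
}

run_grid <- function(row_values, col_values, statistic, make_config, base) {
  cells <- purrr::map_dfr(seq_along(row_values), function(i) {
    purrr::map_dfr(seq_along(col_values), function(j) {
      idx <- (i - 1L) * length(col_values) + (j - 1L)
      cfg <- make_config(row_values[i], col_values[j])
      res <- run_scenario(cfg, scenario_index = idx)
      g <- glance(res)
      g$scenario_index <- idx
      g
    })
  })
  cells
}

#' Mean-variability correlation grid (CV by heritability)
#'
#' Runs the full scale-effect simulation over a grid of coefficient of
#' variation (rows) and heritability (columns) at full scale-effect strength,
#' and summarises the mean genetic correlation between the trait and
#' variability breeding values in each cell. The default axes reproduce the
#' 100-scenario study grid (0.05 to 0.50 in 0.05 steps on both axes, 10
#' replicates of 100,000 individuals per cell).
#'
#' @param cv_values Ordered vector of CV values (rows).
#' @param h2_values Ordered vector of heritabilities (columns).
#' @param base Optional [scenario_config()] supplying `mu`, `n_individuals`,
#'   `n_replicates`, `seed` and the negative-record convention; its `cv` and
#'   `h2` are overridden cell by cell and `r` is fixed at 1. When `NULL`, the
#'   study defaults are used.
#'
#' @return A `grid_table`: a tibble with one row per cell (`cv`, `h2`, `r`,
#'   `mean_rho`, `se_rho`, `mean_gcv`, `se_gcv`, `max_frac_negative`, ...),
#'   with axis metadata in attributes. See [grid_matrix()], [verify_grid()]
#'   and [autoplot.grid_table()].
#' @examples
#' \donttest{
#' g <- run_correlation_grid(cv_values = c(0.05, 0.10), h2_values = c(0.1, 0.3),
#'                           base = scenario_config(cv = 0.05, h2 = 0.1,
#'                                                  n_individuals = 2000,
#'                                                  n_replicates = 3))
#' grid_matrix(g)
#' }
#' @export
run_correlation_grid <- function(cv_values = seq(0.05, 0.50, by = 0.05),
                                 h2_values = seq(0.05, 0.50, by = 0.05),
                                 base = NULL) {
  check_numeric_vector(cv_values, "cv_values")
  check_numeric_vector(h2_values, "h2_values")
  base <- default_base(base, cv_values[1], h2_values[1])
  cells <- run_grid(
    cv_values, h2_values, "mean_rho",
    function(cv, h2) {
      scenario_config(
        cv = cv, h2 = h2, mu = base$mu, r = 1,
        n_individuals = base$n_individuals, n_replicates = base$n_replicates,
        seed = base$seed, negative_handling = base$negative_handling
      )
    },
    base
  )
  new_grid_table(
    cells,
    statistic = "mean_rho",
    row_axis = list(name = "cv", values = cv_values),
    col_axis = list(name = "h2", values = h2_values),
    base = base
  )
}

#' GCV grid (scale-effect strength by CV)
#'
#' Runs the strength-modulated simulation over a grid of scale-effect
#' strength `r` (rows) and coefficient of variation (columns), summarising
#' the genetic coefficient of variation of the variability in each cell. The
#' default axes reproduce the 200-scenario study grid (`r` from 0.05 to 1.00
#' and CV from 0.05 to 0.50, both in 0.05 steps). The GCV does not depend on
#' the heritability (only on the distribution of the standardised record), so
#' the heritability is taken from `base`.
#'
#' Cells whose mean GCV exceeds `flag_threshold` are marked in the `flagged`
#' column: such values are larger than any credible estimate reported for
#' real populations and indicate a biologically implausible corner of the
#' parameter space. They are flagged, not suppressed.
#'
#' @param r_values Ordered vector of strengths in (0, 1] (rows).
#' @param cv_values Ordered vector of CV values (columns).
#' @param base Optional [scenario_config()]; defaults to the study conditions
#'   with `h2 = 0.30`.
#' @param flag_threshold Flag cells with `mean_gcv` above this value.
#'   Default 0.69.
#'
#' @return A `grid_table` tibble with one row per cell, including a `flagged`
#'   logical column.
#' @examples
#' \donttest{
#' g <- run_gcv_grid(r_values = c(0.5, 1), cv_values = c(0.05, 0.1),
#'                   base = scenario_config(cv = 0.05, h2 = 0.3,
#'                                          n_individuals = 2000,
#'                                          n_replicates = 3))
#' g$mean_gcv
#' }
#' @export
run_gcv_grid <- function(r_values = seq(0.05, 1.00, by = 0.05),
                         cv_values = seq(0.05, 0.50, by = 0.05),
                         base = NULL,
                         flag_threshold = 0.69) {
  check_numeric_vector(r_values, "r_values")
  check_numeric_vector(cv_values, "cv_values")
  check_positive(flag_threshold, "flag_threshold")
  if (is.null(base)) base <- scenario_config(cv = cv_values[1], h2 = 0.30)
  cells <- run_grid(
    r_values, cv_values, "mean_gcv",
    function(r, cv) {
      scenario_config(
        cv = cv, h2 = base$h2, mu = base$mu, r = r,
        n_individuals = base$n_individuals, n_replicates = base$n_replicates,
        seed = base$seed, negative_handling = base$negative_handling
      )
    },
    base
  )
  cells$flagged <- cells$mean_gcv > flag_threshold
  new_grid_table(
    cells,
    statistic = "mean_gcv",
    row_axis = list(name = "r", values = r_values),
    col_axis = list(name = "cv", values = cv_values),
    base = base
  )
}

#' Arrange a grid's summary statistic as a labelled matrix
#'
#' @param grid A `grid_table` from [run_correlation_grid()] or
#'   [run_gcv_grid()].
#' @param statistic Column to spread; defaults to the grid's primary
#'   statistic (`mean_rho` or `mean_gcv`).
#'
#' @return A numeric matrix, rows and columns named by the grid axes.
#' @export
grid_matrix <- function(grid, statistic = NULL) {
  stopifnot(inherits(grid, "grid_table"))
  statistic <- statistic %||% attr(grid, "statistic")
  row_axis <- attr(grid, "row_axis")
  col_axis <- attr(grid, "col_axis")
  m <- matrix(
    grid[[statistic]],
    nrow = length(row_axis$values),
    ncol = length(col_axis$values),
    byrow = TRUE,
    dimnames = list(
      vapply(row_axis$values, format, character(1)),
      vapply(col_axis$values, format, character(1))
    )
  )
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.grid_table <- function(x, ...) {
  ra <- attr(x, "row_axis")
  ca <- attr(x, "col_axis")
  cat(sprintf("<grid_table> %s over %s (rows) x %s (columns), %d cells\n",
              attr(x, "statistic"), ra$name, ca$name, nrow(x)))
  NextMethod()
}
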